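#' Construct a spatial contiguity graph
#'
#' Canonical neighbour structure for the ICAR prior: symmetric, no
#' self-loops, with per-area degree and connected-component labels.
#'
#' @param n number of areas.
#' @param edges two-column integer matrix of undirected edges (1-based area
#'   indices); duplicates and reversed pairs are merged.
#' @param area_id optional area identifiers (defaults to `as.character(1:n)`).
#' @return A `spatial_graph`: list with `n`, `edges` (deduplicated, i < j),
#'   `neighbors` (sorted index list per area), `degree`,
#'   `component_labels` (1..c), `n_components`.
#' @export
spatial_graph <- function(n, edges, area_id = NULL) {
  n <- as.integer(n)
  if (n < 1) stop_domain("need at least one area")
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n))
      stop_domain("edge index out of range [1, ", n, "]")
    if (any(edges[, 1] == edges[, 2]))
      stop_domain("self-loop not allowed: area ",
                  edges[edges[, 1] == edges[, 2], 1][1])
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  neighbors <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
  }
  neighbors <- lapply(neighbors, sort)
  structure(
    list(n = n, edges = edges, neighbors = neighbors,
         degree = lengths(neighbors),
         component_labels = bfs_components(n, neighbors),
         area_id = as.character(area_id %||% seq_len(n))),
    class = "spatial_graph")
}

bfs_components <- function(n, neighbors) {
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- neighbors[[i]]
      new <- nb[labels[nb] == 0L]
      labels[new] <- comp
      queue <- c(queue, new)
    }
  }
  labels
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph:", x$n, "areas,", nrow(x$edges), "edges,",
      max(x$component_labels), "component(s)\n")
  invisible(x)
}

#' Connected components of a spatial graph
#'
#' Breadth-first-search labelling; areas share a label iff connected by a
#' path. Needed for the ICAR rank (n - c) and the per-component sum-to-zero
#' constraint.
#'
#' @param graph a `spatial_graph`.
#' @return Integer labels 1..c, one per area.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  graph$component_labels
}

#' Build a graph from an explicit edge list
#'
#' Symmetrizes and deduplicates the supplied pairs. Isolated areas are
#' permitted (their structured effect is pinned at 0 by the sampler).
#'
#' @param n number of areas.
#' @param edges two-column matrix or flat pair sequence of 1-based indices.
#' @param area_id optional identifiers.
#' @return A `spatial_graph`.
#' @export
graph_from_edgelist <- function(n, edges, area_id = NULL) {
  spatial_graph(n, edges, area_id = area_id)
}

#' Read an adjacency edge-list file
#'
#' Plain text, one `id_i<TAB>id_j` pair per line, ids matching the county
#' table; lines starting with `#` are comments.
#'
#' @param path edge-list file path.
#' @param area_id character vector giving the canonical area order.
#' @return A `spatial_graph` over `area_id`.
#' @export
read_edgelist <- function(path, area_id) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  area_id <- as.character(area_id)
  if (!length(lines)) return(spatial_graph(length(area_id),
                                           matrix(integer(0), ncol = 2),
                                           area_id = area_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop_domain("malformed edge-list line: ", lines[bad][1])
  a <- match(vapply(parts, `[`, "", 1), area_id)
  b <- match(vapply(parts, `[`, "", 2), area_id)
  if (anyNA(a) || anyNA(b)) {
    unk <- unique(c(vapply(parts, `[`, "", 1)[is.na(a)],
                    vapply(parts, `[`, "", 2)[is.na(b)]))
    stop_domain("edge-list id not in the county table: ",
                paste(unk, collapse = ", "))
  }
  spatial_graph(length(area_id), cbind(a, b), area_id = area_id)
}

#' Write a graph as an edge-list file
#' @param graph a `spatial_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  lines <- c("# adjacency edge list: id_i<TAB>id_j, one undirected edge per line",
             sprintf("%s\t%s", graph$area_id[graph$edges[, 1]],
                     graph$area_id[graph$edges[, 2]]))
  writeLines(lines, path)
  invisible(path)
}

# ---- contiguity from polygons ----------------------------------------------

# orientation of ordered triple (sign of cross product), with tolerance
orient <- function(p, q, r, tol) {
  v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  if (abs(v) <= tol) 0 else sign(v)
}

on_segment <- function(p, q, r) {
  # r collinear with p-q: is r within the bounding box of p-q?
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

segments_touch <- function(p1, p2, q1, q2, tol) {
  o1 <- orient(p1, p2, q1, tol); o2 <- orient(p1, p2, q2, tol)
  o3 <- orient(q1, q2, p1, tol); o4 <- orient(q1, q2, p2, tol)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_segment(p1, p2, q1)) ||
    (o2 == 0 && on_segment(p1, p2, q2)) ||
    (o3 == 0 && on_segment(q1, q2, p1)) ||
    (o4 == 0 && on_segment(q1, q2, p2))
}

# length of the overlap of two collinear segments (0 if not collinear/overlapping)
collinear_overlap_len <- function(p1, p2, q1, q2, tol) {
  if (orient(p1, p2, q1, tol) != 0 || orient(p1, p2, q2, tol) != 0) return(0)
  d <- p2 - p1
  L2 <- sum(d^2)
  if (L2 <= tol) return(0)
  t <- sort(c(sum((q1 - p1) * d), sum((q2 - p1) * d)) / L2)
  lo <- max(0, t[1]); hi <- min(1, t[2])
  if (hi <= lo) return(0)
  (hi - lo) * sqrt(L2)
}

poly_segments <- function(rings) {
  do.call(rbind, lapply(rings, function(r) {
    k <- nrow(r) - 1
    cbind(r[seq_len(k), , drop = FALSE], r[seq_len(k) + 1, , drop = FALSE])
  }))
}

poly_bbox <- function(rings) {
  all <- do.call(rbind, rings)
  c(min(all[, 1]), min(all[, 2]), max(all[, 1]), max(all[, 2]))
}

pair_contiguous <- function(seg_a, seg_b, rule, tol) {
  shared_len <- 0
  for (i in seq_len(nrow(seg_a))) {
    p1 <- seg_a[i, 1:2]; p2 <- seg_a[i, 3:4]
    for (j in seq_len(nrow(seg_b))) {
      q1 <- seg_b[j, 1:2]; q2 <- seg_b[j, 3:4]
      # cheap per-segment bbox rejection
      if (max(p1[1], p2[1]) < min(q1[1], q2[1]) - tol ||
          min(p1[1], p2[1]) > max(q1[1], q2[1]) + tol ||
          max(p1[2], p2[2]) < min(q1[2], q2[2]) - tol ||
          min(p1[2], p2[2]) > max(q1[2], q2[2]) + tol) next
      if (rule == "queen") {
        if (segments_touch(p1, p2, q1, q2, tol)) return(TRUE)
      } else {
        shared_len <- shared_len + collinear_overlap_len(p1, p2, q1, q2, tol)
        if (shared_len > tol) return(TRUE)
      }
    }
  }
  FALSE
}

#' Contiguity graph from area polygons
#'
#' Two areas are neighbours under queen contiguity iff their boundaries
#' share at least one point (corner touches count); under rook contiguity
#' iff they share a boundary segment of positive length. Computed directly
#' on the supplied coordinates (contiguity is projection-invariant for
#' valid polygons), with a bounding-box prefilter and exact
#' segment-intersection tests.
#'
#' @param polygons a `polygon_set`.
#' @param rule `"queen"` (default) or `"rook"`.
#' @param tol coordinate tolerance for touch detection.
#' @return A `spatial_graph` in the polygon set's area order.
#' @export
build_queen_adjacency <- function(polygons, rule = c("queen", "rook"),
                                  tol = 1e-9) {
  stopifnot(inherits(polygons, "polygon_set"))
  rule <- match.arg(rule)
  n <- polygons$n_areas
  if (n < 2) stop_domain("need at least 2 areas")
  segs <- lapply(polygons$geometry, poly_segments)
  boxes <- t(vapply(polygons$geometry, poly_bbox, numeric(4)))
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (boxes[i, 3] < boxes[j, 1] - tol || boxes[j, 3] < boxes[i, 1] - tol ||
          boxes[i, 4] < boxes[j, 2] - tol || boxes[j, 4] < boxes[i, 2] - tol)
        next
      if (pair_contiguous(segs[[i]], segs[[j]], rule, tol))
        edges[[length(edges) + 1]] <- c(i, j)
    }
  }
  if (!length(edges))
    stop_domain("no contiguity edges found between the ", n, " areas; ",
                "supply an explicit adjacency edge-list instead")
  spatial_graph(n, do.call(rbind, edges), area_id = polygons$area_id)
}

#' ICAR structure/precision matrix
#'
#' The intrinsic CAR structure matrix Q = D - A: diagonal entries are
#' neighbour counts, off-diagonal entries are -1 for neighbouring pairs.
#' Every row sums to zero; Q is positive semidefinite with rank n - c,
#' where c is the number of connected components (the rank deficiency).
#' The ICAR prior on the structured effect w has precision Q / sigma_w^2 on
#' the per-component sum-to-zero subspace.
#'
#' @param graph a `spatial_graph` with at least one edge.
#' @return List with `Q` (a sparse symmetric [Matrix::Matrix]) and
#'   `rank_deficiency` (number of components).
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (!nrow(graph$edges)) stop_domain("graph has no edges")
  n <- graph$n
  e <- graph$edges
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n), e[, 1], e[, 2]),
    j = c(seq_len(n), e[, 2], e[, 1]),
    x = c(as.numeric(graph$degree), rep(-1, 2 * nrow(e))),
    dims = c(n, n), symmetric = FALSE)
  list(Q = Matrix::forceSymmetric(Q),
       rank_deficiency = max(graph$component_labels))
}

#' Regular lattice contiguity graph
#'
#' Grid of `rows x cols` cells in row-major order; rook edges join
#' horizontal/vertical neighbours, queen additionally joins diagonals.
#'
#' @param rows,cols lattice dimensions (`rows * cols >= 2`).
#' @param rule `"rook"` (default) or `"queen"`.
#' @return A `spatial_graph` with ids `"r<i>c<j>"`.
#' @export
lattice_graph <- function(rows, cols, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 2) stop_domain("need at least 2 cells")
  idx <- function(r, c) (r - 1L) * cols + c
  edges <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) edges[[length(edges) + 1]] <- c(idx(r, c), idx(r, c + 1))
    if (r < rows) edges[[length(edges) + 1]] <- c(idx(r, c), idx(r + 1, c))
    if (rule == "queen") {
      if (r < rows && c < cols)
        edges[[length(edges) + 1]] <- c(idx(r, c), idx(r + 1, c + 1))
      if (r < rows && c > 1)
        edges[[length(edges) + 1]] <- c(idx(r, c), idx(r + 1, c - 1))
    }
  }
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(r, c) sprintf("r%dc%d", r, c))))
  spatial_graph(rows * cols, do.call(rbind, edges), area_id = ids)
}

#' Unit-square polygons for a lattice
#'
#' Synthetic geometry matching [lattice_graph()] cell order, so the mapping
#' and contiguity code are testable without real geography.
#'
#' @param rows,cols lattice dimensions.
#' @return A `polygon_set` of unit squares (cell (r,c) spans
#'   `[c-1,c] x [rows-r, rows-r+1]`).
#' @export
grid_polygons <- function(rows, cols) {
  geoms <- list(); ids <- character(0)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    x0 <- c - 1; y0 <- rows - r
    ring <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                  c(x0, y0 + 1), c(x0, y0))
    geoms[[length(geoms) + 1]] <- list(ring)
    ids <- c(ids, sprintf("r%dc%d", r, c))
  }
  new_polygon_set(ids, geoms)
}
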