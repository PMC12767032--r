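test_that("queen contiguity on a 2x2 grid finds all 6 touching pairs", {
  polys <- grid_polygons(2, 2)
  g <- build_queen_adjacency(polys, rule = "queen")
  # brute-force oracle: every pair of the 4 unit squares shares at least a
  # corner, so all choose(4,2) = 6 pairs are neighbours
  expect_equal(nrow(g$edges), 6L)
  expect_equal(sort(g$degree), rep(3L, 4))

  rook <- build_queen_adjacency(polys, rule = "rook")
  expect_equal(nrow(rook$edges), 4L)  # diagonal corner-touches drop out
})

test_that("a 1x3 strip yields only shared-border edges", {
  g <- build_queen_adjacency(grid_polygons(1, 3))
  expect_equal(g$edges, cbind(c(1L, 2L), c(2L, 3L)),
               ignore_attr = TRUE)
  expect_equal(g$degree, c(1L, 2L, 1L))
})

test_that("polygons with no contiguity at all are rejected with advice", {
  far <- structure(list(area_id = c("a", "b"), geometry = list(
    list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))),
    list(rbind(c(5, 5), c(6, 5), c(6, 6), c(5, 6), c(5, 5)))),
    n_areas = 2L), class = "polygon_set")
  expect_error(build_queen_adjacency(far), "edge-list")
})

test_that("edge lists are symmetrized, deduplicated and validated", {
  g <- graph_from_edgelist(3, rbind(c(1, 2), c(2, 1), c(2, 3)))
  expect_equal(g$neighbors[[2]], c(1L, 3L))
  expect_equal(g$degree, c(1L, 2L, 1L))
  expect_equal(nrow(g$edges), 2L)

  g2 <- graph_from_edgelist(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(max(connected_components(g2)), 2L)

  expect_error(graph_from_edgelist(2, rbind(c(1, 1))), "self-loop")
  expect_error(graph_from_edgelist(2, rbind(c(1, 3))), "out of range")
})

test_that("connected components match the igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    m <- sample(1:(2 * n), 1)
    edges <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (!nrow(edges)) edges <- cbind(1, 2)
    g <- graph_from_edgelist(n, edges)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    oracle <- igraph::components(ig)$membership
    labels <- connected_components(g)
    # same partition: labels agree up to relabelling
    expect_equal(length(unique(labels)), length(unique(oracle)))
    expect_true(all(tapply(oracle, labels,
                           function(v) length(unique(v))) == 1))
  }
  g8 <- lattice_graph(8, 8, "rook")
  expect_equal(max(connected_components(g8)), 1L)
})

test_that("ICAR precision has the defining structure, rank and row sums", {
  g <- graph_from_edgelist(3, rbind(c(1, 2), c(2, 3)))
  Q <- as.matrix(icar_precision(g)$Q)
  expect_equal(unname(Q),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  g64 <- lattice_graph(8, 8, "rook")
  p <- icar_precision(g64)
  ev <- eigen(as.matrix(p$Q), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-8), 63L)  # rank n - c by eigenvalue count
  expect_equal(p$rank_deficiency, 1L)

  set.seed(4)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    m <- sample(1:(2 * n), 1)
    edges <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (!nrow(edges)) edges <- cbind(1, 2)
    g <- graph_from_edgelist(n, edges)
    p <- icar_precision(g)
    Q <- as.matrix(p$Q)
    A <- matrix(0, n, n)
    A[g$edges] <- 1
    A <- A + t(A)
    expect_equal(Q, diag(as.numeric(g$degree)) - A, ignore_attr = TRUE)
    expect_equal(max(abs(rowSums(Q))), 0)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    c_g <- max(connected_components(g))
    expect_true(all(ev > -1e-10))
    expect_equal(sum(abs(ev) < 1e-8), c_g)  # null-space multiplicity = c
  }
})

test_that("Q implies the stated full conditional on a 5-node toy", {
  # conditional of a Gaussian with precision P = Q/sigma2:
  # mean -P_ii^{-1} sum_j P_ij w_j = neighbour average, var = sigma2/n_i
  g <- graph_from_edgelist(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                    c(2, 5)))
  sigma2 <- 0.7
  P <- as.matrix(icar_precision(g)$Q) / sigma2
  set.seed(9)
  w <- rnorm(5)
  for (i in 1:5) {
    cond_mean <- -sum(P[i, -i] * w[-i]) / P[i, i]
    expect_equal(cond_mean, mean(w[g$neighbors[[i]]]))
    expect_equal(1 / P[i, i], sigma2 / g$degree[i])
  }
})

test_that("lattice graphs have the known edge counts and degrees", {
  expect_equal(nrow(lattice_graph(2, 2, "rook")$edges), 4L)
  expect_equal(nrow(lattice_graph(2, 2, "queen")$edges), 6L)
  g15 <- lattice_graph(1, 5, "rook")
  expect_equal(g15$degree, c(1L, 2L, 2L, 2L, 1L))
  # rook edge count formula r(c-1) + c(r-1) vs brute-force cell adjacency
  for (r in 1:6) for (cc in 1:6) {
    if (r * cc < 2) next
    g <- lattice_graph(r, cc, "rook")
    pos <- expand.grid(col = seq_len(cc), row = seq_len(r))
    brute <- sum(as.matrix(dist(pos[, c("row", "col")],
                                method = "manhattan")) == 1) / 2
    expect_equal(nrow(g$edges), r * (cc - 1) + cc * (r - 1))
    expect_equal(nrow(g$edges), as.integer(brute))
  }
})

test_that("edge-list files round trip, honour comments, reject unknown ids", {
  g <- lattice_graph(3, 3, "rook")
  path <- tempfile(fileext = ".tsv")
  write_edgelist(g, path)
  back <- read_edgelist(path, g$area_id)
  expect_equal(back$edges, g$edges)
  expect_error(read_edgelist(path, g$area_id[-1]), "not in the county table")
  writeLines(c("# comment", "a\tb"), path)
  g2 <- read_edgelist(path, c("a", "b", "c"))
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$degree, c(1L, 1L, 0L))
})
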