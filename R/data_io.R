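#' Construct a county table
#'
#' The canonical per-area container used by every other module: one row per
#' area with a unique id, a display name, an outcome proportion strictly
#' inside (0,1), and a numeric covariate matrix in percent units. Row order
#' is the canonical area order throughout the package.
#'
#' @param area_id character vector of unique area identifiers.
#' @param y numeric outcome proportions, all strictly in (0,1).
#' @param X numeric matrix of covariates (one row per area), or NULL for an
#'   intercept-only model. Column names are the covariate names.
#' @param area_name optional display names; defaults to `area_id`.
#' @return An object of class `county_table` with fields `area_id`,
#'   `area_name`, `y`, `X`, `n_areas`.
#' @export
county_table <- function(area_id, y, X = NULL, area_name = NULL) {
  area_id <- as.character(area_id)
  n <- length(area_id)
  if (anyDuplicated(area_id))
    stop_domain("integrity error: duplicate area_id: ",
                paste(unique(area_id[duplicated(area_id)]), collapse = ", "))
  y <- as.numeric(y)
  if (length(y) != n) stop_domain("y must have one value per area")
  bad <- !is.finite(y) | y <= 0 | y >= 1
  if (any(bad))
    stop_domain("domain error: outcome not in open interval (0,1) for area_id: ",
                paste(area_id[bad], collapse = ", "))
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (nrow(X) != n) stop_domain("X must have one row per area")
    if (anyNA(X)) {
      bad_col <- colnames(X)[colSums(is.na(X)) > 0]
      stop_domain("missing covariate values in column(s): ",
                  paste(bad_col, collapse = ", "))
    }
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  structure(
    list(area_id = area_id,
         area_name = as.character(area_name %||% area_id),
         y = y, X = X, n_areas = n),
    class = "county_table")
}

#' @export
print.county_table <- function(x, ...) {
  cat("county_table:", x$n_areas, "areas,", ncol(x$X), "covariates\n")
  cat("  y: mean", format(mean(x$y), digits = 4),
      " range [", format(min(x$y), digits = 4), ",",
      format(max(x$y), digits = 4), "]\n")
  if (ncol(x$X)) cat("  covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Read a county table from CSV
#'
#' Reads a UTF-8 CSV with a header row, maps the named columns onto the
#' `county_table` schema, and normalizes the outcome to a proportion.
#' Outcomes reported as percentages (the usual public-health convention)
#' are divided by 100. Values exactly at the boundary (0 or 1 as a
#' proportion; 0 or 100 as a percent) are rejected, not clamped: the beta
#' likelihood places no mass on the boundary.
#'
#' @param path CSV file path.
#' @param id_col name of the unique-identifier column.
#' @param outcome_col name of the outcome column.
#' @param covariate_cols character vector of covariate column names; NULL
#'   (default) takes every numeric column other than id/name/outcome.
#' @param name_col optional display-name column.
#' @param outcome_unit `"percent"` (divide by 100) or `"proportion"`.
#' @param standardize if TRUE, center and scale covariate columns. Off by
#'   default so coefficients stay interpretable per percentage point.
#' @return A [county_table].
#' @export
read_county_table <- function(path, id_col = "area_id", outcome_col = "y",
                              covariate_cols = NULL, name_col = NULL,
                              outcome_unit = c("percent", "proportion"),
                              standardize = FALSE) {
  outcome_unit <- match.arg(outcome_unit)
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  need <- c(id_col, outcome_col, name_col, covariate_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_domain("schema error: missing column(s): ",
                paste(missing_cols, collapse = ", "))
  y_raw <- as.numeric(df[[outcome_col]])
  if (outcome_unit == "percent") {
    bad <- !is.finite(y_raw) | y_raw <= 0 | y_raw >= 100
    if (any(bad))
      stop_domain("domain error: percent outcome outside (0,100) for area_id: ",
                  paste(df[[id_col]][bad], collapse = ", "))
    y <- y_raw / 100
  } else {
    bad <- !is.finite(y_raw) | y_raw <= 0 | y_raw >= 1
    if (any(bad))
      stop_domain("domain error: proportion outcome outside (0,1) for area_id: ",
                  paste(df[[id_col]][bad], collapse = ", "))
    y <- y_raw
  }
  if (is.null(covariate_cols)) {
    skip <- c(id_col, outcome_col, name_col)
    covariate_cols <- names(df)[vapply(df, is.numeric, logical(1)) &
                                  !(names(df) %in% skip)]
  }
  X <- if (length(covariate_cols)) {
    m <- as.matrix(df[, covariate_cols, drop = FALSE])
    storage.mode(m) <- "double"
    m
  } else NULL
  if (standardize && !is.null(X)) X <- scale(X)[, , drop = FALSE]
  county_table(area_id = df[[id_col]], y = y, X = X,
               area_name = if (!is.null(name_col)) df[[name_col]])
}

#' Write a county table to CSV
#'
#' Inverse of [read_county_table()] with `outcome_unit = "proportion"`:
#' writes full-precision proportions so a round trip reproduces `y` exactly
#' and preserves area order.
#'
#' @param table a [county_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_county_table <- function(table, path) {
  stopifnot(inherits(table, "county_table"))
  df <- data.frame(area_id = table$area_id, area_name = table$area_name,
                   y = format(table$y, digits = 17, scientific = FALSE,
                              trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(table$X)) df <- cbind(df, as.data.frame(table$X))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a county table
#'
#' Re-checks every `county_table` invariant without raising, returning a
#' report listing each violation (severity `"error"`) and each suspicious
#' but tolerable feature (severity `"warning"`, e.g. a zero-variance
#' covariate column). Status is `"fail"` iff at least one error-severity
#' issue exists.
#'
#' @param table a list or `county_table` with fields `area_id`, `y`, `X`.
#' @return A `validation_report`: list with `status` (`"pass"`/`"fail"`)
#'   and `issues` (data.frame with columns severity, where, message).
#' @export
validate_county_table <- function(table) {
  issues <- data.frame(severity = character(0), where = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  add <- function(severity, where, message)
    rbind(issues, data.frame(severity = severity, where = where,
                             message = message, stringsAsFactors = FALSE))
  ids <- as.character(table$area_id)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) issues <- add("error", d, "duplicate area_id")
  y <- table$y
  bad_y <- which(!is.finite(y) | y <= 0 | y >= 1)
  for (i in bad_y)
    issues <- add("error", ids[i], "outcome not strictly inside (0,1)")
  X <- table$X
  if (!is.null(X) && ncol(X)) {
    for (j in seq_len(ncol(X))) {
      cn <- colnames(X)[j] %||% paste0("x", j)
      if (anyNA(X[, j])) issues <- add("error", cn, "missing covariate values")
      else if (isTRUE(var(X[, j]) == 0))
        issues <- add("warning", cn, "covariate column has zero variance")
    }
  }
  status <- if (any(issues$severity == "error")) "fail" else "pass"
  structure(list(status = status, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", x$status, "-", nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}

# ---- polygons (GeoJSON) -----------------------------------------------------

# A polygon_set stores, per area, a list of rings; each ring is a closed
# 2-column coordinate matrix. MultiPolygons flatten to their outer+hole rings.

new_polygon_set <- function(area_id, geoms) {
  structure(list(area_id = as.character(area_id), geometry = geoms,
                 n_areas = length(area_id)),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat("polygon_set:", x$n_areas, "areas\n")
  invisible(x)
}

clean_ring <- function(m) {
  m <- as.matrix(m)
  # drop consecutive duplicate vertices, then close the ring
  if (nrow(m) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 3) return(NULL)
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

geojson_geom_rings <- function(geom) {
  type <- geom$type
  coords <- geom$coordinates
  ring_from <- function(r) {
    if (is.matrix(r)) r else do.call(rbind, lapply(r, function(p) unlist(p)[1:2]))
  }
  rings <- switch(type,
    Polygon = lapply(coords, ring_from),
    MultiPolygon = unlist(lapply(coords, function(poly)
      lapply(poly, ring_from)), recursive = FALSE),
    stop_domain("unsupported geometry type: ", type))
  rings <- lapply(rings, clean_ring)
  rings[!vapply(rings, is.null, logical(1))]
}

#' Read area polygons from GeoJSON
#'
#' Parses an RFC 7946 GeoJSON FeatureCollection of Polygon/MultiPolygon
#' features into a `polygon_set`. Rings are lightly repaired (consecutive
#' duplicate vertices removed, rings closed); Shapefile input is not
#' supported in this build and raises an informative error.
#'
#' @param path GeoJSON file path (`.json`/`.geojson`).
#' @param id_property name of the feature property carrying the area id.
#' @return A `polygon_set`: `area_id` plus, per area, a list of closed
#'   coordinate rings.
#' @export
read_polygons <- function(path, id_property = "area_id") {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  if (grepl("\\.shp$", path, ignore.case = TRUE))
    stop_domain("Shapefile input is not supported; convert to GeoJSON ",
                "or supply a plain adjacency edge-list instead")
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop_domain("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- character(length(feats))
  geoms <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]]
    if (is.null(id))
      stop_domain("feature ", i, " has no property '", id_property, "'")
    ids[i] <- as.character(id)
    coords <- f$geometry$coordinates
    # normalize nested lists to matrices
    geom <- list(type = f$geometry$type, coordinates = coords)
    geoms[[i]] <- geojson_geom_rings(geom)
    if (!length(geoms[[i]]))
      stop_domain("feature ", i, " (id ", ids[i], ") has no valid ring")
  }
  if (anyDuplicated(ids))
    stop_domain("integrity error: duplicate feature id: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  new_polygon_set(ids, geoms)
}

#' Write a polygon set to GeoJSON
#'
#' @param polygons a `polygon_set`.
#' @param path output path.
#' @param properties optional data.frame of extra per-area feature
#'   properties (row order = area order).
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path, properties = NULL) {
  stopifnot(inherits(polygons, "polygon_set"))
  feats <- lapply(seq_len(polygons$n_areas), function(i) {
    props <- list(area_id = polygons$area_id[i])
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    rings <- lapply(polygons$geometry[[i]], function(r)
      lapply(seq_len(nrow(r)), function(k) as.numeric(r[k, ])))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
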