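#' Conditional replication of a real county analysis
#'
#' End-to-end pipeline for a user-supplied state-wide county dataset (e.g.
#' the Florida BRFSS county prevalence table together with a county
#' adjacency source): reads the CSV and the adjacency edge-list or GeoJSON,
#' reports the crude observed prevalence summary, fits the beta-BYM model,
#' and returns the fitted summaries including the highest- and
#' lowest-predicted counties. The published county table and adjacency are
#' not redistributed with this package; this function errors with download
#' guidance when the files are absent.
#'
#' @param table_path CSV path (see [read_county_table()]).
#' @param adjacency_path edge-list (`.tsv`/`.txt`) or GeoJSON path.
#' @param id_col,name_col,outcome_col,covariate_cols,outcome_unit passed to
#'   [read_county_table()].
#' @param config an [mcmc_config()].
#' @param ... further arguments to [fit_bym()].
#' @return List: `crude` (mean/min/max of observed prevalence, percent),
#'   `fit` (a `bym_fit`), `highest`, `lowest` (area names by predicted
#'   prevalence).
#' @export
florida_replication <- function(table_path, adjacency_path,
                                id_col = "area_id", name_col = NULL,
                                outcome_col = "y",
                                covariate_cols = NULL,
                                outcome_unit = "percent",
                                config = mcmc_config(), ...) {
  for (p in c(table_path, adjacency_path)) {
    if (!file.exists(p))
      stop_domain("replication data not supplied: '", p, "' not found. ",
                  "Obtain the county prevalence table (flhealthcharts.gov) ",
                  "and a county adjacency edge-list or GeoJSON, then pass ",
                  "their paths.")
  }
  table <- read_county_table(table_path, id_col = id_col,
                             name_col = name_col, outcome_col = outcome_col,
                             covariate_cols = covariate_cols,
                             outcome_unit = outcome_unit)
  graph <- if (grepl("\\.(geojson|json)$", adjacency_path,
                     ignore.case = TRUE)) {
    polys <- read_polygons(adjacency_path, id_property = id_col)
    ord <- match(table$area_id, polys$area_id)
    if (anyNA(ord))
      stop_domain("polygon ids do not cover the county table")
    build_queen_adjacency(new_polygon_set(polys$area_id[ord],
                                          polys$geometry[ord]))
  } else {
    read_edgelist(adjacency_path, table$area_id)
  }
  fit <- fit_bym(table, graph, config = config, ...)
  preds <- fit$predictions
  list(crude = 100 * fit$overall$observed,
       fit = fit,
       highest = preds$area_name[which.max(preds$predicted)],
       lowest = preds$area_name[which.min(preds$predicted)])
}
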