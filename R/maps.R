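# Choropleth outputs: static PNG (ggplot2) or deterministic SVG (written
# directly so two identical runs are byte-identical), plus a self-contained
# interactive HTML document with per-area hover tooltips.

# light -> red, the conventional high-burden palette (YlOrRd, 5 classes)
default_palette <- c("#FFFFB2", "#FECC5C", "#FD8D3C", "#F03B20", "#BD0026")

#' Build a choropleth layer
#'
#' Binds per-area values to polygons and classifies them. Quantile breaks
#' (5 classes by default) mirror the ordered-bin legends conventional in
#' disease maps; explicit cut points give cross-run comparability.
#'
#' @param polygons a `polygon_set`.
#' @param values numeric vector named by area_id, or unnamed in polygon
#'   order.
#' @param legend_title legend string.
#' @param palette ordered colours, low to high.
#' @param class_breaks either a single integer (number of quantile classes)
#'   or an explicit strictly increasing vector of interior cut points.
#' @return A `map_layer`.
#' @export
map_layer <- function(polygons, values, legend_title = "value",
                      palette = NULL, class_breaks = 5) {
  stopifnot(inherits(polygons, "polygon_set"))
  if (!is.null(names(values))) {
    miss <- setdiff(polygons$area_id, names(values))
    if (length(miss))
      stop_domain("values missing for area(s): ", paste(miss, collapse = ", "))
    values <- values[polygons$area_id]
  }
  if (length(values) != polygons$n_areas)
    stop_domain("values not aligned with polygons")
  if (length(class_breaks) == 1 && class_breaks >= 1) {
    n_class <- as.integer(class_breaks)
    cuts <- unique(quantile(values, probs = seq_len(n_class - 1) / n_class,
                            type = 7))
  } else {
    cuts <- class_breaks
    if (is.unsorted(cuts, strictly = TRUE))
      stop_domain("explicit class breaks must be strictly increasing")
  }
  n_class <- length(cuts) + 1
  palette <- palette %||% if (n_class <= 5)
    default_palette[round(seq(1, 5, length.out = n_class))]
  else grDevices::colorRampPalette(default_palette)(n_class)
  class_idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  structure(list(polygons = polygons, values = as.numeric(values),
                 legend_title = legend_title, palette = palette,
                 cuts = cuts, class_idx = class_idx),
            class = "map_layer")
}

layer_class_labels <- function(layer) {
  bounds <- c(min(layer$values), layer$cuts, max(layer$values))
  vapply(seq_along(layer$palette), function(i)
    sprintf("%.3g–%.3g", bounds[i], bounds[i + 1]), "")
}

#' Render a static choropleth
#'
#' Writes `.png` via ggplot2 or `.svg` via a direct deterministic SVG
#' writer (two runs with identical inputs produce byte-identical vector
#' output; one `<path>` element per area). A legend is always present.
#'
#' @param layer a [map_layer()].
#' @param path output path ending in `.png` or `.svg`.
#' @param width,height image size (pixels for SVG; inches at 150 dpi for
#'   PNG).
#' @return `path`, invisibly.
#' @export
render_static_map <- function(layer, path, width = 7, height = 6) {
  stopifnot(inherits(layer, "map_layer"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") return(render_svg_map(layer, path,
                                          width * 100, height * 100))
  if (ext != "png") stop_domain("unsupported image format: .", ext)
  polys <- layer$polygons
  dfs <- lapply(seq_len(polys$n_areas), function(i) {
    ring <- polys$geometry[[i]][[1]]
    data.frame(x = ring[, 1], y = ring[, 2], id = polys$area_id[i],
               class = factor(layer$class_idx[i],
                              levels = seq_along(layer$palette)))
  })
  df <- do.call(rbind, dfs)
  labs <- layer_class_labels(layer)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$id,
                                        fill = .data$class)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = layer$palette,
                               labels = labs, drop = FALSE,
                               name = layer$legend_title) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

svg_path_d <- function(rings) {
  paste(vapply(rings, function(r) {
    paste0("M", paste(sprintf("%.4f,%.4f", r[, 1], r[, 2]), collapse = " L"),
           " Z")
  }, ""), collapse = " ")
}

map_transform <- function(polygons, width, height, margin = 20) {
  all <- do.call(rbind, unlist(polygons$geometry, recursive = FALSE))
  xr <- range(all[, 1]); yr <- range(all[, 2])
  s <- min((width - 2 * margin) / max(diff(xr), 1e-12),
           (height - 2 * margin) / max(diff(yr), 1e-12))
  function(ring) cbind(margin + (ring[, 1] - xr[1]) * s,
                       height - margin - (ring[, 2] - yr[1]) * s)
}

render_svg_map <- function(layer, path, width, height) {
  tr <- map_transform(layer$polygons, width, height)
  labs <- layer_class_labels(layer)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            round(width), round(height), round(width), round(height)),
    sprintf('<title>%s</title>', layer$legend_title))
  for (i in seq_len(layer$polygons$n_areas)) {
    rings <- lapply(layer$polygons$geometry[[i]], tr)
    lines <- c(lines, sprintf(
      '<path id="%s" d="%s" fill="%s" stroke="#444444" stroke-width="0.5"/>',
      layer$polygons$area_id[i], svg_path_d(rings),
      layer$palette[layer$class_idx[i]]))
  }
  # legend: one swatch per class
  for (ci in seq_along(layer$palette)) {
    y0 <- 10 + (ci - 1) * 18
    lines <- c(lines,
      sprintf('<rect x="%d" y="%d" width="14" height="14" fill="%s" stroke="#444444"/>',
              round(width) - 130, y0, layer$palette[ci]),
      sprintf('<text x="%d" y="%d" font-size="11">%s</text>',
              round(width) - 112, y0 + 11, labs[ci]))
  }
  lines <- c(lines,
    sprintf('<text x="%d" y="%d" font-size="12" font-weight="bold">%s</text>',
            round(width) - 130, round(height) - 8, layer$legend_title),
    '</svg>')
  writeLines(lines, path)
  invisible(path)
}

pct1 <- function(x) sprintf("%.1f", 100 * x)

#' Render the interactive web map
#'
#' Writes a single self-contained HTML document (inline SVG + vanilla
#' JavaScript; opens offline, no external references). Hovering an area
#' polygon shows its tooltip: county name, observed and predicted
#' prevalence (%), the lower and upper 95% credible bounds (%), and the
#' value of each significant risk factor, all to one decimal place. Fill
#' colour increases toward red with the mapped value; a legend and layer
#' title are embedded.
#'
#' @param fit a `bym_fit`.
#' @param polygons a `polygon_set` covering every fitted area.
#' @param path output `.html` path.
#' @param layer_choice `"predicted"`, `"sd"`, or `"exceedance"`.
#' @param threshold exceedance threshold used when
#'   `layer_choice = "exceedance"`.
#' @param class_breaks passed to [map_layer()].
#' @return `path`, invisibly.
#' @export
render_interactive_map <- function(fit, polygons, path,
                                   layer_choice = c("predicted", "sd",
                                                    "exceedance"),
                                   threshold = 0.70, class_breaks = 5) {
  stopifnot(inherits(fit, "bym_fit"), inherits(polygons, "polygon_set"))
  layer_choice <- match.arg(layer_choice)
  preds <- fit$predictions
  missing_geo <- setdiff(preds$area_id, polygons$area_id)
  if (length(missing_geo))
    stop_domain("no geometry for area(s): ",
                paste(missing_geo, collapse = ", "))
  vals <- switch(layer_choice,
    predicted = setNames(preds$predicted, preds$area_id),
    sd = setNames(preds$sd, preds$area_id),
    exceedance = {
      cn <- sprintf("exceed_%g", threshold)
      if (!cn %in% names(fit$exceedance))
        stop_domain("fit has no exceedance column for threshold ", threshold)
      setNames(fit$exceedance[[cn]], fit$exceedance$area_id)
    })
  title <- switch(layer_choice,
    predicted = "Predicted prevalence",
    sd = "Prediction SD",
    exceedance = sprintf("Pr(prevalence > %s%%)", 100 * threshold))
  keep <- polygons$area_id %in% preds$area_id
  polys <- new_polygon_set(polygons$area_id[keep], polygons$geometry[keep])
  layer <- map_layer(polys, vals, legend_title = title,
                     class_breaks = class_breaks)
  sig <- if (!is.null(fit$covariates))
    fit$covariates$covariate[fit$covariates$significant] else character(0)
  X <- fit$samples$table$X
  ord <- match(polys$area_id, preds$area_id)
  tips <- vapply(seq_along(ord), function(kk) {
    i <- ord[kk]
    parts <- c(
      sprintf("<b>%s</b>", preds$area_name[i]),
      sprintf("Observed prevalence: %s%%", pct1(preds$observed[i])),
      sprintf("Predicted prevalence: %s%%", pct1(preds$predicted[i])),
      sprintf("Lower 95%% CrI: %s%%", pct1(preds$lower[i])),
      sprintf("Upper 95%% CrI: %s%%", pct1(preds$upper[i])))
    for (cv in sig)
      parts <- c(parts, sprintf("%s: %.1f%%", cv, X[i, cv]))
    paste(parts, collapse = "<br/>")
  }, "")
  width <- 800; height <- 650
  tr <- map_transform(polys, width, height)
  labs <- layer_class_labels(layer)
  features <- lapply(seq_len(polys$n_areas), function(i) list(
    id = polys$area_id[i],
    d = svg_path_d(lapply(polys$geometry[[i]], tr)),
    fill = layer$palette[layer$class_idx[i]],
    value = layer$values[i],
    tooltip = tips[i]))
  payload <- jsonlite::toJSON(features, auto_unbox = TRUE, digits = 8)
  legend_html <- paste(vapply(seq_along(layer$palette), function(ci)
    sprintf('<div><span class="sw" style="background:%s"></span>%s</div>',
            layer$palette[ci], labs[ci]), ""), collapse = "\n")
  html <- c(
    '<!DOCTYPE html>',
    '<html><head><meta charset="utf-8"/>',
    sprintf('<title>%s</title>', title),
    '<style>',
    'body{font-family:sans-serif;margin:12px}',
    '#tooltip{position:absolute;display:none;background:#fff;border:1px solid #888;',
    ' padding:6px 8px;font-size:12px;pointer-events:none;box-shadow:2px 2px 4px rgba(0,0,0,.3)}',
    'path.area{stroke:#444;stroke-width:.6;cursor:pointer}',
    'path.area:hover{stroke:#000;stroke-width:1.5}',
    '.legend{font-size:12px}.legend .sw{display:inline-block;width:13px;height:13px;',
    ' margin-right:5px;border:1px solid #444;vertical-align:middle}',
    '</style></head><body>',
    sprintf('<h3>%s</h3>', title),
    sprintf('<svg id="map" width="%d" height="%d"></svg>', width, height),
    sprintf('<div class="legend"><b>%s</b>%s</div>', title, legend_html),
    '<div id="tooltip"></div>',
    '<script>',
    sprintf('var features = %s;', payload),
    'var svg = document.getElementById("map");',
    'var tip = document.getElementById("tooltip");',
    'features.forEach(function(f){',
    ' var p = document.createElementNS("http://www.w3.org/2000/svg","path");',
    ' p.setAttribute("d", f.d); p.setAttribute("fill", f.fill);',
    ' p.setAttribute("class","area"); p.setAttribute("id","area-"+f.id);',
    ' p.addEventListener("mousemove", function(ev){',
    '  tip.style.display="block"; tip.innerHTML=f.tooltip;',
    '  tip.style.left=(ev.pageX+12)+"px"; tip.style.top=(ev.pageY+12)+"px";});',
    ' p.addEventListener("mouseleave", function(){tip.style.display="none";});',
    ' svg.appendChild(p);});',
    '</script></body></html>')
  writeLines(html, path)
  invisible(path)
}
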