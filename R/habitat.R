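#' Classify a suitability map into habitat classes
#'
#' Logistic suitabilities are binned into four classes: unsuitable
#' \[0, 0.25), marginal \[0.25, 0.5), moderate \[0.5, 0.75), core
#' \[0.75, 1\]. Bins are half-open with the top bin closed; cut points are
#' configurable.
#'
#' @param map A logistic `suitability_map` (values in \[0, 1\]).
#' @param bounds The three interior cut points, strictly increasing within
#'   (0, 1).
#' @return Object of class `habitat_map`: a class-code raster (1-4) with a
#'   `levels` legend.
#' @export
classify_suitability <- function(map, bounds = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(map, "grid_raster"))
  kind <- attr(map, "output_kind")
  if (!is.null(kind) && kind != "logistic")
    stop("habitat classification requires a logistic suitability map")
  v <- map$values
  fin <- is.finite(v)
  if (any(v[fin] < 0 | v[fin] > 1))
    stop("suitability values must lie in [0, 1]")
  if (length(bounds) != 3L || is.unsorted(bounds, strictly = TRUE) ||
      bounds[1] <= 0 || bounds[3] >= 1)
    stop("bounds must be three increasing cut points inside (0, 1)")
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[fin] <- findInterval(v[fin], bounds) + 1   # right-open bins
  structure(list(header = map$header, values = cls,
                 levels = c("unsuitable", "marginal", "moderate", "core"),
                 bounds = bounds),
            class = c("habitat_map"))
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("habitat_map: class counts\n")
  print(habitat_counts(x))
  invisible(x)
}

habitat_counts <- function(classes) {
  v <- classes$values[is.finite(classes$values)]
  tab <- table(factor(v, levels = 1:4, labels = classes$levels))
  as.integer(tab) -> n
  stats::setNames(n, classes$levels)
}

#' Per-class climatic envelopes
#'
#' For every habitat class and bioclimatic variable, the minimum and
#' maximum over the class's member cells — the climatic threshold table of
#' a suitability analysis. Empty classes yield `NA` entries with a
#' warning. When an importance table is supplied its percent contribution
#' is carried through and rows are ordered by decreasing importance.
#'
#' @param classes A [classify_suitability()] result.
#' @param stack The [bioclim_stack()] the classes were derived from.
#' @param importance Optional `importance_table` (from
#'   [jackknife_importance()]).
#' @return Data frame of class `envelope_table`: `variable`, optional
#'   `importance`, then `<class>_min` / `<class>_max` columns.
#' @export
envelope_table <- function(classes, stack, importance = NULL) {
  stopifnot(inherits(classes, "habitat_map"))
  layers <- as_layer_list(stack)
  if (!headers_compatible(attr(layers, "header"), classes$header))
    stop("stack and habitat map have incompatible headers")
  vars <- names(layers)
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  if (!is.null(importance)) {
    imp <- stats::setNames(importance$percent_contribution,
                           importance$variable)
    out$importance <- as.numeric(imp[vars])
  }
  for (ci in 1:4) {
    cells <- which(classes$values == ci)
    if (!length(cells))
      warning("habitat class '", classes$levels[ci], "' is empty")
    mins <- maxs <- rep(NA_real_, length(vars))
    for (j in seq_along(vars)) {
      vv <- layers[[vars[j]]][cells]
      vv <- vv[is.finite(vv)]
      if (length(vv)) { mins[j] <- min(vv); maxs[j] <- max(vv) }
    }
    out[[paste0(classes$levels[ci], "_min")]] <- mins
    out[[paste0(classes$levels[ci], "_max")]] <- maxs
  }
  if (!is.null(importance))
    out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("envelope_table", class(out))
  out
}

#' Habitat class areas
#'
#' Cell counts, fractions of the finite cells, and approximate areas in
#' km2 using the spherical cell area
#' `R^2 * cellsize_rad^2 * cos(latitude of cell center)` with
#' `R = 6371 km`.
#'
#' @param classes A [classify_suitability()] result.
#' @return Data frame with columns `class`, `cells`, `fraction_pct`,
#'   `area_km2`.
#' @export
class_area <- function(classes) {
  stopifnot(inherits(classes, "habitat_map"))
  h <- classes$header
  R <- 6371
  cs_rad <- h$cellsize * pi / 180
  lat <- cell_center_lats(h) * pi / 180
  cell_km2 <- matrix(R^2 * cs_rad^2 * cos(lat), nrow = h$nrows,
                     ncol = h$ncols)
  fin <- is.finite(classes$values)
  n_fin <- sum(fin)
  out <- data.frame(class = classes$levels,
                    cells = NA_integer_, fraction_pct = NA_real_,
                    area_km2 = NA_real_, stringsAsFactors = FALSE)
  for (ci in 1:4) {
    sel <- fin & classes$values == ci
    out$cells[ci] <- sum(sel)
    out$fraction_pct[ci] <- 100 * sum(sel) / n_fin
    out$area_km2[ci] <- sum(cell_km2[sel])
  }
  out
}
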