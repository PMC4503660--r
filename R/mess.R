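#' Reference set for environmental similarity
#'
#' Stores, per variable, the sorted reference values and their range,
#' taken from the presence samples-with-data table (each reference point
#' is an occurrence record).
#'
#' @param presence Presence SWD data frame or covariate matrix.
#' @return Object of class `mess_reference`.
#' @export
mess_reference <- function(presence) {
  X <- swd_matrix(presence)
  if (nrow(X) == 0L) stop("reference set is empty")
  refs <- lapply(seq_len(ncol(X)), function(j) {
    v <- sort(X[, j])
    list(values = v, min = v[1], max = v[length(v)])
  })
  names(refs) <- colnames(X)
  structure(list(refs = refs, variables = colnames(X)),
            class = "mess_reference")
}

#' Similarity of a probe value to a reference distribution
#'
#' With `f` the percent of reference values strictly smaller than `p`:
#' \itemize{
#'   \item `f = 0`: `100 * (p - min) / (max - min)` (zero or negative)
#'   \item `0 < f <= 50`: `2 f`
#'   \item `50 < f < 100`: `2 (100 - f)`
#'   \item `f = 100`: `100 * (max - p) / (max - min)` (negative)
#' }
#' Both boundary branches carry the x100 range scaling, keeping the
#' similarity continuous at the reference extremes; `eq2_literal = TRUE`
#' drops the factor from the `f = 0` branch, reproducing a common printed
#' (asymmetric) form of the rule. Similarity is 100 at the reference
#' median and negative exactly when `p` lies outside \[min, max\].
#'
#' @param p Probe value(s), native units.
#' @param reference Sorted numeric vector of reference values (or a
#'   single-variable `mess_reference`).
#' @param eq2_literal Use the asymmetric literal form of the `f = 0`
#'   branch.
#' @return Similarity value(s), unitless, at most 100.
#' @export
similarity_one_variable <- function(p, reference, eq2_literal = FALSE) {
  if (inherits(reference, "mess_reference")) {
    stopifnot(length(reference$refs) == 1L)
    reference <- reference$refs[[1]]$values
  }
  n <- length(reference)
  if (n == 0L) stop("reference is empty")
  lo <- min(reference); hi <- max(reference)
  vapply(p, function(pi) {
    f <- 100 * sum(reference < pi) / n
    if (f == 0) {
      if (hi == lo) {
        if (pi == lo) return(100)
        warning("degenerate reference range; returning large negative similarity")
        return(-1e10)
      }
      s <- (pi - lo) / (hi - lo)
      if (!eq2_literal) s <- s * 100
      s
    } else if (f <= 50) 2 * f
    else if (f < 100) 2 * (100 - f)
    else {
      if (hi == lo) {
        warning("degenerate reference range; returning large negative similarity")
        return(-1e10)
      }
      100 * (hi - pi) / (hi - lo)
    }
  }, numeric(1))
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Per finite cell, the similarity to the reference set is computed for
#' each variable and the minimum taken; the variable attaining the
#' minimum is the cell's most-dissimilar (limiting) variable, with ties
#' broken by layer order. Negative similarity flags climates outside the
#' reference range (extrapolation).
#'
#' @param stack A [bioclim_stack()] (or named raster list) whose variables
#'   include the reference's.
#' @param reference A [mess_reference()].
#' @param eq2_literal Passed to [similarity_one_variable()].
#' @return Object of class `mess_result`: `similarity` raster, `mod`
#'   raster of most-dissimilar variable indices, and the index legend.
#' @export
mess_map <- function(stack, reference, eq2_literal = FALSE) {
  stopifnot(inherits(reference, "mess_reference"))
  layers <- as_layer_list(stack)
  header <- attr(layers, "header")
  vars <- reference$variables
  miss <- setdiff(vars, names(layers))
  if (length(miss))
    stop("stack lacks variable(s): ", paste(miss, collapse = ", "))
  fin <- Reduce(`&`, lapply(layers[vars], is.finite))
  cells <- which(fin)
  sims <- vapply(vars, function(v)
    similarity_one_variable(layers[[v]][cells],
                            reference$refs[[v]]$values,
                            eq2_literal = eq2_literal),
    numeric(length(cells)))
  if (!is.matrix(sims)) sims <- matrix(sims, nrow = length(cells))
  mins <- do.call(pmin, as.data.frame(sims))
  mod <- max.col(-sims, ties.method = "first")
  sim_m <- matrix(NA_real_, header$nrows, header$ncols)
  mod_m <- matrix(NA_real_, header$nrows, header$ncols)
  sim_m[cells] <- mins; mod_m[cells] <- mod
  structure(list(similarity = grid_raster(header, sim_m, "mess"),
                 mod = grid_raster(header, mod_m, "mod"),
                 legend = stats::setNames(seq_along(vars), vars)),
            class = "mess_result")
}

#' @export
print.mess_result <- function(x, ...) {
  v <- x$similarity$values
  fin <- v[is.finite(v)]
  cat(sprintf("MESS: %d cells, similarity range [%.2f, %.2f], %.1f%% extrapolated (negative)\n",
              length(fin), min(fin), max(fin), 100 * mean(fin < 0)))
  tab <- table(factor(x$mod$values[is.finite(x$mod$values)],
                      levels = x$legend, labels = names(x$legend)))
  cat("most-dissimilar variable counts:\n")
  print(tab)
  invisible(x)
}
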