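#' Percent contribution of each variable
#'
#' During fitting, every accepted coordinate update's decrease of the
#' regularized objective is credited to the updated feature's source
#' variable (product features split their credit half and half between
#' their two parents). Contributions are floored at zero and normalized to
#' sum to 100. This mirrors the heuristic, path-dependent "percent
#' contribution" of classic MaxEnt output; it depends on the optimization
#' path, unlike the jackknife measures.
#'
#' @param model A fitted [maxent()] model.
#' @return Named numeric vector of percentages, in the model's variable
#'   order, summing to 100 (all zeros, with a warning, if no gain accrued).
#' @export
percent_contribution <- function(model) {
  tab <- model$features$table
  vars <- model$features$variables
  acc <- stats::setNames(numeric(length(vars)), vars)
  g <- pmax(model$feature_gain, 0)
  for (i in seq_len(nrow(tab))) {
    if (tab$kind[i] == "product") {
      acc[tab$var1[i]] <- acc[tab$var1[i]] + g[i] / 2
      acc[tab$var2[i]] <- acc[tab$var2[i]] + g[i] / 2
    } else {
      acc[tab$var1[i]] <- acc[tab$var1[i]] + g[i]
    }
  }
  tot <- sum(acc)
  if (tot <= 0) {
    warning("model accrued no gain; contributions are all zero")
    return(acc)
  }
  100 * acc / tot
}

#' Jackknife variable importance
#'
#' For each variable `v`, refits the model twice — once with only `v`'s
#' features and once with every feature except `v`'s — and records the
#' regularized training gain (log cell count minus the optimal penalized
#' objective) of each fit alongside the full model's. On that scale a
#' feature subset can never out-gain its superset, so `gain_without` and
#' `gain_with_only` are bounded by the full-model gain.
#' A variable whose with-only gain is high carries useful information on
#' its own; one whose without gain is far below the full gain carries
#' information absent from the others.
#'
#' @param presence,background SWD data frames as for [maxent()].
#' @param ... Passed to [maxent()] (feature kinds, `beta`, knots, ...).
#' @return An object of class `importance_table`: a data frame with
#'   columns `variable`, `percent_contribution`, `gain_with_only`,
#'   `gain_without`, plus the full-model gain in attribute `"full_gain"`.
#' @export
jackknife_importance <- function(presence, background, ...) {
  full <- maxent(presence, background, ...)
  fs <- full$features
  vars <- fs$variables
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables")
  contrib <- percent_contribution(full)

  refit_gain <- function(keep_vars) {
    keep <- fs$table$var1 %in% keep_vars &
      (is.na(fs$table$var2) | fs$table$var2 %in% keep_vars)
    sub <- fs
    sub$table <- fs$table[keep, , drop = FALSE]
    sub$variables <- keep_vars
    sub$lo <- fs$lo[keep_vars]; sub$hi <- fs$hi[keep_vars]
    m <- tryCatch(maxent(presence, background, feature_set = sub, ...),
                  error = function(e)
                    stop("jackknife refit failed for variable set {",
                         paste(keep_vars, collapse = ","), "}: ",
                         conditionMessage(e)))
    m$reg_gain
  }
  with_only <- vapply(vars, function(v) refit_gain(v), numeric(1))
  without <- vapply(vars, function(v) refit_gain(setdiff(vars, v)),
                    numeric(1))
  out <- data.frame(variable = vars,
                    percent_contribution = as.numeric(contrib[vars]),
                    gain_with_only = with_only,
                    gain_without = without,
                    stringsAsFactors = FALSE)
  attr(out, "full_gain") <- full$reg_gain
  class(out) <- c("importance_table", class(out))
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("Variable importance (full-model gain %.4f nats)\n",
              attr(x, "full_gain")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Univariate response curve
#'
#' Refits the model with a single variable (avoiding the confounding of
#' correlated covariates) and evaluates its logistic output on an evenly
#' spaced grid spanning the variable's background range.
#'
#' @param variable Variable name.
#' @param presence,background SWD data frames.
#' @param grid_points Number of evaluation points (default 100).
#' @param ... Passed to [maxent()].
#' @return An object of class `response_curve`: data frame `(value,
#'   suitability)` with the peak location in attribute `"peak"`.
#' @export
response_curve <- function(variable, presence, background,
                           grid_points = 100L, ...) {
  Xb <- swd_matrix(background)
  if (!variable %in% colnames(Xb)) stop("unknown variable ", variable)
  if (max(Xb[, variable]) == min(Xb[, variable]))
    stop("variable ", variable, " is constant over the background")
  keep <- function(d) {
    out <- d[, c(intersect(c("species", "longitude", "latitude"), names(d)),
                 variable), drop = FALSE]
    attr(out, "cell") <- attr(d, "cell")
    out
  }
  mod <- maxent(keep(presence), keep(background), ...)
  grid <- seq(min(Xb[, variable]), max(Xb[, variable]),
              length.out = grid_points)
  nd <- matrix(grid, ncol = 1, dimnames = list(NULL, variable))
  suit <- predict(mod, nd, type = "logistic")
  out <- data.frame(value = grid, suitability = suit)
  attr(out, "peak") <- grid[which.max(suit)]
  attr(out, "variable") <- variable
  class(out) <- c("response_curve", class(out))
  out
}

#' Plot response curves of a fitted model
#'
#' Draws the univariate response curve of each requested variable, refit
#' with that variable alone as in [response_curve()].
#'
#' @param x A fitted [maxent()] model.
#' @param presence,background The SWD data frames used for the fit.
#' @param variables Variables to plot (default: all in the model).
#' @param ... Passed to [response_curve()].
#' @return The list of response curves, invisibly.
#' @export
plot.maxent <- function(x, presence, background,
                        variables = x$features$variables, ...) {
  k <- length(variables)
  mfrow <- grDevices::n2mfrow(k)
  op <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  curves <- lapply(variables, function(v) {
    rc <- response_curve(v, presence, background, ...)
    graphics::plot(rc$value, rc$suitability, type = "l", ylim = c(0, 1),
                   xlab = v, ylab = "suitability", main = v)
    rc
  })
  invisible(curves)
}
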