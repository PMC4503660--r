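# Independent brute-force oracles used across the suite. These are written
# as direct transcriptions of the definitions, never calling the package's
# own computational paths.

# AUC by exhaustive pair counting with half credit for ties
bf_auc <- function(pres, bg) {
  s <- 0
  for (x in pres) for (y in bg)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pres) * length(bg))
}

# scalar similarity rule, transcribed case by case
bf_similarity <- function(p, ref, literal = FALSE) {
  n <- length(ref)
  f <- 100 * sum(ref < p) / n
  mn <- min(ref); mx <- max(ref)
  if (f == 0) {
    v <- (p - mn) / (mx - mn)
    if (!literal) v <- 100 * v
    v
  } else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (mx - p) / (mx - mn)
}

# regularized maxent objective evaluated directly from its definition
bf_objective <- function(cvec, Fcell, Fp, lambda) {
  eta <- as.numeric(Fcell %*% cvec)
  m <- max(eta)
  (m + log(sum(exp(eta - m)))) - mean(Fp %*% cvec) + sum(lambda * abs(cvec))
}

# dense grid search over coefficients with iterative zooming; feasible for
# up to 3 features
bf_grid_search <- function(Fcell, Fp, lambda, lo = -12, hi = 12,
                           n_grid = 13L, levels = 7L) {
  J <- ncol(Fcell)
  center <- rep(0, J); width <- hi - lo
  best <- bf_objective(center, Fcell, Fp, lambda)
  for (lev in seq_len(levels)) {
    axes <- lapply(seq_len(J), function(j)
      seq(center[j] - width / 2, center[j] + width / 2,
          length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1L, bf_objective, Fcell = Fcell, Fp = Fp,
                  lambda = lambda)
    i <- which.min(vals)
    center <- grid[i, ]; best <- vals[i]
    width <- width * 2 / (n_grid - 1)   # new span = 2 grid steps
  }
  list(coef = center, objective = best)
}

# brute-force cell assignment: scan every cell rectangle (half-open, edges
# belong east/north)
bf_cell <- function(header, lon, lat) {
  cs <- header$cellsize
  for (col in seq_len(header$ncols)) {
    for (row_s in seq_len(header$nrows)) {
      x0 <- header$xll + (col - 1) * cs
      y0 <- header$yll + (row_s - 1) * cs
      if (lon >= x0 && lon < x0 + cs && lat >= y0 && lat < y0 + cs)
        return(c(row = header$nrows - row_s + 1L, col = col))
    }
  }
  c(row = NA_integer_, col = NA_integer_)
}

# trapezoidal area under an roc curve
trapezoid_area <- function(curve)
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
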