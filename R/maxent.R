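#' Sample background cells from a bioclimatic stack
#'
#' Draws `n` cells uniformly without replacement from the cells that are
#' finite in every layer (all of them if fewer than `n` exist). Sampling
#' from all finite cells — including any that hold occurrences — follows
#' the usual background convention for presence-background models.
#'
#' @param stack A [bioclim_stack()] or named list of compatible rasters.
#' @param n Number of background points (default 10000).
#' @param seed Integer seed; the draw is reproducible given `seed`.
#' @return An SWD data frame (`species = "background"`) with attribute
#'   `"cell"` holding the sampled cell ids.
#' @export
sample_background <- function(stack, n = 10000L, seed = 1L) {
  layers <- as_layer_list(stack)
  header <- attr(layers, "header")
  fin <- Reduce(`&`, lapply(layers, is.finite))
  cells <- which(fin)   # column-major cell ids
  if (!length(cells)) stop("stack has no finite cells")
  if (length(cells) > n) {
    rng <- local_rng(seed)
    cells <- sort(cells[rng$sample_int(length(cells), n)])
  }
  rc <- arrayInd(cells, c(header$nrows, header$ncols))
  lons <- cell_center_lons(header)[rc[, 2L]]
  lats <- cell_center_lats(header)[rc[, 1L]]
  vals <- lapply(layers, function(m) m[cells])
  swd <- data.frame(species = "background", longitude = lons,
                    latitude = lats, vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(swd, "cell") <- as.integer(cells)
  swd
}

# run expr-free reproducible RNG without touching the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    res <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    res
  }
  list(
    sample_int = function(n, k, replace = FALSE, prob = NULL)
      with_state(function() sample.int(n, k, replace = replace, prob = prob)),
    runif = function(k) with_state(function() stats::runif(k)),
    rnorm = function(k, sd = 1) with_state(function() stats::rnorm(k, sd = sd))
  )
}

#' Fit a regularized maximum-entropy presence-background model
#'
#' Estimates the Gibbs distribution `P(x) = exp(sum_j c_j f_j(x)) / Z` over
#' the fitting cell set (background cells plus any presence cells not
#' already among them), choosing coefficients `c` to maximize the mean
#' presence log-probability minus an L1 penalty
#' `sum_j beta * sd_j / sqrt(n_presence) * |c_j|`, where `sd_j` is feature
#' `j`'s background standard deviation. The optimizer is cyclic coordinate
#' descent with proximal-Newton steps and backtracking; fitting stops when a
#' sweep improves the regularized objective by less than `tol` or after
#' `max_iter` sweeps. The objective decrease of every accepted coordinate
#' update is credited to that feature's source variable(s), which is what
#' percent-contribution importance later reports.
#'
#' @param presence SWD data frame of presence records (covariate columns
#'   plus optional `species`/`longitude`/`latitude`).
#' @param background SWD data frame of background samples, same covariates.
#' @param features Feature kinds to enable, or a prebuilt
#'   [build_features()] object via `feature_set`.
#' @param beta Regularization multiplier; scalar, or named per-kind vector
#'   (e.g. `c(linear = 1, hinge = 0.5)`).
#' @param n_knots Threshold/hinge knots per variable.
#' @param tol Convergence threshold on the regularized objective
#'   (default 1e-5).
#' @param max_iter Maximum number of sweeps (default 500).
#' @param feature_set Optional `maxent_features` object overriding
#'   `features`/`n_knots`.
#' @return An object of class `maxent`; see Details. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`, `simulate`.
#' @details The fitted object carries the feature set with its background
#'   normalization, named coefficients, `logZ` and entropy `H` of the raw
#'   distribution over the fitting cell set, the regularized training gain,
#'   the per-feature gain-attribution trace, and convergence metadata.
#' @seealso [predict.maxent()], [training_gain()], [cross_validate()]
#' @export
maxent <- function(presence, background,
                   features = c("linear", "quadratic", "product",
                                "threshold", "hinge"),
                   beta = 1, n_knots = 10L, tol = 1e-5, max_iter = 500L,
                   feature_set = NULL) {
  if (is.null(feature_set))
    feature_set <- build_features(background, kinds = features,
                                  n_knots = n_knots)
  if (nrow(swd_matrix(presence)) < 1L) stop("need at least one presence")
  Fb <- evaluate_features(feature_set, background)
  Fp <- evaluate_features(feature_set, presence)

  # cell set = background union presence cells
  bc <- attr(background, "cell"); pc <- attr(presence, "cell")
  if (!is.null(bc) && !is.null(pc)) {
    extra <- !(pc %in% bc) & !duplicated(pc)
    Fcell <- rbind(Fb, Fp[extra, , drop = FALSE])
  } else {
    Fcell <- rbind(Fb, Fp)
  }

  m <- nrow(Fp)
  sdj <- apply(Fb, 2L, pop_sd)
  tab <- feature_set$table
  betaj <- if (length(beta) == 1L && is.null(names(beta)))
    rep(as.numeric(beta), nrow(tab))
  else {
    if (!all(tab$kind %in% names(beta)))
      stop("beta must be scalar or named for every enabled feature kind")
    as.numeric(beta[tab$kind])
  }
  lambda <- betaj * pmax(sdj, 1e-6) / sqrt(m)

  if (all(colSums(Fp > 0) == 0))
    warning("presence values have no overlap with feature support")

  fit <- .maxent_cd(Fcell, Fp, lambda, tol, as.integer(max_iter))
  coefv <- as.numeric(fit$coef)
  names(coefv) <- colnames(Fb)
  eta_p <- as.numeric(Fp %*% coefv)
  n_cells <- nrow(Fcell)
  gain <- log(n_cells) + mean(eta_p) - fit$logZ
  # regularized gain subtracts the L1 penalty (log N minus the optimal
  # objective); it is exactly monotone in the enabled feature set
  reg_gain <- log(n_cells) - fit$objective

  structure(list(features = feature_set,
                 coef = coefv,
                 lambda = lambda,
                 logZ = fit$logZ,
                 entropy = fit$entropy,
                 n_cells = n_cells,
                 n_presence = m,
                 gain = gain,
                 reg_gain = reg_gain,
                 objective = fit$objective,
                 iterations = fit$iterations,
                 converged = fit$converged,
                 feature_gain = as.numeric(fit$feature_gain),
                 beta = beta, tol = tol, max_iter = max_iter,
                 call = match.call()),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat("Maximum-entropy presence-background model\n")
  cat(sprintf("  %d presences, %d cells, %d features (%d active)\n",
              x$n_presence, x$n_cells, length(x$coef),
              sum(x$coef != 0)))
  cat(sprintf("  regularized training gain: %.4f nats;  entropy H = %.4f\n",
              x$gain, x$entropy))
  cat(sprintf("  %s after %d iteration sweep(s)\n",
              if (x$converged) "converged" else "iteration limit reached",
              x$iterations))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$coef

#' @export
summary.maxent <- function(object, ...) {
  contrib <- percent_contribution(object)
  active <- object$coef[object$coef != 0]
  structure(list(model = object, contrib = contrib,
                 active = active[order(-abs(active))]),
            class = "summary.maxent")
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat("\nPercent contribution by variable:\n")
  print(round(x$contrib, 2))
  cat("\nLargest coefficients:\n")
  print(round(utils::head(x$active, 10), 4))
  invisible(x)
}

#' Regularized training gain of a fitted model
#'
#' Gain is the log of the fitting cell-set size minus the log loss (the
#' mean negative log raw probability of the presence samples); the uniform
#' (null) model has gain 0.
#'
#' @param model A fitted [maxent()] model.
#' @param presence SWD data frame of presences to score.
#' @param cellset_size Cell-set size `N`; defaults to the model's own.
#' @return Gain in nats.
#' @export
training_gain <- function(model, presence, cellset_size = model$n_cells) {
  Fp <- evaluate_features(model$features, presence)
  eta <- as.numeric(Fp %*% model$coef)
  log(cellset_size) + mean(eta) - model$logZ
}

#' Predict from a maximum-entropy model
#'
#' @param object A fitted [maxent()] model.
#' @param newdata A [bioclim_stack()] (returns a suitability raster) or a
#'   data frame / matrix of covariates (returns a vector).
#' @param type `"logistic"` (default): `e^H * raw / (1 + e^H * raw)`, a 0-1
#'   suitability index with `H` the entropy of the fitted raw distribution;
#'   `"raw"`: `exp(eta - logZ)` using the model's stored normalizer;
#'   `"link"`: the linear predictor `eta`.
#' @param ... Unused.
#' @return Numeric vector, or a `suitability_map` raster when `newdata` is
#'   a stack.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "bioclim_stack") ||
      (is.list(newdata) && inherits(newdata[[1]], "grid_raster"))) {
    layers <- as_layer_list(newdata)
    header <- attr(layers, "header")
    fin <- Reduce(`&`, lapply(layers[object$features$variables], is.finite))
    cells <- which(fin)
    X <- do.call(cbind, lapply(layers[object$features$variables],
                               function(m) m[cells]))
    colnames(X) <- object$features$variables
    v <- predict_vector(object, X, type)
    out <- matrix(NA_real_, header$nrows, header$ncols)
    out[cells] <- v
    r <- grid_raster(header, out, name = type)
    class(r) <- c("suitability_map", class(r))
    attr(r, "output_kind") <- type
    return(r)
  }
  X <- swd_matrix(newdata)
  predict_vector(object, X, type)
}

predict_vector <- function(object, X, type) {
  Fm <- evaluate_features(object$features, X)
  eta <- as.numeric(Fm %*% object$coef)
  switch(type,
         link = eta,
         raw = exp(eta - object$logZ),
         logistic = {
           r <- exp(object$entropy + eta - object$logZ)
           r / (1 + r)
         })
}

#' Simulate occurrence records from a fitted model
#'
#' Draws cells from the model's raw (Gibbs) distribution evaluated over a
#' stack and places points at cell centers — the sampling process the model
#' assumes generated the presences.
#'
#' @param object A fitted [maxent()] model.
#' @param nsim Number of replicate occurrence sets.
#' @param seed Integer seed.
#' @param stack A [bioclim_stack()] to simulate over.
#' @param n Points per replicate.
#' @param ... Unused.
#' @return A list of `nsim` occurrence data frames.
#' @export
simulate.maxent <- function(object, nsim = 1, seed = 1L, stack, n = 100L,
                            ...) {
  raw <- predict(object, stack, type = "raw")
  header <- raw$header
  cells <- which(is.finite(raw$values))
  p <- raw$values[cells]; p <- p / sum(p)
  rng <- local_rng(seed)
  lapply(seq_len(nsim), function(i) {
    draw <- cells[rng$sample_int(length(cells), n, replace = TRUE, prob = p)]
    rc <- arrayInd(draw, c(header$nrows, header$ncols))
    data.frame(species = "simulated",
               longitude = cell_center_lons(header)[rc[, 2L]],
               latitude = cell_center_lats(header)[rc[, 1L]],
               stringsAsFactors = FALSE)
  })
}
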