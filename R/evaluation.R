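#' Presence-background ROC curve and AUC
#'
#' AUC is computed exactly from rank statistics as the probability that a
#' random presence outscores a random background point, with half credit
#' for ties (the Mann-Whitney form); it equals the trapezoidal area under
#' the ROC curve built over the distinct score thresholds.
#'
#' @param presence_scores,background_scores Numeric score vectors
#'   (non-empty). Any strictly increasing rescaling of the scores leaves
#'   the result unchanged.
#' @return An object of class `roc_result`: `auc`, the curve as a data
#'   frame of `(fpr, tpr)` from (0,0) to (1,1), and the class sizes.
#' @export
roc_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("score vectors must be non-empty")
  if (anyNA(presence_scores) || anyNA(background_scores))
    stop("scores must not contain NA")
  all_sc <- c(presence_scores, background_scores)
  r <- rank(all_sc)                       # midranks: ties get half credit
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)

  th <- sort(unique(all_sc), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(presence_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(background_scores >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- curve[!duplicated(curve), , drop = FALSE]
  rownames(curve) <- NULL
  structure(list(auc = auc, curve = curve,
                 n_presence = np, n_background = nb),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%s) over %d presences vs %d background\n",
              x$auc, classify_auc(x$auc), x$n_presence, x$n_background))
  invisible(x)
}

#' Label an AUC value on the conventional five-band scale
#'
#' Bands are half-open with the top band closed:
#' poor \[0.5, 0.6), fair \[0.6, 0.7), good \[0.7, 0.8),
#' very good \[0.8, 0.9), excellent \[0.9, 1\]; values below 0.5 are
#' "worse than random".
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return Character label(s).
#' @export
classify_auc <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  vapply(auc, function(a) {
    if (a < 0.5) "worse than random"
    else if (a < 0.6) "poor"
    else if (a < 0.7) "fair"
    else if (a < 0.8) "good"
    else if (a < 0.9) "very good"
    else "excellent"
  }, character(1))
}

#' Assign records to k cross-validation folds
#'
#' A seeded random permutation is dealt round-robin, so fold sizes differ
#' by at most one.
#'
#' @param n_records Number of records (or a data frame, whose row count is
#'   used).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..k, one per record.
#' @export
kfold_split <- function(n_records, k = 10L, seed = 1L) {
  if (is.data.frame(n_records)) n_records <- nrow(n_records)
  if (k < 2L) stop("k must be at least 2")
  if (k > n_records) stop("k exceeds the number of records")
  rng <- local_rng(seed)
  perm <- rng$sample_int(n_records, n_records)
  fold <- integer(n_records)
  fold[perm] <- rep_len(seq_len(k), n_records)
  fold
}

#' AUC-weighted average of suitability maps
#'
#' Cell-wise weighted mean `sum(w_i m_i) / sum(w_i)`; NoData wherever any
#' input map is NoData.
#'
#' @param maps List of compatible `suitability_map` / [grid_raster()]
#'   objects.
#' @param weights Positive weights, one per map (e.g. per-fold test AUC).
#' @return A `suitability_map`.
#' @export
auc_weighted_ensemble <- function(maps, weights) {
  if (length(maps) != length(weights)) stop("one weight per map required")
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive")
  h <- maps[[1]]$header
  for (m in maps) if (!headers_compatible(m$header, h))
    stop("maps have incompatible headers")
  acc <- matrix(0, h$nrows, h$ncols)
  for (i in seq_along(maps)) acc <- acc + weights[i] * maps[[i]]$values
  vals <- acc / sum(weights)
  r <- grid_raster(h, vals, name = "ensemble")
  class(r) <- c("suitability_map", class(r))
  attr(r, "output_kind") <- attr(maps[[1]], "output_kind") %||% "logistic"
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' k-fold cross-validation of a maximum-entropy model
#'
#' Splits the presences into `k` folds; for each fold fits on the other
#' k-1 folds, scores the held-out presences and the shared background
#' sample, and records training and test AUC. The per-fold logistic maps
#' are combined by [auc_weighted_ensemble()] with the test AUCs as weights.
#'
#' @param presence Presence SWD data frame (from [extract_values()]).
#' @param stack The [bioclim_stack()] used for background sampling,
#'   prediction and the ensemble map.
#' @param k Number of folds (default 10).
#' @param background Optional precomputed background SWD; otherwise
#'   `n_background` cells are sampled from the stack.
#' @param n_background Background sample size (default 10000).
#' @param seed Integer seed controlling the fold split (and background
#'   sampling when `background` is not supplied).
#' @param ... Passed to [maxent()] (feature kinds, `beta`, `tol`, ...).
#' @return An object of class `maxent_cv`: fold assignment, per-fold
#'   models and train/test AUCs, their mean and coefficient of variation
#'   (sd/mean x 100), and the ensemble `suitability_map`.
#' @export
cross_validate <- function(presence, stack, k = 10L, background = NULL,
                           n_background = 10000L, seed = 1L, ...) {
  if (is.null(background))
    background <- sample_background(stack, n_background, seed = seed + 1L)
  fold <- kfold_split(nrow(presence), k, seed = seed)
  models <- vector("list", k)
  maps <- vector("list", k)
  train_auc <- test_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- presence[fold != f, , drop = FALSE]
    attr(tr, "cell") <- attr(presence, "cell")[fold != f]
    te <- presence[fold == f, , drop = FALSE]
    mod <- maxent(tr, background, ...)
    bg_sc <- predict(mod, background, type = "logistic")
    train_auc[f] <- roc_auc(predict(mod, tr, type = "logistic"), bg_sc)$auc
    test_auc[f] <- roc_auc(predict(mod, te, type = "logistic"), bg_sc)$auc
    models[[f]] <- mod
    maps[[f]] <- predict(mod, stack, type = "logistic")
  }
  ens <- auc_weighted_ensemble(maps, test_auc)
  structure(list(fold = fold, models = models,
                 train_auc = train_auc, test_auc = test_auc,
                 mean_test_auc = mean(test_auc),
                 cv_test_auc = 100 * stats::sd(test_auc) / mean(test_auc),
                 ensemble = ens, k = k, seed = seed),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated maximum-entropy model\n", x$k))
  tab <- data.frame(fold = seq_len(x$k),
                    train_auc = round(x$train_auc, 4),
                    test_auc = round(x$test_auc, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("mean test AUC %.4f (%s), CV %.1f%%\n", x$mean_test_auc,
              classify_auc(x$mean_test_auc), x$cv_test_auc))
  invisible(x)
}
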