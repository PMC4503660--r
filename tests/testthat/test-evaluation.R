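test_that("AUC reproduces the worked pair-counting example and bounds", {
  r <- roc_auc(c(0.9, 0.4), c(0.5, 0.1, 0.4))
  expect_equal(r$auc, 4.5 / 6)
  expect_equal(roc_auc(c(5, 6), c(1, 2))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("AUC equals brute-force pair counting on random score sets", {
  set.seed(11)
  for (i in 1:60) {
    np <- sample(1:12, 1); nb <- sample(1:12, 1)
    # ties are likely: scores drawn from a small discrete set
    p <- sample(seq(0, 1, 0.1), np, replace = TRUE)
    b <- sample(seq(0, 1, 0.1), nb, replace = TRUE)
    expect_equal(roc_auc(p, b)$auc, bf_auc(p, b), tolerance = 1e-12)
  }
})

test_that("AUC is a rank statistic with the expected symmetries", {
  set.seed(12)
  p <- runif(25); b <- runif(40)
  a <- roc_auc(p, b)$auc
  # invariant under strictly increasing transforms
  expect_equal(roc_auc(exp(3 * p), exp(3 * b))$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(p), qlogis(b))$auc, a, tolerance = 1e-12)
  # swapping the classes complements the area
  expect_equal(roc_auc(b, p)$auc, 1 - a, tolerance = 1e-12)
})

test_that("the ROC curve spans (0,0)-(1,1) and integrates to the AUC", {
  set.seed(13)
  for (i in 1:10) {
    p <- sample(seq(0, 1, 0.05), 15, replace = TRUE)
    b <- sample(seq(0, 1, 0.05), 25, replace = TRUE)
    r <- roc_auc(p, b)
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(!is.unsorted(r$curve$fpr) && !is.unsorted(r$curve$tpr))
    expect_equal(trapezoid_area(r$curve), r$auc, tolerance = 1e-9)
  }
})

test_that("AUC bands use half-open intervals with a closed top", {
  expect_equal(classify_auc(0.93), "excellent")
  expect_equal(classify_auc(0.65), "fair")
  expect_equal(classify_auc(0.70), "good")
  expect_equal(classify_auc(c(0.5, 0.6, 0.8, 0.9, 1.0)),
               c("poor", "fair", "very good", "excellent", "excellent"))
  expect_equal(classify_auc(0.49), "worse than random")
})

test_that("k-fold splits partition records into near-equal folds", {
  f <- kfold_split(97, k = 10, seed = 5)
  expect_length(f, 97L)
  sz <- as.integer(table(f))
  expect_equal(sort(sz), c(9, 9, 9, rep(10, 7)))
  expect_identical(f, kfold_split(97, k = 10, seed = 5))
  expect_false(identical(f, kfold_split(97, k = 10, seed = 6)))
  expect_equal(as.integer(table(kfold_split(4, 2, seed = 1))), c(2L, 2L))
  expect_error(kfold_split(5, k = 6), "exceeds")
  expect_error(kfold_split(5, k = 1), "at least 2")
})

test_that("AUC-weighted ensembling is the weighted cell-wise mean", {
  h <- grid_header(2, 1, 0, 0, 1)
  mk <- function(v) {
    r <- grid_raster(h, matrix(v, 1, 2))
    class(r) <- c("suitability_map", class(r)); r
  }
  e <- auc_weighted_ensemble(list(mk(c(0.2, 0.8)), mk(c(0.4, 0.6))),
                             c(0.9, 0.6))
  expect_equal(as.vector(e$values), c(0.28, 0.72))
  # equal weights give the arithmetic mean; a single map is unchanged
  e2 <- auc_weighted_ensemble(list(mk(c(0.2, 0.8)), mk(c(0.4, 0.6))),
                              c(1, 1))
  expect_equal(as.vector(e2$values), c(0.3, 0.7))
  expect_equal(auc_weighted_ensemble(list(mk(c(0.1, 0.9))), 0.7)$values,
               mk(c(0.1, 0.9))$values)
  # output bounded by the inputs; NoData propagates
  m3 <- mk(c(NA, 0.5))
  e3 <- auc_weighted_ensemble(list(mk(c(0.2, 0.8)), m3), c(1, 2))
  expect_true(is.na(e3$values[1, 1]))
  expect_error(auc_weighted_ensemble(list(mk(c(0, 1))), c(1, 2)),
               "one weight per map")
  expect_error(auc_weighted_ensemble(list(mk(c(0, 1))), -1), "positive")
})

test_that("cross-validation recovers strong synthetic structure", {
  sc <- small_scene()
  cv <- cross_validate(sc$presence, sc$fx$stack, k = 5,
                       background = sc$background, seed = 2,
                       features = c("linear", "quadratic", "hinge"),
                       n_knots = 5L)
  expect_length(cv$test_auc, 5L)
  expect_true(all(table(cv$fold) >= floor(nrow(sc$presence) / 5)))
  expect_true(cv$mean_test_auc > 0.8)
  # ensemble values bounded by the per-fold map extremes cell-wise
  fin <- which(is.finite(cv$ensemble$values))
  maps <- lapply(seq_len(5), function(i)
    predict(cv$models[[i]], sc$fx$stack, type = "logistic")$values[fin])
  mn <- Reduce(pmin, maps); mx <- Reduce(pmax, maps)
  ens <- cv$ensemble$values[fin]
  expect_true(all(ens >= mn - 1e-12 & ens <= mx + 1e-12))
  expect_true(all(ens >= 0 & ens <= 1))
})
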