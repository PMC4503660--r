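# small presence/background tables on one variable with clear separation
toy_bg <- data.frame(v = seq(0, 1, length.out = 21))
toy_pres <- data.frame(v = c(0.8, 0.9, 0.95, 1.0, 0.85))

test_that("the null model is uniform with zero gain and unit mass", {
  mod <- maxent(toy_pres, toy_bg, features = "linear", max_iter = 0L)
  expect_equal(unname(coef(mod)), 0)
  expect_equal(mod$gain, 0)
  raw <- predict(mod, toy_bg, type = "raw")
  expect_equal(raw, rep(1 / mod$n_cells, nrow(toy_bg)))
  expect_equal(mod$entropy, log(mod$n_cells))
  # null logistic output is exactly 0.5 everywhere
  expect_equal(predict(mod, toy_bg, type = "logistic"),
               rep(0.5, nrow(toy_bg)))
})

test_that("raw probabilities over the fitting cell set sum to one", {
  sc <- small_scene()
  mod <- maxent(sc$presence, sc$background,
                features = c("linear", "quadratic", "hinge"), n_knots = 5L)
  Fb <- evaluate_features(mod$features, sc$background)
  pc <- attr(sc$presence, "cell"); bc <- attr(sc$background, "cell")
  extra <- !(pc %in% bc) & !duplicated(pc)
  Fp <- evaluate_features(mod$features, sc$presence)
  Fcell <- rbind(Fb, Fp[extra, , drop = FALSE])
  raw <- exp(as.numeric(Fcell %*% coef(mod)) - mod$logZ)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_true(mod$entropy >= 0 && mod$entropy <= log(mod$n_cells) + 1e-12)
})

test_that("a single binary feature matches 1-D numeric optimization", {
  bg <- data.frame(v = rep(c(0, 1), c(30, 10)))
  pres <- data.frame(v = rep(c(1, 0), c(6, 2)))
  for (b in c(0, 1, 5)) {
    fs <- build_features(bg, kinds = "threshold", n_knots = 1L)
    mod <- maxent(pres, bg, feature_set = fs, beta = b, tol = 1e-10,
                  max_iter = 2000L)
    Fc <- evaluate_features(fs, bg)
    Fp <- evaluate_features(fs, pres)
    oracle <- optimize(function(c1)
      bf_objective(c1, rbind(Fc, Fp), Fp, mod$lambda), c(-30, 30),
      tol = 1e-12)
    expect_equal(unname(coef(mod)), oracle$minimum, tolerance = 1e-6)
  }
})

test_that("raw prediction on a four-cell toy equals hand arithmetic", {
  bg <- data.frame(v = c(0, 1, 2, 3))
  pres <- data.frame(v = c(2, 3, 3))
  attr(bg, "cell") <- 1:4; attr(pres, "cell") <- c(3L, 4L, 4L)
  mod <- maxent(pres, bg, features = "linear")
  cf <- unname(coef(mod))
  z <- c(0, 1, 2, 3) / 3                   # normalized feature values
  expect_equal(mod$n_cells, 4L)
  hand <- exp(cf * z) / sum(exp(cf * z))
  expect_equal(predict(mod, bg, type = "raw"), hand, tolerance = 1e-12)
  # gain by hand: log N - mean(-log P) over the presences
  hand_gain <- log(4) + mean(log(hand[c(3, 4, 4)]))
  expect_equal(training_gain(mod, pres), hand_gain, tolerance = 1e-12)
  expect_equal(mod$gain, hand_gain, tolerance = 1e-12)
})

test_that("logistic output is the entropy-scaled transform of raw", {
  sc <- small_scene()
  mod <- maxent(sc$presence, sc$background, features = c("linear", "hinge"),
                n_knots = 5L)
  raw <- predict(mod, sc$background, type = "raw")
  lgs <- predict(mod, sc$background, type = "logistic")
  expect_equal(lgs, exp(mod$entropy) * raw / (1 + exp(mod$entropy) * raw),
               tolerance = 1e-12)
  expect_true(all(lgs > 0 & lgs < 1))
  # strictly increasing in raw: rankings coincide
  expect_equal(order(raw), order(lgs))
  # fixed point: raw = exp(-H) maps to exactly 0.5
  r0 <- exp(-mod$entropy)
  expect_equal(exp(mod$entropy) * r0 / (1 + exp(mod$entropy) * r0), 0.5)
})

test_that("fits are deterministic and invariant to presence row order", {
  sc <- small_scene()
  m1 <- maxent(sc$presence, sc$background, features = c("linear", "hinge"),
               n_knots = 5L)
  m2 <- maxent(sc$presence, sc$background, features = c("linear", "hinge"),
               n_knots = 5L)
  expect_identical(coef(m1), coef(m2))
  perm <- rev(seq_len(nrow(sc$presence)))
  pres_r <- sc$presence[perm, ]
  attr(pres_r, "cell") <- attr(sc$presence, "cell")[perm]
  m3 <- maxent(pres_r, sc$background, features = c("linear", "hinge"),
               n_knots = 5L)
  expect_equal(coef(m1), coef(m3), tolerance = 1e-10)
})

test_that("enlarging the feature set cannot worsen the optimum", {
  sc <- small_scene()
  kinds <- list(c("linear"),
                c("linear", "quadratic"),
                c("linear", "quadratic", "hinge"),
                c("linear", "quadratic", "hinge", "threshold", "product"))
  objs <- sapply(kinds, function(k)
    maxent(sc$presence, sc$background, features = k, n_knots = 5L,
           tol = 1e-8, max_iter = 2000L)$objective)
  expect_true(all(diff(objs) <= 1e-4))
  gains <- sapply(kinds, function(k)
    maxent(sc$presence, sc$background, features = k, n_knots = 5L,
           tol = 1e-8, max_iter = 2000L)$gain)
  expect_true(all(gains >= -1e-8))
})

test_that("prediction on a stack returns a suitability raster", {
  sc <- small_scene()
  mod <- maxent(sc$presence, sc$background, features = "linear")
  map <- predict(mod, sc$fx$stack, type = "logistic")
  expect_s3_class(map, "suitability_map")
  fin <- map$values[is.finite(map$values)]
  expect_true(all(fin >= 0 & fin <= 1))
  expect_error(predict(mod, data.frame(bogus = 1:3)), "lacks variable")
})

test_that("simulated occurrences come from the fitted distribution", {
  sc <- small_scene()
  mod <- maxent(sc$presence, sc$background, features = "linear")
  sims <- simulate(mod, nsim = 2, seed = 9, stack = sc$fx$stack, n = 50)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), 50L)
  sims2 <- simulate(mod, nsim = 2, seed = 9, stack = sc$fx$stack, n = 50)
  expect_identical(sims, sims2)
})

test_that("background sampling is seeded, distinct and exhaustive", {
  st <- small_scene()$fx$stack
  b1 <- sample_background(st, 100, seed = 3)
  b2 <- sample_background(st, 100, seed = 3)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 100L)
  expect_false(any(duplicated(attr(b1, "cell"))))
  ball <- sample_background(st, 10^6, seed = 3)
  fin <- sum(Reduce(`&`, lapply(st$layers, is.finite)))
  expect_equal(nrow(ball), fin)
})
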