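tm_example <- c(-5, -3, 0, 5, 10, 15, 20, 22, 18, 12, 5, -2)
pr_example <- c(2, 4, 10, 30, 60, 120, 150, 130, 80, 40, 10, 4)

test_that("temperature summaries reproduce hand-derived values", {
  s <- temperature_summaries(rep(10, 12), rep(15, 12), rep(5, 12))
  expect_equal(unname(s), c(10, 10, 10, 10))
  s2 <- temperature_summaries(rep(10, 12), rep(15, 12), rep(5, 12),
                              art_mode = "footnote_literal")
  expect_equal(s2[["ART"]], 10)

  s3 <- temperature_summaries(tm_example, tm_example + 5, tm_example - 5)
  expect_equal(s3[["AMT"]], 97 / 12)
  expect_equal(s3[["MTWM"]], 22)
  expect_equal(s3[["MTCM"]], -5)
  expect_equal(s3[["ART"]], 27 - (-10))   # max tmax - min tmin

  expect_true(all(is.na(
    temperature_summaries(c(tm_example[-1], NA), tm_example + 5,
                          tm_example - 5))))
})

test_that("precipitation summaries and seasonality match the definitions", {
  s <- precipitation_summaries(rep(50, 12))
  expect_equal(unname(s), c(600, 50, 50, 0))

  s2 <- precipitation_summaries(pr_example)
  expect_equal(s2[["AP"]], 640)
  expect_equal(s2[["PWM"]], 150)
  expect_equal(s2[["PDM"]], 2)
  m <- mean(pr_example)
  expect_equal(s2[["PSD"]], 100 * sqrt(mean((pr_example - m)^2)) / m)
  s3 <- precipitation_summaries(pr_example, psd_mode = "worldclim_cv")
  expect_equal(s3[["PSD"]], 100 * sqrt(mean((pr_example - m)^2)) / (1 + m))

  z <- precipitation_summaries(rep(0, 12))
  expect_equal(z[["AP"]], 0)
  expect_equal(z[["PSD"]], 0)
  expect_error(precipitation_summaries(c(-1, rep(5, 11))), "negative")
})

test_that("thermal indices follow the warmth/coldness definitions", {
  s <- thermal_indices(rep(10, 12))
  expect_equal(unname(s), c(10, 60, 0))

  s2 <- thermal_indices(tm_example)
  expect_equal(s2[["WI"]], 67)
  expect_equal(s2[["CI"]], -30)
  expect_equal(s2[["ABT"]], 107 / 12)
  expect_equal(thermal_indices(tm_example,
                               abt_mode = "footnote_literal")[["ABT"]],
               107 / 12)

  # months at exactly 5 degC contribute to neither index
  s3 <- thermal_indices(rep(5, 12))
  expect_equal(s3[["WI"]], 0)
  expect_equal(s3[["CI"]], 0)
  # all months above 5 -> CI = 0
  expect_equal(thermal_indices(rep(8, 12))[["CI"]], 0)
  # holdridge clamp keeps ABT in [0, 30]
  expect_equal(thermal_indices(rep(-20, 12))[["ABT"]], 0)
  expect_equal(thermal_indices(rep(40, 12))[["ABT"]], 30)
  # the literal footnote excludes months at or beyond the bounds entirely
  expect_equal(thermal_indices(rep(40, 12),
                               abt_mode = "footnote_literal")[["ABT"]], 0)
})

test_that("moisture ratios and their degenerate denominators", {
  expect_equal(moisture_indices(10, 589.3, 60)[["PER"]], 1.0)
  expect_equal(moisture_indices(10, 600, 60)[["HI"]], 10)
  expect_true(is.na(moisture_indices(10, 0, 60)[["PER"]]))
  expect_true(is.na(moisture_indices(10, 600, 0)[["HI"]]))
})

test_that("grid derivation equals the scalar calculators cell by cell", {
  set.seed(7)
  nr <- 5L; nc <- 5L
  h <- grid_header(nc, nr, 100, 30, 0.5)
  tmean <- lapply(1:12, function(m)
    matrix(rnorm(nr * nc, 10 + 10 * cos(2 * pi * (m - 7) / 12), 4), nr, nc))
  tmax <- lapply(tmean, function(x) x + runif(1, 2, 6))
  tmin <- lapply(tmean, function(x) x - runif(1, 2, 6))
  prec <- lapply(1:12, function(m)
    matrix(runif(nr * nc, 0, 120), nr, nc))
  mc <- monthly_climate(h, tmean, tmax, tmin, prec)

  for (modes in list(
    list(art = "annual_range", psd = "plain_cv", abt = "holdridge_clamp"),
    list(art = "footnote_literal", psd = "worldclim_cv",
         abt = "footnote_literal"))) {
    st <- derive_bioclim(mc, modes$art, modes$psd, modes$abt)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      tv <- sapply(tmean, `[`, r, cc); txv <- sapply(tmax, `[`, r, cc)
      tnv <- sapply(tmin, `[`, r, cc); pv <- sapply(prec, `[`, r, cc)
      ts <- temperature_summaries(tv, txv, tnv, modes$art)
      ps <- precipitation_summaries(pv, modes$psd)
      th <- thermal_indices(tv, modes$abt)
      mo <- moisture_indices(th[["ABT"]], ps[["AP"]], th[["WI"]])
      want <- c(ts, ps, th, mo)[bioclim_layer_names()]
      got <- sapply(st$layers, `[`, r, cc)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("layer invariants hold and NoData propagates everywhere", {
  fx <- small_scene()$fx
  st <- fx$stack$layers
  fin <- Reduce(`&`, lapply(st, is.finite))
  expect_true(all(st$PDM[fin] <= st$PWM[fin]))
  expect_true(all(st$MTCM[fin] <= st$AMT[fin] + 1e-12))
  expect_true(all(st$AMT[fin] <= st$MTWM[fin] + 1e-12))
  expect_true(all(st$CI[fin] <= 0) && all(st$WI[fin] >= 0))
  expect_true(all(st$ABT[fin] >= 0 & st$ABT[fin] <= 30))

  mc <- constant_climate(rep(10, 12), rep(15, 12), rep(5, 12), rep(50, 12))
  mc$prec[[4]][2, 2] <- NA    # one missing month in one cell
  st2 <- derive_bioclim(mc)
  for (l in st2$layers) expect_true(is.na(l[2, 2]))
  expect_true(all(is.finite(unlist(lapply(st2$layers, `[`, 1, 1)))))
})

test_that("scaling precipitation scales the water indices coherently", {
  mc <- small_scene()$fx$climate
  st1 <- derive_bioclim(mc)
  mc2 <- mc
  mc2$prec <- lapply(mc$prec, function(m) 2 * m)
  st2 <- derive_bioclim(mc2)
  fin <- is.finite(st1$layers$AP) & is.finite(st2$layers$AP) &
    is.finite(st1$layers$HI)
  expect_equal(st2$layers$AP[fin], 2 * st1$layers$AP[fin])
  expect_equal(st2$layers$PWM[fin], 2 * st1$layers$PWM[fin])
  expect_equal(st2$layers$PDM[fin], 2 * st1$layers$PDM[fin])
  expect_equal(st2$layers$HI[fin], 2 * st1$layers$HI[fin])
  nz <- fin & st1$layers$AP > 0
  expect_equal(st2$layers$PSD[nz], st1$layers$PSD[nz], tolerance = 1e-9)
})

test_that("bioclim stacks round-trip through a directory of asc layers", {
  st <- small_scene()$fx$stack
  d <- tempfile()
  write_bioclim(st, d)
  expect_setequal(list.files(d), paste0(bioclim_layer_names(), ".asc"))
  back <- read_bioclim(d)
  expect_identical(back$layers, st$layers)
})
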