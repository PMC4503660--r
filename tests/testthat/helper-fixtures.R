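# Shared in-memory fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 1L, nrows = 100L, ncols = 100L,
                           n = 100L) {
  key <- paste("fx", seed, nrows, ncols, n, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- default_fixture(seed, nrows, ncols, n)
  .fixture_cache[[key]]
}

# a small landscape for fast unit tests
small_scene <- function(seed = 1L) {
  key <- paste0("scene_", seed)
  if (is.null(.fixture_cache[[key]])) {
    # cooler base temperature so every thermal index varies on a small grid
    climate <- generate_monthly_climate(30L, 30L, seed = seed, t_base = 16)
    stack <- derive_bioclim(climate)
    truth <- true_model_spec(n = 60L)
    occ <- sample_occurrences(truth, stack, seed = seed + 1L, n = 60L)
    fx <- list(climate = climate, stack = stack, occurrences = occ,
               truth = truth)
    pres <- extract_values(fx$stack, fx$occurrences, dedup = TRUE)
    bg <- sample_background(fx$stack, 2000L, seed = seed + 5L)
    .fixture_cache[[key]] <- list(fx = fx, presence = pres,
                                  background = bg)
  }
  .fixture_cache[[key]]
}

# random compatible raster layer list for map-level oracles
random_layers <- function(nrows, ncols, vars, seed) {
  rng_old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  h <- grid_header(ncols, nrows, 0, 0, 1)
  out <- lapply(vars, function(v)
    grid_raster(h, matrix(stats::rnorm(nrows * ncols, sd = 3),
                          nrows, ncols), v))
  names(out) <- vars
  if (!is.null(rng_old)) assign(".Random.seed", rng_old, globalenv())
  out
}

# 12-month constant climate helper
constant_climate <- function(tmean_v, tmax_v, tmin_v, prec_v,
                             nrows = 3L, ncols = 3L) {
  h <- grid_header(ncols, nrows, 0, 0, 1)
  mk <- function(vals) lapply(vals, function(x) matrix(x, nrows, ncols))
  monthly_climate(h, mk(tmean_v), mk(tmax_v), mk(tmin_v), mk(prec_v))
}
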