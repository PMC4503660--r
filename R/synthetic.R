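#' Generate a synthetic monthly climate
#'
#' Builds WorldClim-style monthly fields with known structure: mean
#' temperature is a latitudinal gradient plus a seasonal sinusoid plus
#' spatially smoothed noise; tmax/tmin bracket tmean by a strictly
#' positive seasonal half-range; precipitation is a longitudinal gradient
#' scaled by a summer-peaked seasonal profile plus smoothed noise, clamped
#' non-negative. Optional square NoData patches emulate masked cells.
#' Everything is a pure function of the arguments and `seed`.
#'
#' @param nrows,ncols Grid dimensions (>= 2).
#' @param seed Integer seed.
#' @param xll,yll,cellsize Grid geometry (degrees); defaults give a
#'   10 arc-min grid.
#' @param t_base Mean temperature at the southern edge in July, degC.
#' @param t_lat_gradient Cooling per degree latitude, degC.
#' @param t_seasonal_amp Seasonal temperature amplitude, degC.
#' @param p_range Monthly precipitation of the west and east edges
#'   (annual mean scale), mm.
#' @param p_seasonal_amp Relative seasonal precipitation amplitude in
#'   \[0, 1).
#' @param noise_sd_t,noise_sd_p Standard deviation of the smoothed noise
#'   for temperature (degC) and precipitation (mm); 0 gives the exact
#'   analytic gradient fields.
#' @param smooth_window Moving-average window (cells) for the noise.
#' @param nodata_patches Number of random square NoData patches.
#' @return A [monthly_climate()].
#' @export
generate_monthly_climate <- function(nrows = 100L, ncols = 100L, seed = 1L,
                                     xll = 95, yll = 25, cellsize = 1 / 6,
                                     t_base = 24, t_lat_gradient = 0.9,
                                     t_seasonal_amp = 12,
                                     p_range = c(15, 100),
                                     p_seasonal_amp = 0.8,
                                     noise_sd_t = 0.8, noise_sd_p = 6,
                                     smooth_window = 7L,
                                     nodata_patches = 0L) {
  stopifnot(nrows >= 2L, ncols >= 2L)
  header <- grid_header(ncols, nrows, xll, yll, cellsize)
  lat <- cell_center_lats(header)                    # north -> south
  lon <- cell_center_lons(header)
  lat_m <- matrix(lat, nrows, ncols)                 # by row
  lon_m <- matrix(lon, nrows, ncols, byrow = TRUE)
  rng <- local_rng(seed)

  noise_field <- function(sd) {
    if (sd <= 0) return(matrix(0, nrows, ncols))
    w <- matrix(rng$rnorm(nrows * ncols), nrows, ncols)
    s <- smooth_matrix(w, smooth_window)
    s * sd / max(stats::sd(as.vector(s)), 1e-12)
  }

  t_grad <- t_base - t_lat_gradient * (lat_m - min(lat))
  p_base <- p_range[1] +
    diff(p_range) * (lon_m - min(lon)) / (max(lon) - min(lon))

  tmean <- tmax <- tmin <- prec <- vector("list", 12L)
  for (m in 1:12) {
    seas_t <- t_seasonal_amp * cos(2 * pi * (m - 7) / 12)
    half <- 5 + 2 * cos(2 * pi * (m - 1) / 12)       # > 0 always
    tm <- t_grad + seas_t + noise_field(noise_sd_t)
    tmean[[m]] <- tm
    tmax[[m]] <- tm + half
    tmin[[m]] <- tm - half
    seas_p <- 1 + p_seasonal_amp * cos(2 * pi * (m - 7) / 12)
    prec[[m]] <- pmax(p_base * seas_p + noise_field(noise_sd_p), 0)
  }

  if (nodata_patches > 0L) {
    for (i in seq_len(nodata_patches)) {
      sz <- 2L + rng$sample_int(4L, 1L)
      r0 <- rng$sample_int(max(nrows - sz, 1L), 1L)
      c0 <- rng$sample_int(max(ncols - sz, 1L), 1L)
      rows <- r0:min(r0 + sz, nrows); cols <- c0:min(c0 + sz, ncols)
      for (m in 1:12) {
        tmean[[m]][rows, cols] <- NA; tmax[[m]][rows, cols] <- NA
        tmin[[m]][rows, cols] <- NA; prec[[m]][rows, cols] <- NA
      }
    }
  }
  monthly_climate(header, tmean, tmax, tmin, prec)
}

# separable moving average with edge renormalization
smooth_matrix <- function(m, window) {
  if (window <= 1L) return(m)
  k <- rep(1, window)
  sm1 <- function(x) {
    n <- length(x)
    num <- stats::convolve(x, k, type = "open")
    den <- stats::convolve(rep(1, n), k, type = "open")
    off <- (window - 1L) %/% 2L
    (num / den)[(1L + off):(n + off)]
  }
  m <- apply(m, 2L, sm1)
  t(apply(m, 1L, sm1))
}

#' Specify a known ("true") Gibbs suitability model
#'
#' Defines the ground-truth sampling distribution for synthetic
#' occurrences: a linear/quadratic polynomial per variable on that
#' variable's landscape min-max normalized scale, exponentiated and
#' normalized over the finite cells. The default encodes a unimodal
#' response to annual precipitation (optimum mid-range) and an exponential
#' decay in driest-month precipitation.
#'
#' @param coefs Named list (per variable) of named coefficient vectors
#'   with entries `linear` and/or `quadratic`, on the normalized \[0, 1\]
#'   scale.
#' @param n Default number of presences to sample.
#' @return Object of class `true_model_spec`.
#' @export
true_model_spec <- function(coefs = list(AP = c(linear = 24,
                                                quadratic = -24),
                                         PDM = c(linear = -16)),
                            n = 100L) {
  stopifnot(length(coefs) >= 1L, !is.null(names(coefs)), n >= 1L)
  structure(list(variables = names(coefs), coefs = coefs, n = as.integer(n)),
            class = "true_model_spec")
}

#' True raw (Gibbs) distribution of a truth spec over a stack
#'
#' @param truth A [true_model_spec()].
#' @param stack A [bioclim_stack()] carrying the truth's variables.
#' @return A raw-kind `suitability_map`; finite cells sum to 1.
#' @export
true_raw <- function(truth, stack) {
  stopifnot(inherits(truth, "true_model_spec"))
  layers <- as_layer_list(stack)
  header <- attr(layers, "header")
  miss <- setdiff(truth$variables, names(layers))
  if (length(miss)) stop("stack lacks truth variable(s): ",
                         paste(miss, collapse = ", "))
  fin <- Reduce(`&`, lapply(layers[truth$variables], is.finite))
  cells <- which(fin)
  if (!length(cells)) stop("no finite cells under the truth's variables")
  eta <- numeric(length(cells))
  for (v in truth$variables) {
    x <- layers[[v]][cells]
    z <- (x - min(x)) / (max(x) - min(x))
    cf <- truth$coefs[[v]]
    if ("linear" %in% names(cf)) eta <- eta + cf[["linear"]] * z
    if ("quadratic" %in% names(cf)) eta <- eta + cf[["quadratic"]] * z^2
  }
  w <- exp(eta - max(eta))
  out <- matrix(NA_real_, header$nrows, header$ncols)
  out[cells] <- w / sum(w)
  r <- grid_raster(header, out, name = "true_raw")
  class(r) <- c("suitability_map", class(r))
  attr(r, "output_kind") <- "raw"
  r
}

#' Sample occurrences from a known suitability surface
#'
#' Cells are drawn with replacement with probability proportional to the
#' truth's raw distribution; points are placed at cell centers.
#'
#' @param truth A [true_model_spec()].
#' @param stack The [bioclim_stack()] to sample over.
#' @param seed Integer seed.
#' @param n Number of draws (default `truth$n`).
#' @param dedup Drop repeat draws of the same cell.
#' @return Occurrence data frame (`species`, `longitude`, `latitude`).
#' @export
sample_occurrences <- function(truth, stack, seed = 1L, n = truth$n,
                               dedup = FALSE) {
  raw <- true_raw(truth, stack)
  header <- raw$header
  cells <- which(is.finite(raw$values))
  p <- raw$values[cells]
  rng <- local_rng(seed)
  draw <- cells[rng$sample_int(length(cells), n, replace = TRUE, prob = p)]
  if (dedup) draw <- unique(draw)
  rc <- arrayInd(draw, c(header$nrows, header$ncols))
  data.frame(species = "synthetic_species",
             longitude = cell_center_lons(header)[rc[, 2L]],
             latitude = cell_center_lats(header)[rc[, 1L]],
             stringsAsFactors = FALSE)
}

#' The package's canonical synthetic test scene
#'
#' A 100 x 100 landscape with the default synthetic climate, its 13
#' derived bioclimatic layers, a two-variable ground truth (unimodal in
#' AP, exponential decay in PDM), and `n` occurrences sampled from it.
#' Fully reproducible from `seed`.
#'
#' @param seed Integer seed.
#' @param nrows,ncols Grid dimensions.
#' @param n Number of occurrences.
#' @return List with elements `climate`, `stack`, `occurrences`, `truth`.
#' @export
default_fixture <- function(seed = 1L, nrows = 100L, ncols = 100L,
                            n = 100L) {
  climate <- generate_monthly_climate(nrows, ncols, seed = seed)
  stack <- derive_bioclim(climate)
  truth <- true_model_spec(n = n)
  occ <- sample_occurrences(truth, stack, seed = seed + 1L, n = n)
  list(climate = climate, stack = stack, occurrences = occ, truth = truth)
}
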