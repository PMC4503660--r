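#' @name bioclim-indices
#' @title Scalar bioclimatic index calculators
#'
#' @description
#' The thirteen derived variables summarise a 12-month climatology per cell:
#' annual temperature summaries (AMT, MTWM, MTCM, ART), precipitation
#' summaries (AP, PWM, PDM, PSD), Kira's thermal indices (WI, CI) with
#' Holdridge's annual biotemperature (ABT), and the two moisture ratios
#' (PER, HI). These scalar functions are the single source of truth; the
#' grid-level [derive_bioclim()] applies them cell-wise.
#'
#' Conventions with more than one defensible reading carry a mode argument:
#' \describe{
#'   \item{`art_mode`}{`"annual_range"` (default): ART = max monthly tmax
#'     minus min monthly tmin, the annual-range statistic matching the
#'     variable's name and the magnitudes reported for temperate habitats;
#'     `"footnote_literal"`: the mean of the twelve monthly (tmax - tmin)
#'     diurnal ranges.}
#'   \item{`psd_mode`}{`"plain_cv"` (default): 100 * population-sd / mean;
#'     `"worldclim_cv"`: 100 * population-sd / (1 + mean).}
#'   \item{`abt_mode`}{`"holdridge_clamp"` (default): mean of monthly
#'     temperatures clamped into \[0, 30\] degC; `"footnote_literal"`: sum of
#'     months with 0 < T < 30 divided by 12.}
#' }
NULL

# population sd: months are the complete climatology, not a sample
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @describeIn bioclim-indices Annual mean (AMT), warmest-month (MTWM) and
#'   coldest-month (MTCM) mean temperature, and annual temperature range
#'   (ART), all degC. Any missing month yields all-`NA`.
#' @param tmean,tmax,tmin Twelve monthly mean/maximum/minimum temperatures,
#'   degC.
#' @param art_mode See Description.
#' @return A named numeric vector.
#' @export
temperature_summaries <- function(tmean, tmax, tmin,
                                  art_mode = c("annual_range",
                                               "footnote_literal")) {
  art_mode <- match.arg(art_mode)
  stopifnot(length(tmean) == 12L, length(tmax) == 12L, length(tmin) == 12L)
  if (anyNA(tmean) || anyNA(tmax) || anyNA(tmin) ||
      any(!is.finite(c(tmean, tmax, tmin))))
    return(c(AMT = NA_real_, MTWM = NA_real_, MTCM = NA_real_,
             ART = NA_real_))
  art <- if (art_mode == "annual_range") max(tmax) - min(tmin)
         else mean(tmax - tmin)
  c(AMT = mean(tmean), MTWM = max(tmean), MTCM = min(tmean), ART = art)
}

#' @describeIn bioclim-indices Annual precipitation (AP), wettest (PWM) and
#'   driest (PDM) month, all mm, and precipitation seasonality PSD (%), the
#'   coefficient of variation of the monthly values (0 when the mean is 0).
#' @param prec Twelve monthly precipitation totals, mm (non-negative).
#' @param psd_mode See Description.
#' @export
precipitation_summaries <- function(prec,
                                    psd_mode = c("plain_cv",
                                                 "worldclim_cv")) {
  psd_mode <- match.arg(psd_mode)
  stopifnot(length(prec) == 12L)
  if (anyNA(prec) || any(!is.finite(prec)))
    return(c(AP = NA_real_, PWM = NA_real_, PDM = NA_real_, PSD = NA_real_))
  if (any(prec < 0)) stop("negative precipitation")
  m <- mean(prec)
  psd <- if (psd_mode == "plain_cv") {
    if (m == 0) 0 else 100 * pop_sd(prec) / m
  } else {
    100 * pop_sd(prec) / (1 + m)
  }
  c(AP = sum(prec), PWM = max(prec), PDM = min(prec), PSD = psd)
}

#' @describeIn bioclim-indices Holdridge annual biotemperature ABT (degC)
#'   and Kira's warmth index WI = sum over months with T > 5 of (T - 5) and
#'   coldness index CI = -sum over months with T < 5 of (5 - T); months with
#'   T exactly 5 contribute to neither. WI >= 0 >= CI always.
#' @param abt_mode See Description.
#' @export
thermal_indices <- function(tmean,
                            abt_mode = c("holdridge_clamp",
                                         "footnote_literal")) {
  abt_mode <- match.arg(abt_mode)
  stopifnot(length(tmean) == 12L)
  if (anyNA(tmean) || any(!is.finite(tmean)))
    return(c(ABT = NA_real_, WI = NA_real_, CI = NA_real_))
  wi <- sum(pmax(tmean - 5, 0)[tmean > 5], 0)
  ci <- -sum(pmax(5 - tmean, 0)[tmean < 5], 0)
  abt <- if (abt_mode == "holdridge_clamp") mean(pmin(pmax(tmean, 0), 30))
         else sum(tmean[tmean > 0 & tmean < 30]) / 12
  c(ABT = abt, WI = wi, CI = ci)
}

#' @describeIn bioclim-indices Holdridge potential evapotranspiration ratio
#'   PER = 58.93 * ABT / AP (`NA` when AP = 0) and humidity index
#'   HI = AP / WI (mm/degC, `NA` when WI = 0).
#' @param ABT,AP,WI Scalars as produced by the other calculators.
#' @export
moisture_indices <- function(ABT, AP, WI) {
  per <- if (!is.finite(ABT) || !is.finite(AP) || AP == 0) NA_real_
         else 58.93 * ABT / AP
  hi <- if (!is.finite(AP) || !is.finite(WI) || WI == 0) NA_real_
        else AP / WI
  c(PER = per, HI = hi)
}

#' Names of the thirteen derived variables, in canonical order
#' @export
bioclim_layer_names <- function()
  c("AMT", "MTWM", "MTCM", "ART", "AP", "PWM", "PDM", "PSD",
    "ABT", "WI", "CI", "PER", "HI")

#' Bundle monthly climate grids
#'
#' @param header A [grid_header()].
#' @param tmean,tmax,tmin Lists of 12 matrices (`nrows x ncols`), degC.
#' @param prec List of 12 matrices, mm.
#' @return An object of class `monthly_climate`.
#' @export
monthly_climate <- function(header, tmean, tmax, tmin, prec) {
  stopifnot(inherits(header, "grid_header"),
            length(tmean) == 12L, length(tmax) == 12L,
            length(tmin) == 12L, length(prec) == 12L)
  chk <- function(l) for (m in l)
    if (!is.matrix(m) || nrow(m) != header$nrows || ncol(m) != header$ncols)
      stop("monthly layer dimensions do not match the header")
  chk(tmean); chk(tmax); chk(tmin); chk(prec)
  structure(list(header = header, tmean = tmean, tmax = tmax,
                 tmin = tmin, prec = prec),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("monthly_climate: %d x %d grid, 12 months of tmean/tmax/tmin (degC) and prec (mm)\n",
              x$header$nrows, x$header$ncols))
  invisible(x)
}

#' Construct a 13-layer bioclimatic stack
#'
#' @param header A [grid_header()].
#' @param layers Named list of 13 matrices, names as in
#'   [bioclim_layer_names()].
#' @return Object of class `bioclim_stack`.
#' @export
bioclim_stack <- function(header, layers) {
  if (!identical(names(layers), bioclim_layer_names()))
    stop("layers must be exactly ", paste(bioclim_layer_names(),
                                          collapse = ", "), " in order")
  structure(list(header = header, layers = layers),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack: %d x %d grid, 13 layers (%s)\n",
              x$header$nrows, x$header$ncols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Derive the 13 bioclimatic layers from monthly climate
#'
#' Applies the scalar index calculators cell-wise. A cell that is NoData in
#' any input month is NoData in every derived layer, as are cells whose
#' moisture ratios have zero denominators.
#'
#' @param mc A [monthly_climate()].
#' @param art_mode,psd_mode,abt_mode Passed to the scalar calculators.
#' @return A [bioclim_stack()].
#' @export
derive_bioclim <- function(mc, art_mode = "annual_range",
                           psd_mode = "plain_cv",
                           abt_mode = "holdridge_clamp") {
  stopifnot(inherits(mc, "monthly_climate"))
  h <- mc$header
  n <- h$nrows * h$ncols
  # month-by-cell matrices (12 x n), vectorized across cells
  tme <- do.call(rbind, lapply(mc$tmean, as.vector))
  tma <- do.call(rbind, lapply(mc$tmax, as.vector))
  tmi <- do.call(rbind, lapply(mc$tmin, as.vector))
  pre <- do.call(rbind, lapply(mc$prec, as.vector))
  bad <- colSums(!is.finite(tme)) + colSums(!is.finite(tma)) +
    colSums(!is.finite(tmi)) + colSums(!is.finite(pre)) > 0L
  if (any(pre[, !bad] < 0, na.rm = TRUE)) stop("negative precipitation")

  AMT <- colMeans(tme)
  MTWM <- apply(tme, 2L, max); MTCM <- apply(tme, 2L, min)
  ART <- if (art_mode == "annual_range")
    apply(tma, 2L, max) - apply(tmi, 2L, min) else colMeans(tma - tmi)
  AP <- colSums(pre)
  PWM <- apply(pre, 2L, max); PDM <- apply(pre, 2L, min)
  mp <- AP / 12
  sdp <- sqrt(colMeans(sweep(pre, 2L, mp)^2))
  PSD <- if (psd_mode == "plain_cv")
    ifelse(mp == 0, 0, 100 * sdp / mp) else 100 * sdp / (1 + mp)
  WI <- colSums(pmax(tme - 5, 0))
  CI <- -colSums(pmax(5 - tme, 0))
  ABT <- if (abt_mode == "holdridge_clamp")
    colMeans(pmin(pmax(tme, 0), 30)) else colSums(tme * (tme > 0 & tme < 30)) / 12
  PER <- ifelse(AP == 0, NA_real_, 58.93 * ABT / AP)
  HI <- ifelse(WI == 0, NA_real_, AP / WI)

  layers <- list(AMT = AMT, MTWM = MTWM, MTCM = MTCM, ART = ART,
                 AP = AP, PWM = PWM, PDM = PDM, PSD = PSD,
                 ABT = ABT, WI = WI, CI = CI, PER = PER, HI = HI)
  layers <- lapply(layers, function(v) {
    v[bad] <- NA_real_
    matrix(v, nrow = h$nrows, ncol = h$ncols)
  })
  bioclim_stack(h, layers)
}

#' Write the 13 layers of a stack as ESRI ASCII grids
#'
#' Files are named `<layer>.asc` (`AMT.asc` ... `HI.asc`).
#'
#' @param stack A [bioclim_stack()].
#' @param dir Output directory (created if absent).
#' @return The vector of paths written, invisibly.
#' @export
write_bioclim <- function(stack, dir) {
  stopifnot(inherits(stack, "bioclim_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(grid_raster(stack$header, stack$layers[[nm]], nm), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a 13-layer bioclimatic stack from a directory of `.asc` files
#'
#' @param dir Directory containing `AMT.asc` ... `HI.asc`.
#' @return A [bioclim_stack()].
#' @export
read_bioclim <- function(dir) {
  rs <- lapply(bioclim_layer_names(), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    if (!file.exists(p)) stop("missing layer file ", p)
    read_ascii_grid(p)
  })
  h <- rs[[1]]$header
  for (r in rs) if (!headers_compatible(r$header, h))
    stop("bioclim layers have incompatible headers")
  layers <- lapply(rs, `[[`, "values")
  names(layers) <- bioclim_layer_names()
  bioclim_stack(h, layers)
}
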