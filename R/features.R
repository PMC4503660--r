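#' Build a MaxEnt feature set from background samples
#'
#' Each covariate is min-max normalized to \[0, 1\] using its background
#' extremes (prediction-time values outside that range are clamped). On the
#' normalized scale the feature kinds are:
#' \describe{
#'   \item{linear}{the normalized value itself}
#'   \item{quadratic}{its square}
#'   \item{product}{pairwise products of two distinct normalized variables}
#'   \item{threshold}{step features at `n_knots` evenly spaced knots
#'     `v = i/(n_knots+1)`; value 1 iff the variable exceeds `v`}
#'   \item{hinge}{ramp features at the same knots; 0 at or below `v`, rising
#'     linearly to 1 at the variable's background maximum}
#' }
#' Covariates constant over the background are dropped with a warning.
#'
#' @param background Data frame of background samples (SWD layout or plain
#'   covariate columns; `species`/`longitude`/`latitude` columns are
#'   ignored).
#' @param kinds Character vector of enabled feature kinds.
#' @param n_knots Number of threshold and hinge knots per variable.
#' @return An object of class `maxent_features`: a list with the feature
#'   table (`kind`, `var1`, `var2`, `knot`), per-variable normalization
#'   bounds, and the variable names used.
#' @export
build_features <- function(background,
                           kinds = c("linear", "quadratic", "product",
                                     "threshold", "hinge"),
                           n_knots = 10L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  X <- swd_matrix(background)
  if (nrow(X) == 0L) stop("background is empty")
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  keep <- hi > lo
  if (!all(keep)) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]
  }
  vars <- colnames(X)
  if (!length(vars)) stop("no usable (non-constant) variables")
  knots <- if (n_knots >= 1L) seq_len(n_knots) / (n_knots + 1) else numeric(0)
  rows <- list()
  add <- function(kind, v1, v2 = NA_character_, knot = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, var1 = v1,
                                             var2 = v2, knot = knot,
                                             stringsAsFactors = FALSE)
  for (v in vars) {
    if ("linear" %in% kinds) add("linear", v)
    if ("quadratic" %in% kinds) add("quadratic", v)
    if ("threshold" %in% kinds) for (k in knots) add("threshold", v, knot = k)
    if ("hinge" %in% kinds) for (k in knots) add("hinge", v, knot = k)
  }
  if ("product" %in% kinds && length(vars) >= 2L)
    for (i in seq_len(length(vars) - 1L))
      for (j in (i + 1L):length(vars))
        add("product", vars[i], vars[j])
  structure(list(table = do.call(rbind, rows),
                 lo = lo, hi = hi, variables = vars),
            class = "maxent_features")
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("maxent_features: %d features over %d variable(s) [%s]\n",
              nrow(x$table), length(x$variables),
              paste(names(table(x$table$kind)),
                    table(x$table$kind), sep = ":", collapse = " ")))
  invisible(x)
}

# covariate columns of an SWD-style data frame as a numeric matrix
swd_matrix <- function(d) {
  if (is.matrix(d)) return(d)
  stopifnot(is.data.frame(d))
  drop <- tolower(names(d)) %in% c("species", "longitude", "latitude",
                                   "lon", "lat")
  m <- as.matrix(d[, !drop, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Evaluate a feature set on covariate data
#'
#' Values are clamped into the background normalization range first, so
#' every feature maps into \[0, 1\].
#'
#' @param features A `maxent_features` object.
#' @param data Data frame or matrix carrying the feature set's variables.
#' @param subset Optional integer vector of feature rows to evaluate.
#' @return Numeric matrix, one column per (selected) feature.
#' @export
evaluate_features <- function(features, data, subset = NULL) {
  X <- swd_matrix(data)
  miss <- setdiff(features$variables, colnames(X))
  if (length(miss))
    stop("data lacks variable(s): ", paste(miss, collapse = ", "))
  Z <- sapply(features$variables, function(v) {
    z <- (X[, v] - features$lo[[v]]) / (features$hi[[v]] - features$lo[[v]])
    pmin(pmax(z, 0), 1)
  })
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = nrow(X),
                                 dimnames = list(NULL, features$variables))
  tab <- features$table
  idx <- if (is.null(subset)) seq_len(nrow(tab)) else subset
  out <- matrix(0, nrow = nrow(X), ncol = length(idx))
  for (k in seq_along(idx)) {
    r <- tab[idx[k], ]
    z <- Z[, r$var1]
    out[, k] <- switch(r$kind,
      linear = z,
      quadratic = z * z,
      product = z * Z[, r$var2],
      threshold = as.numeric(z > r$knot),
      hinge = pmin(pmax((z - r$knot) / (1 - r$knot), 0), 1),
      stop("unknown feature kind ", r$kind))
  }
  colnames(out) <- feature_labels(features)[idx]
  out
}

feature_labels <- function(features) {
  tab <- features$table
  ifelse(tab$kind == "product", paste0(tab$var1, "*", tab$var2),
         ifelse(is.na(tab$knot), paste0(tab$kind, "(", tab$var1, ")"),
                sprintf("%s(%s,%.3f)", tab$kind, tab$var1, tab$knot)))
}
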