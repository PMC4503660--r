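#' Grid header for a regular lon/lat raster
#'
#' Describes the geometry shared by every layer in an analysis: grid size,
#' lower-left corner (corner registration), cell size in degrees, and the
#' NoData sentinel used on disk. All layers entering a model fit must carry
#' compatible headers.
#'
#' @param ncols,nrows Grid dimensions (positive integers).
#' @param xll,yll Longitude / latitude of the lower-left corner, degrees.
#' @param cellsize Cell edge length in degrees (> 0).
#' @param nodata_value Sentinel written to disk for missing cells.
#' @return An object of class `grid_header`.
#' @export
grid_header <- function(ncols, nrows, xll, yll, cellsize,
                        nodata_value = -9999) {
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (is.na(ncols) || is.na(nrows) || ncols < 1L || nrows < 1L)
    stop("ncols and nrows must be positive integers")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("cellsize must be > 0")
  structure(list(ncols = ncols, nrows = nrows,
                 xll = as.numeric(xll), yll = as.numeric(yll),
                 cellsize = as.numeric(cellsize),
                 nodata_value = as.numeric(nodata_value)),
            class = "grid_header")
}

#' Test whether two grid headers describe the same geometry
#'
#' Headers are compatible when all six fields agree within `tol`.
#'
#' @param a,b `grid_header` objects.
#' @param tol Numeric tolerance for the comparison.
#' @return `TRUE` or `FALSE`.
#' @export
headers_compatible <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_header"), inherits(b, "grid_header"))
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$nodata_value - b$nodata_value) < tol
}

#' Construct a raster layer
#'
#' A raster couples a [grid_header()] with an `nrows x ncols` numeric matrix
#' whose row 1 is the northern edge (cell \[1, 1\] is the NW corner).
#' Missing cells are `NA` in memory and the header's `nodata_value` on disk.
#'
#' @param header A `grid_header`.
#' @param values Numeric matrix, `nrows x ncols`, or a vector of that length
#'   filled row-wise from the north.
#' @param name Optional layer name.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(header, values, name = NULL) {
  stopifnot(inherits(header, "grid_header"))
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), nrow = header$nrows,
                     ncol = header$ncols, byrow = TRUE)
  if (nrow(values) != header$nrows || ncol(values) != header$ncols)
    stop(sprintf("values are %d x %d but header declares %d x %d",
                 nrow(values), ncol(values), header$nrows, header$ncols))
  storage.mode(values) <- "double"
  structure(list(header = header, values = values, name = name),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  h <- x$header
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster%s: %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              h$nrows, h$ncols, h$cellsize, h$xll, h$yll))
  cat(sprintf("  finite cells: %d / %d", length(v), h$nrows * h$ncols))
  if (length(v))
    cat(sprintf("; range [%.6g, %.6g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

# longitude of cell centers, west -> east (columns)
cell_center_lons <- function(header)
  header$xll + (seq_len(header$ncols) - 0.5) * header$cellsize

# latitude of cell centers, north -> south (rows, matching matrix row order)
cell_center_lats <- function(header)
  header$yll + (header$nrows - seq_len(header$nrows) + 0.5) * header$cellsize

#' Read an ESRI ASCII grid
#'
#' Accepts the standard six-line header (case-insensitive keys) with either
#' corner (`xllcorner`/`yllcorner`) or center (`xllcenter`/`yllcenter`)
#' registration; center-registered origins are converted to the corner
#' convention (`corner = center - cellsize/2`). Values equal to the NoData
#' sentinel become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A [grid_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop("not an ESRI ASCII grid: fewer than 7 lines in ", path)
  keys <- character(6); vals <- numeric(6)
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header line ", i, ": '", lines[i], "'")
    keys[i] <- tolower(parts[1])
    v <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(v))
      stop("malformed header line ", i, ": '", lines[i], "'")
    vals[i] <- v
  }
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  for (k in need)
    if (!k %in% keys) stop("header missing key '", k, "'")
  if ("xllcorner" %in% keys && "yllcorner" %in% keys) {
    xll <- vals[["xllcorner"]]; yll <- vals[["yllcorner"]]
  } else if ("xllcenter" %in% keys && "yllcenter" %in% keys) {
    xll <- vals[["xllcenter"]] - vals[["cellsize"]] / 2
    yll <- vals[["yllcenter"]] - vals[["cellsize"]] / 2
  } else {
    stop("header must carry xllcorner/yllcorner or xllcenter/yllcenter")
  }
  h <- grid_header(vals[["ncols"]], vals[["nrows"]], xll, yll,
                   vals[["cellsize"]], vals[["nodata_value"]])
  body <- paste(lines[-(1:6)], collapse = " ")
  toks <- strsplit(trimws(body), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) != h$ncols * h$nrows)
    stop(sprintf("value count mismatch in %s: expected %d, found %d",
                 path, h$ncols * h$nrows, length(toks)))
  x <- as.numeric(toks)
  if (anyNA(x)) stop("non-numeric cell value in ", path)
  x[x == h$nodata_value] <- NA_real_
  grid_raster(h, x, name = sub("\\.asc$", "", basename(path),
                               ignore.case = TRUE))
}

#' Write an ESRI ASCII grid
#'
#' Values are printed with enough significant digits (17) that
#' `read_ascii_grid(write_ascii_grid(r))` reproduces `r` exactly, and two
#' writes of the same raster are byte-identical.
#'
#' @param raster A [grid_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "grid_raster"))
  h <- raster$header
  v <- raster$values
  v[!is.finite(v)] <- h$nodata_value
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", h$ncols),
    sprintf("nrows %d", h$nrows),
    sprintf("xllcorner %.17g", h$xll),
    sprintf("yllcorner %.17g", h$yll),
    sprintf("cellsize %.17g", h$cellsize),
    sprintf("NODATA_value %.17g", h$nodata_value)), con)
  writeLines(apply(v, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = " ")), con)
  invisible(path)
}

#' Read occurrence records from delimited text
#'
#' Expects a header row `species,longitude,latitude` (any delimiter
#' `read.csv` accepts with `sep = ","`). Rows are kept in file order.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `species`, `longitude`, `latitude`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no occurrence records in ", path)
  names(df) <- tolower(names(df))
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence file must have columns species, longitude, latitude")
  df <- df[, need]
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad))
    stop("unparseable coordinate at data row ", bad[1])
  out <- which(lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(out))
    stop("coordinate out of range at data row ", out[1],
         " (lon ", lon[out[1]], ", lat ", lat[out[1]], ")")
  df$longitude <- lon; df$latitude <- lat
  df
}

# half-open cell assignment: col = floor((lon - xll)/cs), row counted from
# the north; points on a shared edge belong to the cell to the east/north.
cell_index <- function(header, lon, lat) {
  cs <- header$cellsize
  col <- floor((lon - header$xll) / cs) + 1L
  row_s <- floor((lat - header$yll) / cs) + 1L   # from the south
  inside <- col >= 1L & col <= header$ncols &
    row_s >= 1L & row_s <= header$nrows
  row <- header$nrows - row_s + 1L
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col),
       cell = as.integer((col - 1L) * header$nrows + row))
}

#' Extract covariate values at occurrence points
#'
#' Maps each point to its containing cell (half-open intervals; a point on a
#' shared edge belongs to the cell to the east/north), drops points that fall
#' outside the grid or over NoData in any layer (with a warning), and
#' optionally keeps at most one point per cell.
#'
#' @param stack A [bioclim_stack()] or named list of compatible
#'   [grid_raster()] layers.
#' @param occ Data frame with `species`, `longitude`, `latitude` columns.
#' @param dedup Keep at most one record per grid cell (default `TRUE`,
#'   standard presence-only practice).
#' @return A samples-with-data (SWD) data frame: `species`, `longitude`,
#'   `latitude`, then one column per layer; the matched cell ids are stored
#'   in attribute `"cell"`.
#' @export
extract_values <- function(stack, occ, dedup = TRUE) {
  layers <- as_layer_list(stack)
  header <- attr(layers, "header")
  idx <- cell_index(header, occ$longitude, occ$latitude)
  keep <- !is.na(idx$cell)
  if (any(!keep))
    warning(sum(!keep), " point(s) outside grid bounds dropped")
  vals <- lapply(layers, function(r) r[cbind(idx$row[keep], idx$col[keep])])
  m <- do.call(cbind, vals)
  ok <- rowSums(!is.finite(m)) == 0L
  if (any(!ok))
    warning(sum(!ok), " point(s) over NoData cells dropped")
  rows <- which(keep)[ok]
  if (!length(rows)) stop("all occurrence points dropped during extraction")
  swd <- data.frame(species = occ$species[rows],
                    longitude = occ$longitude[rows],
                    latitude = occ$latitude[rows],
                    m[ok, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  cells <- idx$cell[rows]
  if (dedup) {
    first <- !duplicated(cells)
    swd <- swd[first, , drop = FALSE]
    cells <- cells[first]
  }
  rownames(swd) <- NULL
  attr(swd, "cell") <- cells
  swd
}

# normalize a stack / raster list into a named list of value matrices with
# a shared header in attr "header"; errors on incompatible geometry
as_layer_list <- function(stack) {
  if (inherits(stack, "bioclim_stack")) {
    out <- stack$layers
    attr(out, "header") <- stack$header
    return(out)
  }
  stopifnot(is.list(stack), length(stack) >= 1L)
  h <- stack[[1]]$header
  out <- lapply(stack, function(r) {
    stopifnot(inherits(r, "grid_raster"))
    if (!headers_compatible(r$header, h))
      stop("raster layers have incompatible grid headers")
    r$values
  })
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("raster layers must be named")
  attr(out, "header") <- h
  out
}
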