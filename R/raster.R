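#' Single-band raster on a uniform square-cell grid
#'
#' `grid_raster` is the carrier used throughout the package for covariates,
#' suitability surfaces, binary habitat maps and categorical maps. It wraps a
#' numeric (or integer) matrix with an affine georeference: square cells of
#' side `cellsize` metres, lower-left corner at (`xll`, `yll`). Row 1 of the
#' matrix is the northernmost row, matching the usual map orientation.
#' Missing data is encoded as `NA`.
#'
#' @param values numeric matrix; row 1 is the top (north) row.
#' @param cellsize cell side length in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param crs free-text tag describing the projected CRS; carried, not used.
#' @return an object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(runif(12), 3, 4), cellsize = 120)
#' dim(r)
#' @export
grid_raster <- function(values, cellsize, xll = 0, yll = 0,
                        crs = "local-projected") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have positive dimensions")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll), crs = crs),
    class = "grid_raster")
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  cat(sprintf("  crs: %s\n", x$crs))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], NA cells: %d\n",
                min(fin), max(fin), sum(is.na(v))))
  invisible(x)
}

#' Test that two rasters share one grid and transform
#'
#' All stack operations in the package require an identical grid; this is the
#' guard they use.
#'
#' @param a,b `grid_raster` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(a$xll, b$xll)) &&
    isTRUE(all.equal(a$yll, b$yll))
}

stop_unless_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters do not share the same grid/transform")
  invisible(TRUE)
}

#' Apply a function to raster values, keeping the georeference
#'
#' @param x a `grid_raster`.
#' @param f function applied to the value matrix (must preserve shape).
#' @param ... passed to `f`.
#' @return a `grid_raster` with transformed values.
#' @export
map_values <- function(x, f, ...) {
  v <- f(x$values, ...)
  if (!identical(dim(v), dim(x$values))) {
    v <- matrix(v, nrow(x$values), ncol(x$values))
  }
  grid_raster(v, x$cellsize, x$xll, x$yll, x$crs)
}

#' Cell-center coordinates
#'
#' @param x a `grid_raster`.
#' @return data.frame with columns `row`, `col`, `x`, `y` for every cell,
#'   in column-major cell order.
#' @export
cell_centers <- function(x) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(row = rows, col = cols,
             x = x$xll + (cols - 0.5) * x$cellsize,
             y = x$yll + (nr - rows + 0.5) * x$cellsize)
}

#' Map projected coordinates to raster row/col indices
#'
#' Points outside the extent get `NA` indices.
#'
#' @param x a `grid_raster`.
#' @param px,py coordinate vectors (m).
#' @return data.frame with columns `row`, `col`.
#' @export
xy_to_rowcol <- function(x, px, py) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  col <- floor((px - x$xll) / x$cellsize) + 1L
  row <- nr - floor((py - x$yll) / x$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param x a `grid_raster`.
#' @param px,py coordinate vectors (m).
#' @return numeric vector; `NA` for points outside the extent or on nodata.
#' @export
extract_values <- function(x, px, py) {
  rc <- xy_to_rowcol(x, px, py)
  out <- rep(NA_real_, length(px))
  ok <- !is.na(rc$row)
  out[ok] <- x$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Area of non-zero raster cells in square kilometres
#'
#' Counts cells with value 1 (or any non-zero, non-`NA` value when
#' `nonzero = TRUE`) and multiplies by the cell area `(cellsize/1000)^2`.
#'
#' @param x a `grid_raster` (binary or categorical).
#' @param value count cells equal to this value; default counts non-zero.
#' @return area in km^2.
#' @export
raster_area_km2 <- function(x, value = NULL) {
  v <- x$values
  n <- if (is.null(value)) sum(v != 0, na.rm = TRUE) else
    sum(v == value, na.rm = TRUE)
  n * (x$cellsize / 1000)^2
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format readable by standard GIS
#' software. `NA` cells are written as the nodata value.
#'
#' @param x a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata sentinel written to file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  v <- x$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$xll),
    sprintf("yllcorner %.10g", x$yll),
    sprintf("cellsize %.10g", x$cellsize),
    sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crs CRS tag to attach.
#' @return a `grid_raster`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, crs = "local-projected") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  body <- lines[i:length(lines)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("ASCII grid body does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid_raster(m, hdr$cellsize,
              xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
              yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
              crs = crs)
}
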