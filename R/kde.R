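#' Kernel density estimate utilization distribution and isopleth region
#'
#' Estimates a bivariate-normal-kernel utilization distribution for a point
#' set on the analysis grid, using the reference bandwidth
#' `h_ref = sqrt((var_x + var_y) / 2) * n^(-1/6)`, and extracts the smallest
#' density superlevel set holding at least `level` of the total mass. That
#' region is the standard boundary within which background locations are
#' sampled for state-scale presence-background models, countering the
#' spatial clustering of telemetry.
#'
#' Density is computed by binning the points to the grid and convolving with
#' a (separable) Gaussian kernel of standard deviation `h_ref`.
#'
#' @param points data.frame with `x`, `y` columns (>= 5 rows).
#' @param template `grid_raster` defining the evaluation grid.
#' @param level isopleth mass level (default 0.95).
#' @param h optional bandwidth override (m).
#' @return list of class `kde_region`: `h_ref`, `level`, `density`
#'   (`grid_raster`, cell masses summing to 1), `mask` (binary
#'   `grid_raster`), `threshold` (density cutoff), `mass` (mass actually
#'   enclosed, >= level).
#' @export
kde_polygon <- function(points, template, level = 0.95, h = NULL) {
  n <- if (is.null(points)) 0L else nrow(points)
  if (is.null(n) || n < 5L) stop("need at least 5 points")
  vx <- stats::var(points$x); vy <- stats::var(points$y)
  if (is.null(h)) {
    if (vx + vy <= 0) stop("degenerate bandwidth: all points identical")
    h <- sqrt((vx + vy) / 2) * n^(-1 / 6)
  }
  if (h <= 0) stop("bandwidth must be positive")
  cs <- template$cellsize
  nr <- nrow(template$values); nc <- ncol(template$values)
  rc <- xy_to_rowcol(template, points$x, points$y)
  ok <- !is.na(rc$row)
  if (!any(ok)) stop("no points fall inside the template extent")
  counts <- matrix(0, nr, nc)
  tab <- table(factor(rc$row[ok], levels = seq_len(nr)),
               factor(rc$col[ok], levels = seq_len(nc)))
  counts[] <- as.numeric(tab)
  # separable Gaussian blur, kernel sd = h in metres
  half <- max(1L, ceiling(4 * h / cs))
  kx <- stats::dnorm((-half:half) * cs, sd = h)
  kx <- kx / sum(kx)
  dens <- apply(counts, 2L, conv_1d, kernel = kx)
  dens <- t(apply(dens, 1L, conv_1d, kernel = kx))
  dens <- dens / sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  # tolerance guards the level = 1 case against cumsum rounding
  cut_idx <- which(cum >= level - 1e-12)[1]
  if (is.na(cut_idx)) cut_idx <- max(which(dens[ord] > 0))
  threshold <- dens[ord[cut_idx]]
  mask <- (dens >= threshold) * 1
  structure(list(h_ref = h, level = level,
                 density = grid_raster(dens, cs, template$xll, template$yll,
                                       template$crs),
                 mask = grid_raster(mask, cs, template$xll, template$yll,
                                    template$crs),
                 threshold = threshold,
                 mass = sum(dens[mask == 1])),
            class = "kde_region")
}

# 1-D convolution with zero padding, output same length as input.
conv_1d <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  out <- stats::filter(c(rep(0, half), x, rep(0, half)), kernel,
                       sides = 2L)
  as.numeric(out[(half + 1L):(half + length(x))])
}

#' Sample background locations from a region
#'
#' Draws `n` cells uniformly with replacement from the region's eligible
#' cells and returns their center coordinates. Duplicates are allowed, so
#' the draw is well-defined even when the region holds fewer than `n` cells.
#'
#' @param region binary `grid_raster` (non-zero = eligible) or a
#'   `kde_region` (its isopleth mask is used).
#' @param n number of points.
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `row`, `col`.
#' @export
sample_background <- function(region, n = 10000, seed = 1L) {
  if (inherits(region, "kde_region")) region <- region$mask
  v <- region$values
  eligible <- which(!is.na(v) & v != 0)
  if (!length(eligible)) stop("region is empty")
  set.seed(as.integer(seed))
  pick <- eligible[sample.int(length(eligible), n, replace = TRUE)]
  nr <- nrow(v)
  row <- (pick - 1L) %% nr + 1L
  col <- (pick - 1L) %/% nr + 1L
  data.frame(x = region$xll + (col - 0.5) * region$cellsize,
             y = region$yll + (nr - row + 0.5) * region$cellsize,
             row = row, col = col)
}
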