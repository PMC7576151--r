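#' Exact Euclidean distance to the nearest true cell
#'
#' Center-to-center Euclidean distance from every cell to the nearest cell
#' where `mask` is non-zero (true cells map to 0). Uses the exact separable
#' squared-distance transform (lower-envelope-of-parabolas method), so the
#' result equals the brute-force minimum over all true cells to numerical
#' precision.
#'
#' @param mask binary `grid_raster` (non-zero = true); must contain at least
#'   one true cell.
#' @return `grid_raster` of distances in metres.
#' @export
euclidean_distance <- function(mask) {
  m <- mask$values
  if (!any(m != 0, na.rm = TRUE)) stop("mask has no true cells")
  nr <- nrow(m); nc <- ncol(m)
  INF <- .Machine$double.xmax / 4
  # squared distance in cell units, initialized per cell
  g <- matrix(INF, nr, nc)
  g[!is.na(m) & m != 0] <- 0
  # pass 1: 1-D transform down each column (row direction)
  for (j in seq_len(nc)) g[, j] <- edt_1d(g[, j])
  # pass 2: 1-D transform along each row (col direction)
  for (i in seq_len(nr)) g[i, ] <- edt_1d(g[i, ])
  grid_raster(sqrt(g) * mask$cellsize, mask$cellsize, mask$xll, mask$yll,
              mask$crs)
}

# 1-D squared distance transform of a sampled function f (Felzenszwalb &
# Huttenlocher): d(p) = min_q (p - q)^2 + f(q).
edt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Relative (row, col) offsets of cells whose centers lie within radius_cells
# of a focal center.
disc_offsets <- function(radius_cells) {
  r <- floor(radius_cells)
  di <- rep(-r:r, times = 2L * r + 1L)
  dj <- rep(-r:r, each = 2L * r + 1L)
  keep <- di^2 + dj^2 <= radius_cells^2
  cbind(di[keep], dj[keep])
}

# Sum of `v` over the disc neighborhood of each cell, via shifted adds.
# NA cells contribute 0; `counts` returns the number of in-extent, non-NA
# cells in each neighborhood.
disc_sum <- function(v, offsets) {
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  vz <- v; vz[is.na(vz)] <- 0
  ok <- !is.na(v)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets[k, 1L]; dj <- offsets[k, 2L]
    src_r <- max(1L, 1L + di):min(nr, nr + di)
    src_c <- max(1L, 1L + dj):min(nc, nc + dj)
    dst_r <- src_r - di; dst_c <- src_c - dj
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + vz[src_r, src_c]
    cnt[dst_r, dst_c] <- cnt[dst_r, dst_c] + ok[src_r, src_c]
  }
  list(sum = acc, count = cnt)
}

#' Focal (moving-window) density of a binary class
#'
#' Proportion of cells whose centers fall within `radius_m` of the focal
#' cell's center that are true. Edge windows use only in-extent cells, so the
#' output is always a proportion in `[0, 1]`. The same operation serves
#' "local" (0.5 km) and "neighborhood" (1.5 km) density variables through the
#' radius parameter.
#'
#' @param mask binary `grid_raster`.
#' @param radius_m window radius in metres (>= cell size).
#' @return `grid_raster` of proportions.
#' @export
focal_density <- function(mask, radius_m) {
  if (radius_m < mask$cellsize)
    stop("radius must be at least one cell size")
  off <- disc_offsets(radius_m / mask$cellsize)
  ds <- disc_sum((mask$values != 0) * 1, off)
  out <- ds$sum / pmax(ds$count, 1L)
  out[is.na(mask$values)] <- NA_real_
  grid_raster(out, mask$cellsize, mask$xll, mask$yll, mask$crs)
}

#' Terrain ruggedness index
#'
#' Root of the average squared elevation difference between each cell and its
#' eight neighbors. Boundary cells average over the neighbors that exist.
#'
#' @param elevation `grid_raster` of elevation (m).
#' @return `grid_raster` of TRI values (>= 0).
#' @export
tri <- function(elevation) {
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    src_r <- max(1L, 1L + di):min(nr, nr + di)
    src_c <- max(1L, 1L + dj):min(nc, nc + dj)
    dst_r <- src_r - di; dst_c <- src_c - dj
    dz <- z[src_r, src_c, drop = FALSE] - z[dst_r, dst_c, drop = FALSE]
    ok <- !is.na(dz)
    dz[!ok] <- 0
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + dz^2
    cnt[dst_r, dst_c] <- cnt[dst_r, dst_c] + ok
  }
  out <- sqrt(acc / pmax(cnt, 1L))
  out[is.na(z)] <- NA_real_
  grid_raster(out, elevation$cellsize, elevation$xll, elevation$yll,
              elevation$crs)
}

#' Label 4-connected patches of a binary class
#'
#' Flood-fill labeling of rook-connected components of the non-zero cells.
#'
#' @param mask binary `grid_raster`.
#' @return `grid_raster` of integer patch labels (0 = background).
#' @export
label_patches <- function(mask) {
  m <- mask$values
  nr <- nrow(m); nc <- ncol(m)
  fg <- !is.na(m) & m != 0
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(nr * nc)
  for (start in which(fg & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      if (i > 1L) { q <- p - 1L
        if (fg[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (i < nr) { q <- p + 1L
        if (fg[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (j > 1L) { q <- p - nr
        if (fg[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (j < nc) { q <- p + nr
        if (fg[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
    }
  }
  grid_raster(lab, mask$cellsize, mask$xll, mask$yll, mask$crs)
}

#' Patch shape index
#'
#' Normalized edge-to-area ratio of each 4-connected patch:
#' `SHAPE = 0.25 * P / sqrt(A)` with `P` the perimeter in cell-edge units
#' (exterior plus interior edges against non-patch cells) and `A` the patch
#' area in cells. A square patch scores exactly 1 and every patch scores at
#' least 1. Also returns the area-weighted mean across patches.
#'
#' @param patches labeled `grid_raster` (as from [label_patches()]), or a
#'   binary raster which will be labeled first.
#' @return list with `per_patch` (data.frame: `patch`, `area_cells`,
#'   `perimeter_edges`, `shape`) and `area_weighted_mean`.
#' @export
shape_index <- function(patches) {
  lab <- patches$values
  if (all(lab %in% c(0, 1, NA))) lab <- label_patches(patches)$values
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) stop("no patch cells in input")
  nr <- nrow(lab); nc <- ncol(lab)
  lab0 <- lab; lab0[is.na(lab0)] <- 0L
  area <- tabulate(lab0, nbins = max(ids))
  # shared edges between like-labeled rook neighbors
  shared <- integer(max(ids))
  h <- lab0[, -nc, drop = FALSE] == lab0[, -1L, drop = FALSE] &
    lab0[, -nc, drop = FALSE] > 0L
  if (any(h)) {
    t_h <- tabulate(lab0[, -nc, drop = FALSE][h], nbins = max(ids))
    shared <- shared + t_h
  }
  v <- lab0[-nr, , drop = FALSE] == lab0[-1L, , drop = FALSE] &
    lab0[-nr, , drop = FALSE] > 0L
  if (any(v)) {
    t_v <- tabulate(lab0[-nr, , drop = FALSE][v], nbins = max(ids))
    shared <- shared + t_v
  }
  per <- 4L * area - 2L * shared
  df <- data.frame(patch = ids, area_cells = area[ids],
                   perimeter_edges = per[ids],
                   shape = 0.25 * per[ids] / sqrt(area[ids]))
  list(per_patch = df,
       area_weighted_mean = sum(df$shape * df$area_cells) /
         sum(df$area_cells))
}

#' Patch contiguity surface
#'
#' Per-cell contiguity of a binary patch class. Each patch cell gets a
#' 3 x 3 template score (orthogonal neighbors weight 2, diagonals 1, the
#' cell itself 1, only same-patch cells counted), normalized so that an
#' isolated cell scores 0 and a fully surrounded cell scores 1:
#' `(template_sum - 1) / 12`. The output raster averages these per-cell
#' scores over the patch cells inside a local circular window of
#' `window_area_km2`; cells whose window contains no patch cell score 0.
#'
#' @param patches binary `grid_raster` of the class of interest.
#' @param window_area_km2 window area (km^2); radius is
#'   `sqrt(area / pi)`.
#' @return `grid_raster` in `[0, 1]`.
#' @export
contiguity <- function(patches, window_area_km2 = 0.5) {
  cs <- patches$cellsize
  radius_m <- sqrt(window_area_km2 * 1e6 / pi)
  if (radius_m < cs / 2) stop("window smaller than one cell")
  lab <- label_patches(patches)$values
  nr <- nrow(lab); nc <- ncol(lab)
  fg <- lab > 0L
  # per-cell template sum restricted to same-patch neighbors
  tmpl <- matrix(0, nr, nc)
  tmpl[fg] <- 1  # center weight
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    w <- if (di == 0L || dj == 0L) 2 else 1
    src_r <- max(1L, 1L + di):min(nr, nr + di)
    src_c <- max(1L, 1L + dj):min(nc, nc + dj)
    dst_r <- src_r - di; dst_c <- src_c - dj
    same <- lab[src_r, src_c, drop = FALSE] ==
      lab[dst_r, dst_c, drop = FALSE] &
      lab[dst_r, dst_c, drop = FALSE] > 0L
    add <- matrix(0, length(dst_r), length(dst_c))
    add[same] <- w
    tmpl[dst_r, dst_c] <- tmpl[dst_r, dst_c] + add
  }
  score <- matrix(0, nr, nc)
  score[fg] <- (tmpl[fg] - 1) / 12
  # window average of scores over patch cells only
  off <- disc_offsets(max(1, radius_m / cs))
  num <- disc_sum(ifelse(fg, score, NA), off)
  out <- ifelse(num$count > 0L, num$sum / num$count, 0)
  out[is.na(patches$values)] <- NA_real_
  grid_raster(out, cs, patches$xll, patches$yll, patches$crs)
}

#' Build a named covariate stack
#'
#' Thin container tying named rasters to per-variable metadata; all rasters
#' must share one grid.
#'
#' @param rasters named list of `grid_raster`.
#' @param types optional named character vector
#'   (`distance|density|terrain|shape|other`).
#' @return list of class `covariate_stack` with `rasters`, `types`, and a
#'   `correlation` slot filled by [correlation_screen()].
#' @export
covariate_stack <- function(rasters, types = NULL) {
  if (is.null(names(rasters)) || anyDuplicated(names(rasters)))
    stop("rasters must be uniquely named")
  for (r in rasters[-1]) stop_unless_same_grid(rasters[[1]], r)
  structure(list(rasters = rasters, types = types, correlation = NULL),
            class = "covariate_stack")
}

#' Pairwise correlation screen over a covariate stack
#'
#' Pearson correlations over cells that are non-nodata in every variable.
#' Pairs at or above the threshold in absolute value are flagged; the usual
#' convention in this field excludes flagged pairs from the same model.
#' Zero-variance variables are reported as degenerate and excluded from the
#' pairwise screen.
#'
#' @param stack a [covariate_stack()].
#' @param threshold absolute correlation cutoff (default 0.7).
#' @return the stack with `correlation` (matrix), `flagged_pairs`
#'   (data.frame `var1`, `var2`, `r`) and `degenerate` (character) filled.
#' @export
correlation_screen <- function(stack, threshold = 0.7) {
  nms <- names(stack$rasters)
  if (length(nms) < 2L) stop("need at least two variables")
  vals <- sapply(stack$rasters, function(r) as.vector(r$values))
  ok <- stats::complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]
  sds <- apply(vals, 2L, stats::sd)
  degen <- nms[sds == 0 | is.na(sds)]
  live <- setdiff(nms, degen)
  r <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  diag(r) <- 1
  if (length(live) >= 2L)
    r[live, live] <- stats::cor(vals[, live, drop = FALSE])
  pairs <- list()
  if (length(live) >= 2L) {
    for (i in seq_along(live)[-length(live)]) for (j in (i + 1L):length(live)) {
      rij <- r[live[i], live[j]]
      if (abs(rij) >= threshold)
        pairs[[length(pairs) + 1L]] <- data.frame(var1 = live[i],
                                                  var2 = live[j], r = rij,
                                                  stringsAsFactors = FALSE)
    }
  }
  stack$correlation <- r
  stack$flagged_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(var1 = character(0), var2 = character(0), r = numeric(0))
  stack$degenerate <- degen
  stack$threshold <- threshold
  stack
}

#' Engineer the standard covariate stack from a synthetic landscape
#'
#' Derives the habitat variables the analysis uses from a landscape's land
#' cover and elevation — distance to natural vegetation, local (0.5 km
#' radius) and neighborhood (1.5 km radius) densities, TRI, natural
#' vegetation shape/contiguity — and appends the landscape's continuous
#' fields. This is the stack the models are fitted on.
#'
#' @param landscape a `landscape`.
#' @param local_radius_m,neigh_radius_m moving-window radii (m).
#' @return a [covariate_stack()].
#' @export
build_covariates <- function(landscape, local_radius_m = 500,
                             neigh_radius_m = 1500) {
  lc <- landscape$landcover
  natural <- map_values(lc, function(v) (v == LC_NATURAL) * 1)
  agric <- map_values(lc, function(v) (v == LC_AGRICULTURE) * 1)
  wetland <- map_values(lc, function(v) (v == LC_WETLAND) * 1)
  urban <- map_values(lc, function(v) (v == LC_URBAN) * 1)
  rasters <- list(
    dist_natural = euclidean_distance(natural),
    agric_density = focal_density(agric, local_radius_m),
    wetland_density = focal_density(wetland, neigh_radius_m),
    urban_density = focal_density(urban, neigh_radius_m),
    tri = tri(landscape$elevation),
    elevation = landscape$elevation,
    natural_contig = contiguity(natural))
  for (nm in names(landscape$covariates))
    rasters[[nm]] <- landscape$covariates[[nm]]
  covariate_stack(rasters,
                  types = c(dist_natural = "distance",
                            agric_density = "density",
                            wetland_density = "density",
                            urban_density = "density",
                            tri = "terrain", elevation = "terrain",
                            natural_contig = "shape"))
}

#' Write a correlation matrix to CSV
#'
#' @param stack a screened [covariate_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(stack, path) {
  if (is.null(stack$correlation)) stop("run correlation_screen() first")
  utils::write.csv(stack$correlation, path)
  invisible(path)
}
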