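#' Cellwise average of suitability surfaces
#'
#' The consensus operation: arithmetic mean of the iteration surfaces
#' (e.g. all Maxent and Mahalanobis folds for one extent). A cell is nodata
#' if any input is nodata there, so the consensus never extrapolates beyond
#' the common footprint.
#'
#' @param surfaces list of `grid_raster` on one grid (>= 1 surface).
#' @return a `grid_raster`.
#' @export
average_surfaces <- function(surfaces) {
  if (!length(surfaces)) stop("need at least one surface")
  ref <- surfaces[[1]]
  for (s in surfaces[-1]) stop_unless_same_grid(ref, s)
  acc <- surfaces[[1]]$values
  for (s in surfaces[-1]) acc <- acc + s$values
  grid_raster(acc / length(surfaces), ref$cellsize, ref$xll, ref$yll,
              ref$crs)
}

#' Threshold a continuous surface into a binary habitat map
#'
#' Habitat is `value >= t` (the threshold value itself counts as habitat, so
#' binary maps are bit-reproducible); nodata is preserved.
#'
#' @param continuous a `grid_raster`.
#' @param t finite threshold.
#' @return binary `grid_raster`.
#' @export
apply_threshold <- function(continuous, t) {
  if (!is.finite(t)) stop("threshold must be finite")
  map_values(continuous, function(v) (v >= t) * 1)
}

#' Consensus output for one extent
#'
#' Averages iteration surfaces, averages the per-iteration max-SSS
#' thresholds (unrounded), and applies the mean threshold to the mean
#' surface.
#'
#' @param surfaces list of continuous `grid_raster` (all iterations).
#' @param thresholds numeric vector of per-iteration thresholds (from the
#'   Maxent iterations).
#' @param scale label, e.g. `"state"` or `"local"`.
#' @return list of class `consensus_output`: `continuous`, `threshold`,
#'   `binary`, `scale`.
#' @export
consensus_output <- function(surfaces, thresholds, scale = "state") {
  continuous <- average_surfaces(surfaces)
  thr <- mean(thresholds)
  structure(list(continuous = continuous, threshold = thr,
                 binary = apply_threshold(continuous, thr), scale = scale),
            class = "consensus_output")
}

#' Mosaic per-unit surfaces into one statewide raster
#'
#' Every cell takes its value from the surface of the management unit that
#' contains it; the 20-km buffers used to fit local models are context only
#' and are trimmed here, so no cell is covered twice. An error is raised if
#' a cell's unit has no surface.
#'
#' @param unit_outputs named list of `grid_raster`, one per unit label
#'   (names are the labels as character).
#' @param units `grid_raster` of integer unit labels partitioning the
#'   extent.
#' @return a `grid_raster`.
#' @export
mosaic_units <- function(unit_outputs, units) {
  ref <- unit_outputs[[1]]
  stop_unless_same_grid(ref, units)
  for (s in unit_outputs[-1]) stop_unless_same_grid(ref, s)
  lab <- units$values
  present <- sort(unique(lab[!is.na(lab)]))
  missing <- setdiff(as.character(present), names(unit_outputs))
  if (length(missing))
    stop("no surface supplied for unit(s): ", paste(missing, collapse = ", "))
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  for (u in present) {
    sel <- !is.na(lab) & lab == u
    out[sel] <- unit_outputs[[as.character(u)]]$values[sel]
  }
  grid_raster(out, ref$cellsize, ref$xll, ref$yll, ref$crs)
}

#' Combine local- and state-scale binary maps into habitat categories
#'
#' Codes: 0 no habitat, 1 local-only, 2 state-only, 3 both scales
#' (`1 * local + 2 * state`, a weighted sum so the two single-scale classes
#' stay distinguishable). The area table is in km^2 with
#' `cell area = (cellsize / 1000)^2`.
#'
#' @param local_binary,state_binary binary `grid_raster` on one grid.
#' @return list of class `category_map`: `raster`, `areas` (data.frame
#'   `code`, `category`, `km2`).
#' @export
combine_scales <- function(local_binary, state_binary) {
  stop_unless_same_grid(local_binary, state_binary)
  lv <- local_binary$values; sv <- state_binary$values
  code <- 1 * (lv != 0) + 2 * (sv != 0)
  code[is.na(lv) | is.na(sv)] <- NA
  r <- grid_raster(code, local_binary$cellsize, local_binary$xll,
                   local_binary$yll, local_binary$crs)
  cell_km2 <- (local_binary$cellsize / 1000)^2
  areas <- data.frame(
    code = 0:3,
    category = c("none", "local_only", "state_only", "both"),
    km2 = vapply(0:3, function(k) sum(code == k, na.rm = TRUE) * cell_km2,
                 numeric(1)))
  structure(list(raster = r, areas = areas), class = "category_map")
}

#' Cumulative-frequency display bins from presence locations
#'
#' Reclassifies a continuous consensus surface into 10 ordered bins whose
#' boundaries are the deciles of the suitability values at the presence
#' points, so each bin holds (up to ties) 10% of the presence locations —
#' the standard display convention for cumulative-frequency habitat maps.
#'
#' @param continuous a `grid_raster`.
#' @param presence data.frame of points (`x`, `y`) on non-nodata cells.
#' @param step bin share (default 0.10).
#' @return list with `raster` (integer bins 1..`1/step`), `breaks`
#'   (quantile boundaries), `table` (per-bin presence share).
#' @export
cumulative_frequency_bins <- function(continuous, presence, step = 0.10) {
  sp <- extract_values(continuous, presence$x, presence$y)
  sp <- sp[!is.na(sp)]
  nb <- round(1 / step)
  if (length(sp) < nb) stop("fewer presences than bins")
  qs <- stats::quantile(sp, probs = seq(step, 1 - step, by = step),
                        names = FALSE, type = 7)
  binned <- map_values(continuous, function(v) {
    b <- findInterval(v, qs) + 1
    b[is.na(v)] <- NA
    b
  })
  shares <- vapply(seq_len(nb), function(b) {
    lo <- if (b == 1) -Inf else qs[b - 1]
    hi <- if (b == nb) Inf else qs[b]
    mean(sp > lo & sp <= hi)
  }, numeric(1))
  list(raster = binned, breaks = qs,
       table = data.frame(bin = seq_len(nb), presence_share = shares))
}
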