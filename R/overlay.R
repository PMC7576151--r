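#' Overlap of a habitat map with a threat or protection mask
#'
#' Cell-counting overlay: the overlap area is the number of cells that are
#' habitat and inside the mask times the cell area, and the percentage is
#' `100 * overlap / habitat area`. Undefined percentages (zero habitat) are
#' reported as `NA`.
#'
#' @param habitat binary `grid_raster`, or categorical with `value` naming
#'   the code to treat as habitat.
#' @param mask binary `grid_raster` on the same grid.
#' @param value optional habitat code for categorical inputs.
#' @return list with `overlap_km2`, `habitat_km2`, `percent`.
#' @export
overlay_area <- function(habitat, mask, value = NULL) {
  stop_unless_same_grid(habitat, mask)
  hv <- habitat$values
  hab <- if (is.null(value)) !is.na(hv) & hv != 0 else !is.na(hv) & hv == value
  mv <- mask$values
  inmask <- !is.na(mv) & mv != 0
  cell_km2 <- (habitat$cellsize / 1000)^2
  hab_km2 <- sum(hab) * cell_km2
  ov_km2 <- sum(hab & inmask) * cell_km2
  list(overlap_km2 = ov_km2, habitat_km2 = hab_km2,
       percent = overlay_percent(ov_km2, hab_km2))
}

#' Percentage of a habitat area covered by an overlap area
#'
#' The arithmetic behind every threat-table percentage:
#' `100 * overlap / habitat`, `NA` when the habitat area is zero.
#'
#' @param overlap_km2,habitat_km2 areas in km^2.
#' @return percentage on the 0-100 scale.
#' @export
overlay_percent <- function(overlap_km2, habitat_km2) {
  ifelse(habitat_km2 > 0, 100 * overlap_km2 / habitat_km2, NA_real_)
}

#' Round half-up to a number of decimals
#'
#' Report-formatting convention: 0.005 rounds to 0.01 (base R's `round()`
#' rounds half to even). Raw unrounded values are kept in machine outputs.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Unprotected share of a habitat map
#'
#' Complement overlay: habitat outside the protected mask. Protected and
#' unprotected areas partition the habitat exactly.
#'
#' @param habitat binary (or categorical, with `value`) `grid_raster`.
#' @param protected_mask binary `grid_raster`.
#' @param value optional habitat code.
#' @return list with `unprotected_km2`, `protected_km2`, `habitat_km2`,
#'   `percent_unprotected`.
#' @export
protection_gap <- function(habitat, protected_mask, value = NULL) {
  stop_unless_same_grid(habitat, protected_mask)
  hv <- habitat$values
  hab <- if (is.null(value)) !is.na(hv) & hv != 0 else !is.na(hv) & hv == value
  pv <- protected_mask$values
  prot <- !is.na(pv) & pv != 0
  cell_km2 <- (habitat$cellsize / 1000)^2
  hab_km2 <- sum(hab) * cell_km2
  un_km2 <- sum(hab & !prot) * cell_km2
  list(unprotected_km2 = un_km2, protected_km2 = hab_km2 - un_km2,
       habitat_km2 = hab_km2,
       percent_unprotected = overlay_percent(un_km2, hab_km2))
}

#' Three-way overlap of habitat with two masks
#'
#' Area of `habitat AND mask_a AND mask_b` with percentages against each
#' stated denominator: the habitat area, the habitat-and-a area, and the
#' habitat-and-b area (e.g. unprotected habitat that also overlaps projected
#' development).
#'
#' @param habitat binary (or categorical, with `value`) `grid_raster`.
#' @param mask_a,mask_b binary `grid_raster`s.
#' @param value optional habitat code.
#' @return list with `overlap_km2` and named percentages
#'   `percent_of_habitat`, `percent_of_habitat_a`, `percent_of_habitat_b`.
#' @export
compound_overlap <- function(habitat, mask_a, mask_b, value = NULL) {
  stop_unless_same_grid(habitat, mask_a)
  stop_unless_same_grid(habitat, mask_b)
  hv <- habitat$values
  hab <- if (is.null(value)) !is.na(hv) & hv != 0 else !is.na(hv) & hv == value
  a <- !is.na(mask_a$values) & mask_a$values != 0
  b <- !is.na(mask_b$values) & mask_b$values != 0
  cell_km2 <- (habitat$cellsize / 1000)^2
  ov <- sum(hab & a & b) * cell_km2
  list(overlap_km2 = ov,
       percent_of_habitat = overlay_percent(ov, sum(hab) * cell_km2),
       percent_of_habitat_a = overlay_percent(ov, sum(hab & a) * cell_km2),
       percent_of_habitat_b = overlay_percent(ov, sum(hab & b) * cell_km2))
}

#' Threat-and-protection accounting table
#'
#' Builds the threat-table analogue for a combined category map: for each
#' habitat class (local = local-only plus both, state = state-only plus
#' both, both, combined = any habitat) and each supplied mask, the overlap
#' area in km^2 and the percentage of the class area; protection masks are
#' reported as the unprotected complement.
#'
#' @param category a `category_map` from [combine_scales()].
#' @param masks named list of binary `grid_raster`s.
#' @param protection_names names in `masks` to report as unprotected
#'   complements rather than direct overlaps.
#' @return data.frame with columns `habitat_class`, `layer`, `class_km2`,
#'   `overlap_km2`, `percent`.
#' @export
overlay_report <- function(category, masks,
                           protection_names = "protection") {
  cat_r <- category$raster
  classes <- list(
    local = map_values(cat_r, function(v) (v %in% c(1, 3)) * 1),
    state = map_values(cat_r, function(v) (v %in% c(2, 3)) * 1),
    both = map_values(cat_r, function(v) (v == 3) * 1),
    combined = map_values(cat_r, function(v) (v > 0) * 1))
  rows <- list()
  for (cls in names(classes)) {
    for (ly in names(masks)) {
      if (ly %in% protection_names) {
        pg <- protection_gap(classes[[cls]], masks[[ly]])
        rows[[length(rows) + 1L]] <- data.frame(
          habitat_class = cls, layer = paste0("unprotected"),
          class_km2 = pg$habitat_km2, overlap_km2 = pg$unprotected_km2,
          percent = pg$percent_unprotected, stringsAsFactors = FALSE)
      } else {
        oa <- overlay_area(classes[[cls]], masks[[ly]])
        rows[[length(rows) + 1L]] <- data.frame(
          habitat_class = cls, layer = ly, class_km2 = oa$habitat_km2,
          overlap_km2 = oa$overlap_km2, percent = oa$percent,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
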