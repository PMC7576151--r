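#' Simulation configuration for synthetic landscapes and telemetry
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' the study conditions used throughout the package's tests and the
#' end-to-end run: a 200 x 200 grid of 120 m cells (the analysis resolution),
#' spatially autocorrelated covariates, and a mixed VHF/GPS telemetry sample
#' with enough temporal depth that the screening rules (12-month window,
#' distinct months) are non-trivially exercised.
#'
#' @param nrows,ncols grid dimensions.
#' @param cellsize cell side (m); 120 m is the analysis resolution.
#' @param corr_range_cells autocorrelation range of the Gaussian covariate
#'   fields, in cells (exponential covariance).
#' @param n_animals number of collared animals.
#' @param fixes_per_animal GPS fixes per animal before screening.
#' @param fix_interval_h GPS fix interval (hours).
#' @param vhf_interval_h VHF fix interval (hours); VHF animals are tracked at
#'   this coarser cadence over a comparable duration.
#' @param frac_vhf fraction of animals wearing VHF collars.
#' @param juvenile_fraction fraction of animals younger than 4 years.
#' @param dop_meanlog,dop_sdlog lognormal DOP parameters (median
#'   `exp(dop_meanlog)`); the default median 2, sigma 0.6 leaves a nontrivial
#'   tail above the DOP > 7 screen.
#' @param dop_noise_scale positional noise (m) added per DOP unit on GPS
#'   fixes; VHF fixes get a fixed 100 m triangulation error.
#' @param step_sd step-length scale of the movement walk (m).
#' @param mortality_prob probability an animal's record ends in a mortality
#'   event.
#' @param n_units number of management-unit regions (Voronoi partition).
#' @param truth_coefficients named per-covariate weights of the virtual
#'   species (logit scale).
#' @param truth_intercept logit-scale intercept of the virtual species.
#' @param seed integer seed; the seed fully determines all generator output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(nrows = 200, ncols = 200, cellsize = 120,
                       corr_range_cells = 12,
                       n_animals = 35, fixes_per_animal = 1200,
                       fix_interval_h = 2, vhf_interval_h = 48,
                       frac_vhf = 0.2, juvenile_fraction = 0.15,
                       dop_meanlog = log(2), dop_sdlog = 0.6,
                       dop_noise_scale = 10, step_sd = 600,
                       mortality_prob = 0.1, n_units = 4,
                       truth_coefficients = c(greenness = 6,
                                              wetness = -4,
                                              ruggedness = 3),
                       truth_intercept = -8,
                       seed = 1L) {
  if (cellsize <= 0) stop("cell size must be positive")
  if (nrows < 2 || ncols < 2) stop("grid must be at least 2 x 2")
  cfg <- list(nrows = nrows, ncols = ncols, cellsize = cellsize,
              corr_range_cells = corr_range_cells, n_animals = n_animals,
              fixes_per_animal = fixes_per_animal,
              fix_interval_h = fix_interval_h,
              vhf_interval_h = vhf_interval_h, frac_vhf = frac_vhf,
              juvenile_fraction = juvenile_fraction,
              dop_meanlog = dop_meanlog, dop_sdlog = dop_sdlog,
              dop_noise_scale = dop_noise_scale, step_sd = step_sd,
              mortality_prob = mortality_prob, n_units = n_units,
              truth_coefficients = truth_coefficients,
              truth_intercept = truth_intercept, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Spatially autocorrelated Gaussian random field
#'
#' Simulates a stationary zero-mean, unit-variance Gaussian field with an
#' exponential covariance `exp(-d / range)` by spectral (FFT) synthesis on
#' the torus. With `corr_range_cells = 0` the field degenerates to i.i.d.
#' white noise. Output is standardized to exact zero mean and unit variance.
#'
#' @param nrows,ncols grid dimensions.
#' @param corr_range_cells covariance range in cells (>= 0).
#' @param seed integer seed; the same arguments always give the same field.
#' @param cellsize,xll,yll georeference of the returned raster.
#' @return a `grid_raster`.
#' @export
gen_gaussian_field <- function(nrows, ncols, corr_range_cells, seed,
                               cellsize = 120, xll = 0, yll = 0) {
  if (nrows < 1 || ncols < 1) stop("grid dimensions must be positive")
  if (corr_range_cells < 0) stop("correlation range must be >= 0")
  set.seed(as.integer(seed))
  if (corr_range_cells == 0) {
    z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  } else {
    # toroidal distance kernel -> covariance -> spectral synthesis
    di <- pmin(0:(nrows - 1), nrows - (0:(nrows - 1)))
    dj <- pmin(0:(ncols - 1), ncols - (0:(ncols - 1)))
    d <- sqrt(outer(di^2, dj^2, "+"))
    covk <- exp(-d / corr_range_cells)
    spec <- Re(stats::fft(covk))
    spec[spec < 0] <- 0
    white <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
    z <- Re(stats::fft(sqrt(spec) * stats::fft(white), inverse = TRUE)) /
      (nrows * ncols)
  }
  z <- (z - mean(z)) / stats::sd(z)
  grid_raster(z, cellsize, xll, yll)
}

#' Virtual-species truth surface
#'
#' Builds the ground-truth habitat suitability of a virtual species as the
#' inverse-logit of a linear combination of landscape covariates:
#' `suitability(x) = plogis(intercept + sum_i beta_i * cov_i(x))`. The known
#' coefficients make downstream parameter-recovery tests possible.
#'
#' @param landscape a landscape list with a `covariates` element (named list
#'   of `grid_raster`), as built by [make_landscape()].
#' @param coefficients named numeric vector; names must match covariates.
#' @param intercept scalar intercept on the logit scale.
#' @return a `grid_raster` with values in (0, 1).
#' @export
gen_virtual_species <- function(landscape, coefficients, intercept = 0) {
  unknown <- setdiff(names(coefficients), names(landscape$covariates))
  if (length(unknown))
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  ref <- landscape$covariates[[1]]
  eta <- matrix(intercept, nrow(ref$values), ncol(ref$values))
  for (nm in names(coefficients)) {
    eta <- eta + coefficients[[nm]] * landscape$covariates[[nm]]$values
  }
  grid_raster(stats::plogis(eta), ref$cellsize, ref$xll, ref$yll, ref$crs)
}

# Elevation with a west-east gradient plus autocorrelated relief; the west
# edge dips below sea level so inundation masks have somewhere to bite.
gen_elevation <- function(cfg, seed) {
  relief <- gen_gaussian_field(cfg$nrows, cfg$ncols, cfg$corr_range_cells,
                               seed, cfg$cellsize)
  grad <- matrix(rep(seq(-2, 12, length.out = cfg$ncols), each = cfg$nrows),
                 cfg$nrows, cfg$ncols)
  grid_raster(3 * relief$values + grad, cfg$cellsize)
}

# Integer land-cover classes: 1 natural, 2 agriculture, 3 urban, 4 wetland,
# 5 water. Driven by elevation plus two independent autocorrelated fields.
LC_NATURAL <- 1L; LC_AGRICULTURE <- 2L; LC_URBAN <- 3L
LC_WETLAND <- 4L; LC_WATER <- 5L

gen_landcover <- function(cfg, elevation, seed) {
  afield <- gen_gaussian_field(cfg$nrows, cfg$ncols,
                               max(4, cfg$corr_range_cells / 2),
                               seed + 1L, cfg$cellsize)$values
  ufield <- gen_gaussian_field(cfg$nrows, cfg$ncols,
                               max(3, cfg$corr_range_cells / 4),
                               seed + 2L, cfg$cellsize)$values
  lc <- matrix(LC_NATURAL, cfg$nrows, cfg$ncols)
  elev <- elevation$values
  lc[afield > stats::quantile(afield, 0.75)] <- LC_AGRICULTURE
  lc[ufield > stats::quantile(ufield, 0.95)] <- LC_URBAN
  lc[elev >= 0 & elev < 0.8] <- LC_WETLAND
  lc[elev < 0] <- LC_WATER
  grid_raster(lc, cfg$cellsize)
}

#' Voronoi partition of the grid into management units
#'
#' Draws `k` seed points uniformly over the extent and labels every cell by
#' its nearest seed (cell-center Euclidean distance, ties to the lowest
#' label). The resulting regions are the local-scale modeling units
#' (management-unit analogues): they cover the extent and do not overlap.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a `grid_raster` of integer labels `1..k`.
#' @export
gen_units <- function(cfg, seed) {
  set.seed(as.integer(seed))
  k <- cfg$n_units
  sx <- stats::runif(k, 0, cfg$ncols * cfg$cellsize)
  sy <- stats::runif(k, 0, cfg$nrows * cfg$cellsize)
  tmp <- grid_raster(matrix(0, cfg$nrows, cfg$ncols), cfg$cellsize)
  cc <- cell_centers(tmp)
  d2 <- outer(cc$x, sx, "-")^2 + outer(cc$y, sy, "-")^2
  lab <- max.col(-d2, ties.method = "first")
  grid_raster(matrix(lab, cfg$nrows, cfg$ncols), cfg$cellsize)
}

#' Generate a complete synthetic landscape
#'
#' Assembles the pieces every downstream stage needs: continuous
#' autocorrelated covariates (`greenness`, `wetness`, `ruggedness`), integer
#' land cover, elevation (m), a Voronoi unit partition, and the virtual
#' species truth surface with its known coefficients.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `landscape` with elements `covariates`,
#'   `landcover`, `elevation`, `units`, `truth_suitability`,
#'   `truth_coefficients`, `truth_intercept`, `config`.
#' @export
make_landscape <- function(cfg = sim_config()) {
  base_seed <- cfg$seed
  covs <- list()
  cov_names <- names(cfg$truth_coefficients)
  for (i in seq_along(cov_names)) {
    covs[[cov_names[i]]] <- gen_gaussian_field(
      cfg$nrows, cfg$ncols, cfg$corr_range_cells,
      base_seed + 10L + i, cfg$cellsize)
  }
  elevation <- gen_elevation(cfg, base_seed + 20L)
  landcover <- gen_landcover(cfg, elevation, base_seed + 30L)
  units <- gen_units(cfg, base_seed + 40L)
  ls <- list(covariates = covs, landcover = landcover,
             elevation = elevation, units = units,
             truth_coefficients = cfg$truth_coefficients,
             truth_intercept = cfg$truth_intercept, config = cfg)
  ls$truth_suitability <- gen_virtual_species(ls, cfg$truth_coefficients,
                                              cfg$truth_intercept)
  class(ls) <- "landscape"
  ls
}

#' Simulate habitat-biased telemetry from a landscape truth surface
#'
#' Each animal performs a correlated random walk whose proposed steps are
#' accepted with probability proportional to the destination cell's truth
#' suitability (rejection sampling), so the marginal distribution of fixes is
#' enriched in high-suitability cells. Fixes carry exact-interval timestamps,
#' collar type, lognormal DOP (GPS only), fix status, age, a capture record
#' at the first fix and an optional terminal mortality record. Observed
#' coordinates include DOP-scaled positional noise.
#'
#' @param landscape a `landscape` with `truth_suitability`.
#' @param cfg a [sim_config()].
#' @return a data.frame of fixes with columns `animal_id`, `timestamp`
#'   (POSIXct UTC), `x`, `y`, `collar`, `dop`, `fix_status`, `event`,
#'   `age_years`.
#' @export
simulate_telemetry <- function(landscape, cfg = landscape$config) {
  if (is.null(landscape$truth_suitability))
    stop("landscape has no truth_suitability")
  if (cfg$n_animals <= 0) stop("n_animals must be positive")
  set.seed(cfg$seed + 100L)
  suit <- landscape$truth_suitability$values
  nr <- nrow(suit); nc <- ncol(suit)
  cs <- cfg$cellsize
  xmax <- nc * cs; ymax <- nr * cs
  smax <- max(suit)
  # start positions drawn from the suitability surface itself
  start_idx <- sample.int(nr * nc, cfg$n_animals, replace = TRUE,
                          prob = as.vector(suit))
  out <- vector("list", cfg$n_animals)
  t0_base <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")
  for (a in seq_len(cfg$n_animals)) {
    collar <- if (stats::runif(1) < cfg$frac_vhf) "VHF" else "GPS"
    juvenile <- stats::runif(1) < cfg$juvenile_fraction
    age <- if (juvenile) stats::runif(1, 1.5, 3.9) else stats::runif(1, 4, 12)
    interval <- if (collar == "GPS") cfg$fix_interval_h else cfg$vhf_interval_h
    n_fix <- if (collar == "GPS") cfg$fixes_per_animal else
      max(40L, ceiling(cfg$fixes_per_animal * cfg$fix_interval_h /
                         cfg$vhf_interval_h))
    # stagger deployments across two years
    t0 <- t0_base + stats::runif(1, 0, 730) * 86400
    row0 <- (start_idx[a] - 1L) %% nr + 1L
    col0 <- (start_idx[a] - 1L) %/% nr + 1L
    px <- (col0 - 0.5) * cs
    py <- (nr - row0 + 0.5) * cs
    xs <- numeric(n_fix); ys <- numeric(n_fix)
    for (i in seq_len(n_fix)) {
      # rejection sampling: propose steps until one is accepted with
      # probability proportional to the destination cell's suitability
      for (try in 1:200) {
        qx <- px + stats::rnorm(1, 0, cfg$step_sd)
        qy <- py + stats::rnorm(1, 0, cfg$step_sd)
        if (qx < 0 || qx >= xmax || qy < 0 || qy >= ymax) next
        r <- nr - floor(qy / cs); c <- floor(qx / cs) + 1L
        if (stats::runif(1) < suit[r, c] / smax) { px <- qx; py <- qy; break }
      }
      xs[i] <- px; ys[i] <- py
    }
    ts <- t0 + (seq_len(n_fix) - 1L) * interval * 3600
    if (collar == "GPS") {
      dop <- stats::rlnorm(n_fix, cfg$dop_meanlog, cfg$dop_sdlog)
      status <- ifelse(stats::runif(n_fix) < 0.9, "3D", "2D")
      err <- cfg$dop_noise_scale * dop
    } else {
      dop <- rep(NA_real_, n_fix)
      status <- rep(NA_character_, n_fix)
      err <- rep(100, n_fix)
    }
    xs_obs <- xs + stats::rnorm(n_fix, 0, err)
    ys_obs <- ys + stats::rnorm(n_fix, 0, err)
    event <- rep("normal", n_fix)
    event[1] <- "capture"
    if (stats::runif(1) < cfg$mortality_prob) event[n_fix] <- "mortality"
    out[[a]] <- data.frame(
      animal_id = sprintf("A%03d", a), timestamp = ts,
      x = xs_obs, y = ys_obs, collar = collar, dop = dop,
      fix_status = status, event = event, age_years = age,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Threat and protection masks for a synthetic landscape
#'
#' Builds binary masks on the landscape grid: sea-level-rise inundation
#' (elevation below each level), projected development (Bernoulli draws with
#' probability decaying with distance from existing urban cells, mean
#' `dev_fraction` over non-water cells), and protected areas (Bernoulli draws
#' over natural cells weighted by an autocorrelated field, mean
#' `protect_fraction`).
#'
#' @param landscape a `landscape` with `elevation` and `landcover`.
#' @param slr_levels_cm numeric vector of sea-level-rise levels (cm, >= 0).
#' @param dev_fraction expected developed fraction of non-water cells
#'   (in `[0, 1]`).
#' @param protect_fraction expected protected fraction of natural cells
#'   (in `[0, 1]`).
#' @param seed integer seed.
#' @return named list of binary `grid_raster`s: one `slr_<level>cm` mask per
#'   level, `development`, and `protection`.
#' @export
gen_threat_masks <- function(landscape, slr_levels_cm = c(30, 305),
                             dev_fraction = 0.10, protect_fraction = 0.30,
                             seed = landscape$config$seed + 200L) {
  if (any(slr_levels_cm < 0)) stop("sea-level-rise levels must be >= 0")
  if (dev_fraction < 0 || dev_fraction > 1 ||
      protect_fraction < 0 || protect_fraction > 1)
    stop("fractions must lie in [0, 1]")
  set.seed(as.integer(seed))
  elev <- landscape$elevation
  lc <- landscape$landcover$values
  masks <- list()
  for (lev in slr_levels_cm) {
    masks[[sprintf("slr_%dcm", as.integer(lev))]] <-
      map_values(elev, function(v) (v < lev / 100) * 1)
  }
  # development pressure decays with distance from urban seeds
  urban <- map_values(landscape$landcover, function(v) (v == LC_URBAN) * 1)
  eligible <- lc != LC_WATER
  if (any(urban$values == 1)) {
    d <- euclidean_distance(urban)$values
  } else {
    d <- matrix(0, nrow(lc), ncol(lc))
  }
  w <- exp(-d / (10 * elev$cellsize))
  p <- w * (dev_fraction * sum(eligible) / sum(w[eligible]))
  # renormalize after capping so the expected count stays on target
  for (pass in 1:3) {
    p[p > 1] <- 1
    shortfall <- dev_fraction * sum(eligible) - sum(p[eligible])
    room <- eligible & p < 1
    if (shortfall <= 0 || !any(room)) break
    p[room] <- p[room] * (1 + shortfall / sum(p[room]))
  }
  p[p > 1] <- 1
  dev <- matrix(0, nrow(lc), ncol(lc))
  dev[eligible] <- (stats::runif(sum(eligible)) < p[eligible]) * 1
  masks$development <- grid_raster(dev, elev$cellsize, elev$xll, elev$yll)
  # protection is blocky: Bernoulli weighted by an autocorrelated field
  natural <- lc == LC_NATURAL
  pf <- gen_gaussian_field(nrow(lc), ncol(lc),
                           landscape$config$corr_range_cells,
                           seed + 1L, elev$cellsize)$values
  wq <- stats::plogis(1.5 * pf)
  pp <- wq * (protect_fraction * sum(natural) / sum(wq[natural]))
  pp[pp > 1] <- 1
  prot <- matrix(0, nrow(lc), ncol(lc))
  prot[natural] <- (stats::runif(sum(natural)) < pp[natural]) * 1
  masks$protection <- grid_raster(prot, elev$cellsize, elev$xll, elev$yll)
  masks
}

#' Write telemetry fixes to CSV
#'
#' Timestamps are written in ISO-8601 UTC (`%Y-%m-%dT%H:%M:%SZ`).
#'
#' @param fixes fix data.frame as produced by [simulate_telemetry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read telemetry fixes from CSV
#'
#' @param path CSV path with ISO-8601 timestamps.
#' @return fix data.frame with POSIXct UTC timestamps.
#' @export
read_fixes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts) && !anyNA(df$timestamp)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp in record ", bad, ": ", df$timestamp[bad])
  }
  df$timestamp <- ts
  df
}
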