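#' Configuration for a full two-scale pipeline run
#'
#' One object drives the whole analysis: synthetic-landscape settings,
#' screening rules, model settings, scales, and the threat-scenario
#' parameters. The top-level `seed` propagates to every stochastic stage
#' (landscape, telemetry, background samples, fold partitions,
#' permutations, masks), so a run is reproducible from its config alone.
#' Configs round-trip through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param screening a [screening_config()].
#' @param k_folds cross-validation folds per extent (default 10).
#' @param n_background background locations per model iteration.
#' @param reg_multiplier Maxent regularization multiplier.
#' @param kde_level KDE isopleth level bounding state-scale background.
#' @param n_hinge hinge knots per direction.
#' @param buffer_km buffer around each unit for local-scale fitting context.
#' @param scales subset of `c("state", "local")`.
#' @param thresholds_override optional named list (`state`, `local`) of
#'   fixed binarization thresholds replacing the averaged max-SSS values.
#' @param slr_levels_cm sea-level-rise scenarios (cm).
#' @param dev_fraction,protect_fraction threat-mask fractions.
#' @param min_unit_presences minimum screened presences for a unit to be
#'   modeled on its own points; deficient units fall back to the statewide
#'   presence set (recorded in the run log). Default `2 * k_folds`.
#' @param seed master integer seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), screening = screening_config(),
                       k_folds = 10, n_background = 10000,
                       reg_multiplier = 1, kde_level = 0.95, n_hinge = 15,
                       buffer_km = 20, scales = c("state", "local"),
                       thresholds_override = NULL,
                       slr_levels_cm = c(30, 305), dev_fraction = 0.10,
                       protect_fraction = 0.30,
                       min_unit_presences = NULL, seed = 1L) {
  sim$seed <- as.integer(seed)
  if (is.null(min_unit_presences)) min_unit_presences <- 2L * k_folds
  structure(list(sim = sim, screening = screening, k_folds = k_folds,
                 n_background = n_background,
                 reg_multiplier = reg_multiplier, kde_level = kde_level,
                 n_hinge = n_hinge, buffer_km = buffer_km, scales = scales,
                 thresholds_override = thresholds_override,
                 slr_levels_cm = slr_levels_cm,
                 dev_fraction = dev_fraction,
                 protect_fraction = protect_fraction,
                 min_unit_presences = min_unit_presences,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  obj <- unclass_recursive(config)
  # named atomic vectors must become maps to survive the YAML round trip
  obj$sim$truth_coefficients <- as.list(obj$sim$truth_coefficients)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$sim$truth_coefficients <- unlist(raw$sim$truth_coefficients)
  sim <- do.call(sim_config, raw$sim)
  scr <- do.call(screening_config, raw$screening)
  rest <- raw[setdiff(names(raw), c("sim", "screening"))]
  rest$slr_levels_cm <- as.numeric(unlist(rest$slr_levels_cm))
  rest$scales <- as.character(unlist(rest$scales))
  do.call(run_config, c(list(sim = sim, screening = scr), rest))
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

# Region of cells within buffer_km of a unit's cells.
buffered_unit_region <- function(units, unit, buffer_km) {
  um <- map_values(units, function(v) (v == unit) * 1)
  d <- euclidean_distance(um)
  map_values(d, function(v) (v <= buffer_km * 1000) * 1)
}

# Per-unit habitat areas of a statewide binary map (Table-3-style row).
habitat_area_by_unit <- function(binary, units) {
  stop_unless_same_grid(binary, units)
  lab <- units$values
  ids <- sort(unique(lab[!is.na(lab)]))
  cell_km2 <- (binary$cellsize / 1000)^2
  km2 <- vapply(ids, function(u)
    sum(binary$values[lab == u] != 0, na.rm = TRUE) * cell_km2, numeric(1))
  data.frame(unit = ids, km2 = km2)
}

# Fit and evaluate both model families for one extent. Returns surfaces,
# evaluation reports, and the Maxent fold thresholds.
fit_extent <- function(presence, stack, variables, region, config, tag,
                       predict_region = NULL) {
  folds <- cross_validate(presence, stack, k = config$k_folds,
                          seed = config$seed + sum(utf8ToInt(tag)),
                          variables = variables, region = region,
                          n_background = config$n_background,
                          n_hinge = config$n_hinge,
                          reg_multiplier = config$reg_multiplier)
  surfaces <- list(); reports <- list(); thresholds <- numeric(0)
  mah_vars <- NULL
  for (f in folds) {
    surf_mx <- predict_maxent(f$model, stack, region = predict_region)
    rep_mx <- evaluation_report(surf_mx, f$holdout, f$background,
                                model_tag = paste0(tag, "_maxent"),
                                fold = f$fold)
    thresholds <- c(thresholds, rep_mx$threshold)
    # Mahalanobis on the same training presences, PCA-guided selection
    pres_mat <- stack_extract(stack, presence[f$train_idx, , drop = FALSE],
                              variables)
    pres_mat <- pres_mat[stats::complete.cases(pres_mat), , drop = FALSE]
    mah <- mahalanobis_select(pres_mat)
    mah_vars <- mah$variables
    surf_mh <- predict_mahalanobis(mah$model, stack,
                                   region = predict_region)
    rep_mh <- evaluation_report(surf_mh, f$holdout, f$background,
                                model_tag = paste0(tag, "_mahalanobis"),
                                fold = f$fold)
    surfaces[[length(surfaces) + 1L]] <- surf_mx
    surfaces[[length(surfaces) + 1L]] <- surf_mh
    reports[[length(reports) + 1L]] <- rep_mx
    reports[[length(reports) + 1L]] <- rep_mh
  }
  # held-out evaluation of the consensus itself: for each fold, average all
  # iteration surfaces except the two trained with that fold's points, and
  # score that ensemble on the fold's held-out presences
  k <- length(folds)
  total <- surfaces[[1]]$values
  for (s in surfaces[-1]) total <- total + s$values
  ref <- surfaces[[1]]
  for (i in seq_len(k)) {
    loo <- (total - surfaces[[2 * i - 1]]$values -
              surfaces[[2 * i]]$values) / (2 * k - 2)
    loo_r <- grid_raster(loo, ref$cellsize, ref$xll, ref$yll, ref$crs)
    reports[[length(reports) + 1L]] <-
      evaluation_report(loo_r, folds[[i]]$holdout, folds[[i]]$background,
                        model_tag = paste0(tag, "_consensus"),
                        fold = i)
  }
  list(surfaces = surfaces, reports = do.call(rbind, reports),
       thresholds = thresholds, folds = folds,
       mahalanobis_variables = mah_vars)
}

#' Run the full two-scale consensus habitat analysis
#'
#' Executes the complete workflow on synthetic data: landscape and telemetry
#' generation, fix screening and 5-h subsampling, covariate engineering and
#' correlation screening, per-scale cross-validated Maxent and Mahalanobis
#' fits (KDE-bounded background at the state scale; 20-km buffered unit
#' extents at the local scale), accuracy assessment, consensus averaging and
#' max-SSS thresholding, mosaicking of local units, scale combination into
#' habitat categories, and threat/protection overlays. Every stage is seeded
#' from the config, so two runs with one config agree exactly.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, rasters (ASCII grid),
#'   tables (CSV), models (JSON) and a manifest of MD5 hashes are written.
#' @param landscape optionally, a pre-built `landscape` (must match the
#'   config's sim settings); built from the config when `NULL`.
#' @param quiet suppress progress messages.
#' @return a list of class `pipeline_run`; key elements: `landscape`,
#'   `screened`, `presence`, `stack`, `state`/`local` (per-scale results
#'   with `consensus`, `reports`), `category`, `area_by_unit`,
#'   `threat_masks`, `overlay`, `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         landscape = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, "secs")), 2)
    res
  }

  say("simulating landscape and telemetry ...")
  if (is.null(landscape)) landscape <- stage("landscape",
                                             make_landscape(config$sim))
  fixes <- stage("telemetry", simulate_telemetry(landscape, config$sim))
  say("screening %d raw fixes ...", nrow(fixes))
  screened <- stage("screening", screen_fixes(fixes, config$screening))
  sub <- stage("subsample",
               subsample_fixes(screened$kept,
                               config$screening$subsample_hours))
  presence <- sub[, c("x", "y")]
  say("retained %d of %d fixes (%d animals)", nrow(presence), nrow(fixes),
      length(unique(sub$animal_id)))

  say("engineering covariates ...")
  stack <- stage("covariates", {
    s <- build_covariates(landscape)
    correlation_screen(s)
  })
  ref <- stack$rasters[[1]]
  all_land <- map_values(ref, function(v) (!is.na(v)) * 1)

  results <- list(landscape = landscape, fixes = fixes, screened = screened,
                  presence = presence, stack = stack, config = config)

  state_binary <- NULL; local_binary <- NULL

  if ("state" %in% config$scales) {
    say("state scale: KDE background boundary + variable selection ...")
    kde <- stage("kde", kde_polygon(presence, ref, level = config$kde_level))
    bg_sel <- sample_background(kde, n = config$n_background,
                                seed = config$seed + 11L)
    sel <- stage("state_select",
                 stepwise_select(stack, presence, bg_sel,
                                 seed = config$seed + 12L,
                                 n_hinge = config$n_hinge,
                                 reg_multiplier = config$reg_multiplier))
    say("state scale: %d-fold CV over variables: %s", config$k_folds,
        paste(sel$variables, collapse = ", "))
    ext <- stage("state_fit",
                 fit_extent(presence, stack, sel$variables, kde$mask,
                            config, tag = "state"))
    thr <- if (!is.null(config$thresholds_override$state))
      config$thresholds_override$state else mean(ext$thresholds)
    cons <- consensus_output(ext$surfaces, ext$thresholds, scale = "state")
    if (!is.null(config$thresholds_override$state)) {
      cons$threshold <- thr
      cons$binary <- apply_threshold(cons$continuous, thr)
    }
    state_binary <- cons$binary
    results$state <- list(kde = kde, selection = sel, consensus = cons,
                          reports = ext$reports,
                          thresholds = ext$thresholds, folds = ext$folds)
  }

  if ("local" %in% config$scales) {
    units <- landscape$units
    ids <- sort(unique(as.vector(units$values)))
    unit_cont <- list(); unit_reports <- list(); local_thresholds <- numeric(0)
    fallback_units <- integer(0)
    for (u in ids) {
      say("local scale: unit %d ...", u)
      region_u <- buffered_unit_region(units, u, config$buffer_km)
      inside <- extract_values(region_u, presence$x, presence$y)
      pres_u <- presence[!is.na(inside) & inside == 1, , drop = FALSE]
      if (nrow(pres_u) < config$min_unit_presences) {
        fallback_units <- c(fallback_units, u)
        pres_u <- presence
      }
      bg_u <- sample_background(region_u, n = config$n_background,
                                seed = config$seed + 100L + u)
      sel_u <- stepwise_select(stack, pres_u, bg_u,
                               seed = config$seed + 200L + u,
                               n_hinge = config$n_hinge,
                               reg_multiplier = config$reg_multiplier)
      ext_u <- fit_extent(pres_u, stack, sel_u$variables, region_u, config,
                          tag = sprintf("unit%d", u),
                          predict_region = region_u)
      cons_u <- consensus_output(ext_u$surfaces, ext_u$thresholds,
                                 scale = sprintf("local_unit%d", u))
      unit_cont[[as.character(u)]] <- cons_u$continuous
      unit_reports[[length(unit_reports) + 1L]] <- ext_u$reports
      local_thresholds <- c(local_thresholds, ext_u$thresholds)
    }
    say("local scale: mosaicking %d units ...", length(ids))
    local_cont <- mosaic_units(unit_cont, units)
    thr_local <- if (!is.null(config$thresholds_override$local))
      config$thresholds_override$local else mean(local_thresholds)
    # threshold each unit's averaged surface, then mosaic the binaries;
    # with one shared local threshold this equals thresholding the mosaic
    unit_bin <- lapply(unit_cont, apply_threshold, t = thr_local)
    local_binary <- mosaic_units(unit_bin, units)
    results$local <- list(continuous = local_cont, threshold = thr_local,
                          binary = local_binary,
                          unit_continuous = unit_cont,
                          reports = do.call(rbind, unit_reports),
                          thresholds = local_thresholds,
                          fallback_units = fallback_units)
  }

  if (!is.null(state_binary) && !is.null(local_binary)) {
    say("combining scales and overlaying threats ...")
    category <- stage("combine", combine_scales(local_binary, state_binary))
    results$category <- category
    results$area_by_unit <- list(
      local = habitat_area_by_unit(local_binary, landscape$units),
      state = habitat_area_by_unit(state_binary, landscape$units))
    masks <- stage("threat_masks",
                   gen_threat_masks(landscape, config$slr_levels_cm,
                                    config$dev_fraction,
                                    config$protect_fraction,
                                    seed = config$seed + 300L))
    results$threat_masks <- masks
    results$overlay <- stage("overlay", overlay_report(category, masks))
    # compound overlaps: unprotected habitat under development / inundation
    unprot <- map_values(masks$protection, function(v) (v == 0) * 1)
    worst <- masks[[sprintf("slr_%dcm",
                            as.integer(max(config$slr_levels_cm)))]]
    state_hab <- map_values(category$raster, function(v) (v %in% c(2, 3)) * 1)
    local_hab <- map_values(category$raster, function(v) (v %in% c(1, 3)) * 1)
    results$compound <- data.frame(
      habitat_class = rep(c("state", "local"), each = 2),
      masks = rep(c("unprotected+development", "unprotected+slr_worst"), 2),
      percent_of_unprotected = c(
        compound_overlap(state_hab, unprot, masks$development)$percent_of_habitat_a,
        compound_overlap(state_hab, unprot, worst)$percent_of_habitat_a,
        compound_overlap(local_hab, unprot, masks$development)$percent_of_habitat_a,
        compound_overlap(local_hab, unprot, worst)$percent_of_habitat_a))
    results$display_bins <- cumulative_frequency_bins(
      results$state$consensus$continuous, presence)
  }

  results$summary <- pipeline_summary(results)
  results$stage_seconds <- log
  class(results) <- "pipeline_run"
  if (!is.null(out_dir)) write_run_artifacts(results, out_dir)
  results
}

# Headline numbers of a run: per-scale mean held-out accuracy of the
# two-family consensus, thresholds, and areas.
pipeline_summary <- function(res) {
  out <- list(n_fixes_raw = nrow(res$fixes),
              n_fixes_used = nrow(res$presence))
  grab <- function(reports, tag) {
    r <- reports[reports$model_tag == tag, , drop = FALSE]
    list(auc = mean(r$auc), boyce = mean(r$boyce), tss = mean(r$tss),
         sensitivity = mean(r$sensitivity),
         specificity = mean(r$specificity))
  }
  if (!is.null(res$state)) {
    out$state <- grab(res$state$reports, "state_consensus")
    out$state$threshold <- res$state$consensus$threshold
    out$state$habitat_km2 <- raster_area_km2(res$state$consensus$binary)
  }
  if (!is.null(res$local)) {
    tags <- unique(res$local$reports$model_tag)
    ctags <- grep("_consensus$", tags, value = TRUE)
    r <- res$local$reports[res$local$reports$model_tag %in% ctags, ]
    out$local <- list(auc = mean(r$auc), boyce = mean(r$boyce),
                      tss = mean(r$tss),
                      threshold = res$local$threshold,
                      habitat_km2 = raster_area_km2(res$local$binary))
  }
  if (!is.null(res$category)) out$area_table <- res$category$areas
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_run>\n")
  cat(sprintf("  fixes: %d raw -> %d used\n", s$n_fixes_raw, s$n_fixes_used))
  if (!is.null(s$state))
    cat(sprintf("  state:  consensus AUC %.3f, Boyce %.3f, TSS %.3f, threshold %.3f, habitat %.1f km2\n",
                s$state$auc, s$state$boyce, s$state$tss, s$state$threshold,
                s$state$habitat_km2))
  if (!is.null(s$local))
    cat(sprintf("  local:  consensus AUC %.3f, Boyce %.3f, TSS %.3f, threshold %.3f, habitat %.1f km2\n",
                s$local$auc, s$local$boyce, s$local$tss, s$local$threshold,
                s$local$habitat_km2))
  invisible(x)
}

# Write rasters, tables, models and an MD5 manifest under out_dir.
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fixes_csv(res$screened$kept, p("fixes_screened.csv"))
  utils::write.csv(res$screened$log, p("screening_log.csv"),
                   row.names = FALSE)
  write_correlation_csv(res$stack, p("correlation.csv"))
  if (!is.null(res$state)) {
    write_ascii_grid(res$state$consensus$continuous, p("state_continuous.asc"))
    write_ascii_grid(res$state$consensus$binary, p("state_binary.asc"))
    utils::write.csv(res$state$reports, p("accuracy_state.csv"),
                     row.names = FALSE)
    write_maxent_json(res$state$folds[[1]]$model, p("state_maxent_fold1.json"))
  }
  if (!is.null(res$local)) {
    write_ascii_grid(res$local$continuous, p("local_continuous.asc"))
    write_ascii_grid(res$local$binary, p("local_binary.asc"))
    utils::write.csv(res$local$reports, p("accuracy_local.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$category)) {
    write_ascii_grid(res$category$raster, p("habitat_categories.asc"))
    utils::write.csv(res$category$areas, p("category_areas.csv"),
                     row.names = FALSE)
    ab <- rbind(cbind(scale = "local", res$area_by_unit$local),
                cbind(scale = "state", res$area_by_unit$state))
    utils::write.csv(ab, p("area_by_unit.csv"), row.names = FALSE)
  }
  if (!is.null(res$overlay))
    utils::write.csv(res$overlay, p("threat_overlay.csv"), row.names = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}
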