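# Shared fixtures, built in code. The tiny configuration keeps unit tests
# fast; the full-size study conditions are exercised only by the end-to-end
# acceptance test.

tiny_config <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(nrows = 60, ncols = 60, corr_range_cells = 8,
         n_animals = 10, fixes_per_animal = 350, fix_interval_h = 8,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# memoized tiny landscape + telemetry so several test files can share them
.fixture_env <- new.env(parent = emptyenv())

tiny_landscape <- function() {
  if (is.null(.fixture_env$landscape))
    .fixture_env$landscape <- make_landscape(tiny_config())
  .fixture_env$landscape
}

tiny_fixes <- function() {
  if (is.null(.fixture_env$fixes))
    .fixture_env$fixes <- simulate_telemetry(tiny_landscape(), tiny_config())
  .fixture_env$fixes
}

tiny_presence <- function() {
  if (is.null(.fixture_env$presence)) {
    scr <- screen_fixes(tiny_fixes())
    sub <- subsample_fixes(scr$kept)
    .fixture_env$presence <- sub[, c("x", "y")]
  }
  .fixture_env$presence
}

tiny_stack <- function() {
  if (is.null(.fixture_env$stack))
    .fixture_env$stack <- correlation_screen(build_covariates(tiny_landscape()))
  .fixture_env$stack
}

# build a fix data.frame by hand for screening tests
make_fix_df <- function(animal_id, timestamps, collar = "GPS", dop = 2,
                        fix_status = "3D", event = "normal", age = 6,
                        x = 1000, y = 1000) {
  n <- length(timestamps)
  data.frame(animal_id = rep_len(animal_id, n), timestamp = timestamps,
             x = rep_len(x, n), y = rep_len(y, n),
             collar = rep_len(collar, n), dop = rep_len(dop, n),
             fix_status = rep_len(fix_status, n),
             event = rep_len(event, n), age_years = rep_len(age, n),
             stringsAsFactors = FALSE)
}

hours <- function(h) as.POSIXct("2016-03-01 00:00:00", tz = "UTC") + h * 3600
days <- function(d) hours(24 * d)
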