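#' Telemetry screening configuration
#'
#' Inclusion rules for resident-adult habitat modeling: animals younger than
#' `min_age_years` are dropped (juvenile dispersers are not modeled), as are
#' animals without at least `min_fixes` retained locations inside some
#' 12-month window, or without fixes spread over at least
#' `min_distinct_months` distinct calendar months within such a window. At
#' the fix level, capture and mortality records are removed, as are GPS fixes
#' with low-quality fix status or dilution of precision above `max_dop`.
#'
#' @param min_age_years minimum age (years) for an animal to be retained.
#' @param min_fixes minimum retained locations within the window.
#' @param window_days length of the sliding window (days); 365 encodes the
#'   12-month rule.
#' @param min_distinct_months minimum distinct calendar months with a fix
#'   inside a qualifying window.
#' @param max_dop maximum allowed GPS dilution of precision (fixes with
#'   DOP strictly greater are removed).
#' @param subsample_hours temporal subsampling interval for GPS tracks.
#' @param bad_fix_status character vector of fix-status codes treated as low
#'   precision.
#' @return a list of class `screening_config`.
#' @export
screening_config <- function(min_age_years = 4, min_fixes = 30,
                             window_days = 365, min_distinct_months = 3,
                             max_dop = 7, subsample_hours = 5,
                             bad_fix_status = c("2D", "failed")) {
  stopifnot(min_age_years > 0, min_fixes > 0, window_days > 0,
            min_distinct_months > 0, min_distinct_months <= 12,
            max_dop > 0, subsample_hours > 0)
  structure(list(min_age_years = min_age_years, min_fixes = min_fixes,
                 window_days = window_days,
                 min_distinct_months = min_distinct_months,
                 max_dop = max_dop, subsample_hours = subsample_hours,
                 bad_fix_status = bad_fix_status),
            class = "screening_config")
}

#' Screen telemetry fixes and animals
#'
#' Applies the inclusion rules in a fixed order: first fix-level removals
#' (capture/mortality events; GPS fixes with low-quality status or
#' DOP > `max_dop`), then animal-level removals computed on the retained
#' fixes (underage; no sliding 12-month window holding at least `min_fixes`
#' locations; fewer than `min_distinct_months` distinct calendar months in
#' every 12-month window). The animal-count rules deliberately see only fixes
#' that survived the fix-level screen. Input ordering does not matter: fixes
#' are sorted by animal and timestamp internally.
#'
#' @param fixes fix data.frame (see [simulate_telemetry()] for columns).
#'   `timestamp` may be POSIXct or ISO-8601 character.
#' @param config a [screening_config()].
#' @return list with `kept` (fix data.frame) and `log` (data.frame of
#'   rejections: `record`, `stage`, `reason`), plus `n_in`/`n_out` counts.
#' @export
screen_fixes <- function(fixes, config = screening_config()) {
  if (is.null(fixes) || nrow(fixes) == 0) stop("no fixes supplied")
  f <- fixes
  if (!inherits(f$timestamp, "POSIXct")) {
    ts <- as.POSIXct(f$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    bad <- which(is.na(ts) & !is.na(f$timestamp))
    if (length(bad))
      stop("unparseable timestamp in record ", bad[1], ": ",
           f$timestamp[bad[1]])
    f$timestamp <- ts
  }
  if (anyNA(f$timestamp)) {
    bad <- which(is.na(f$timestamp))[1]
    stop("unparseable or missing timestamp in record ", bad)
  }
  f <- f[order(f$animal_id, f$timestamp), , drop = FALSE]
  f$.rec <- seq_len(nrow(f))
  log <- list()
  note <- function(rec, stage, reason) {
    log[[length(log) + 1L]] <<- data.frame(record = rec, stage = stage,
                                           reason = reason,
                                           stringsAsFactors = FALSE)
  }

  # --- fix-level screen -------------------------------------------------
  ev <- f$event %in% c("capture", "mortality")
  if (any(ev)) note(f$.rec[ev], "fix", "capture_or_mortality")
  f1 <- f[!ev, , drop = FALSE]

  gps <- f1$collar == "GPS"
  bad_status <- gps & !is.na(f1$fix_status) &
    f1$fix_status %in% config$bad_fix_status
  if (any(bad_status)) note(f1$.rec[bad_status], "fix", "fix_status")
  f2 <- f1[!bad_status, , drop = FALSE]

  gps <- f2$collar == "GPS"
  bad_dop <- gps & !is.na(f2$dop) & f2$dop > config$max_dop
  if (any(bad_dop)) note(f2$.rec[bad_dop], "fix", "dop")
  f3 <- f2[!bad_dop, , drop = FALSE]

  # --- animal-level screen on retained fixes ----------------------------
  keep_animals <- character(0)
  for (id in unique(f3$animal_id)) {
    sub <- f3[f3$animal_id == id, , drop = FALSE]
    if (sub$age_years[1] < config$min_age_years) {
      note(id, "animal", "age")
      next
    }
    w <- best_window_stats(sub$timestamp, config$window_days)
    if (w$max_fixes < config$min_fixes) {
      note(id, "animal", "too_few_fixes_in_window")
      next
    }
    if (w$max_months < config$min_distinct_months) {
      note(id, "animal", "too_few_distinct_months")
      next
    }
    keep_animals <- c(keep_animals, id)
  }
  kept <- f3[f3$animal_id %in% keep_animals, , drop = FALSE]
  kept$.rec <- NULL
  rownames(kept) <- NULL
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(record = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(kept = kept, log = log_df, n_in = nrow(fixes), n_out = nrow(kept))
}

# Sliding-window summaries over sorted timestamps: the best (max) fix count
# in any window of window_days, and the best distinct-calendar-month count.
best_window_stats <- function(ts, window_days) {
  ts <- sort(ts)
  n <- length(ts)
  win <- window_days * 86400
  months <- format(ts, "%Y-%m")
  max_fixes <- 0L; max_months <- 0L
  j <- 1L
  for (i in seq_len(n)) {
    # window anchored at fix i: [ts[i], ts[i] + win)
    while (j < n && as.numeric(ts[j + 1L]) - as.numeric(ts[i]) < win)
      j <- j + 1L
    if (as.numeric(ts[j]) - as.numeric(ts[i]) >= win) next
    cnt <- j - i + 1L
    if (cnt > max_fixes) max_fixes <- cnt
    m <- length(unique(months[i:j]))
    if (m > max_months) max_months <- m
  }
  list(max_fixes = max_fixes, max_months = max_months)
}

#' Temporally subsample one animal's GPS track
#'
#' Greedy forward pass: keep the first fix, then the earliest fix at least
#' `interval_hours` after the last kept fix. The output is a subsequence of
#' the input and the pass is deterministic; VHF fixes should be passed
#' through unchanged by the caller (see [subsample_fixes()]).
#'
#' @param fixes one animal's fixes, sorted by timestamp.
#' @param interval_hours minimum spacing between kept fixes (hours).
#' @return the kept subset of `fixes`.
#' @export
subsample_track <- function(fixes, interval_hours = 5) {
  if (is.null(fixes) || nrow(fixes) == 0) return(fixes)
  ts <- as.numeric(fixes$timestamp)
  if (is.unsorted(ts)) stop("fixes must be sorted by timestamp")
  gap <- interval_hours * 3600
  keep <- logical(length(ts))
  last <- -Inf
  for (i in seq_along(ts)) {
    if (ts[i] - last >= gap) { keep[i] <- TRUE; last <- ts[i] }
  }
  fixes[keep, , drop = FALSE]
}

#' Subsample GPS tracks across all animals
#'
#' Applies [subsample_track()] per animal to GPS fixes only; VHF fixes pass
#' through untouched (their cadence is already coarse and carries no DOP).
#'
#' @param fixes fix data.frame.
#' @param interval_hours minimum spacing (hours).
#' @return fix data.frame sorted by animal and timestamp.
#' @export
subsample_fixes <- function(fixes, interval_hours = 5) {
  f <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  parts <- lapply(split(f, f$animal_id), function(sub) {
    if (sub$collar[1] == "GPS") subsample_track(sub, interval_hours) else sub
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
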