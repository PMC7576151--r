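test_that("underage animals are removed with reason 'age'", {
  fx <- rbind(
    make_fix_df("young", hours(seq(0, 5000, by = 10)), age = 3.9),
    make_fix_df("adult", hours(seq(0, 5000, by = 10)), age = 4.0))
  out <- screen_fixes(fx)
  expect_setequal(unique(out$kept$animal_id), "adult")
  expect_true(any(out$log$record == "young" & out$log$reason == "age"))
})

test_that("DOP screen is strict at the boundary and GPS-only", {
  ts <- hours(seq(0, 5000, by = 10))
  fx <- make_fix_df("a", ts, dop = 2)
  fx$dop[1] <- 7.0     # kept: rule is strictly greater than 7
  fx$dop[2] <- 7.01    # removed
  fx_vhf <- make_fix_df("v", ts, collar = "VHF", dop = NA,
                        fix_status = NA)
  fx_vhf$dop[3] <- 9   # VHF carries no DOP screen
  out <- screen_fixes(rbind(fx, fx_vhf))
  kept_a <- out$kept[out$kept$animal_id == "a", ]
  expect_true(7.0 %in% kept_a$dop)
  expect_false(any(kept_a$dop > 7))
  kept_v <- out$kept[out$kept$animal_id == "v", ]
  expect_equal(nrow(kept_v), length(ts))
})

test_that("capture/mortality fixes and bad fix status are removed first", {
  ts <- hours(seq(0, 5000, by = 10))
  fx <- make_fix_df("a", ts)
  fx$event[1] <- "capture"; fx$event[10] <- "mortality"
  fx$fix_status[5] <- "2D"
  out <- screen_fixes(fx)
  expect_equal(nrow(out$kept), length(ts) - 3)
  expect_setequal(unique(out$log$reason),
                  c("capture_or_mortality", "fix_status"))
})

test_that("the 12-month window rule counts retained fixes only", {
  # 29 clean fixes in the best window -> removed
  fx29 <- make_fix_df("few", days(seq(1, 300, length.out = 29)))
  # 30 fixes but one is a capture record -> 29 retained -> removed
  fx30 <- make_fix_df("cap", days(seq(1, 300, length.out = 30)))
  fx30$event[15] <- "capture"
  # 30 clean fixes -> kept
  fx_ok <- make_fix_df("ok", days(seq(1, 300, length.out = 30)))
  out <- screen_fixes(rbind(fx29, fx30, fx_ok))
  expect_setequal(unique(out$kept$animal_id), "ok")
  expect_true(any(out$log$record == "few" &
                    out$log$reason == "too_few_fixes_in_window"))
  expect_true(any(out$log$record == "cap" &
                    out$log$reason == "too_few_fixes_in_window"))
})

test_that("animals spanning under three distinct months are removed", {
  # 40 fixes, all inside one calendar month
  one_month <- make_fix_df("narrow", hours(seq(0, 27 * 24, length.out = 40)))
  # 40 fixes across four months
  spread <- make_fix_df("wide", days(seq(1, 120, length.out = 40)))
  out <- screen_fixes(rbind(one_month, spread))
  expect_setequal(unique(out$kept$animal_id), "wide")
  expect_true(any(out$log$record == "narrow" &
                    out$log$reason == "too_few_distinct_months"))
})

test_that("screening is stable under input reordering", {
  fx <- tiny_fixes()
  set.seed(1)
  shuffled <- fx[sample.int(nrow(fx)), ]
  a <- screen_fixes(fx)$kept
  b <- screen_fixes(shuffled)$kept
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("screening filters are exercised on generator defaults", {
  out <- screen_fixes(tiny_fixes())
  frac <- out$n_out / out$n_in
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("unparseable timestamps are a hard error naming the record", {
  fx <- make_fix_df("a", hours(1:40))
  fx$timestamp <- as.character(fx$timestamp)
  fx$timestamp[7] <- "not-a-time"
  expect_error(screen_fixes(fx), "record")
})

test_that("greedy subsampling keeps the documented subsequence", {
  # 25 hourly fixes at 5 h -> exactly t = 0, 5, 10, 15, 20
  fx <- make_fix_df("a", hours(0:24))
  kept <- subsample_track(fx, 5)
  expect_equal(as.numeric(kept$timestamp - hours(0), units = "hours"),
               c(0, 5, 10, 15, 20))
  # irregular gaps: hand-traced greedy result
  fx2 <- make_fix_df("a", hours(c(0, 4.9, 5.1, 9.9, 10.2)))
  kept2 <- subsample_track(fx2, 5)
  expect_equal(as.numeric(kept2$timestamp - hours(0), units = "hours"),
               c(0, 5.1, 10.2))
  # already-spaced input is untouched (idempotence)
  expect_equal(subsample_track(kept, 5), kept)
  # empty input passes through
  expect_equal(nrow(subsample_track(fx[0, ], 5)), 0)
})

test_that("subsampling leaves VHF tracks alone and spaces GPS tracks", {
  fx <- rbind(make_fix_df("g", hours(0:30), collar = "GPS"),
              make_fix_df("v", hours(0:30), collar = "VHF", dop = NA))
  out <- subsample_fixes(fx, 5)
  g <- out[out$animal_id == "g", ]
  v <- out[out$animal_id == "v", ]
  expect_true(all(diff(as.numeric(g$timestamp)) >= 5 * 3600))
  expect_equal(nrow(v), 31)
})
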