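test_that("AUC handles separation, ties, and matches brute force", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7)), 0.5)
  set.seed(70)
  sp <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)
  sb <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)
  # O(n^2) pairwise oracle with half-credit ties
  oracle <- mean(outer(sp, sb, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc(sp, sb), oracle, tolerance = 1e-12)
  expect_error(auc(numeric(0), sb), "non-empty")
  expect_error(auc(c(1, NaN), sb), "finite")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(71)
  sp <- runif(50); sb <- runif(80)
  a0 <- auc(sp, sb)
  expect_equal(auc(qlogis(sp), qlogis(sb)), a0)
  expect_equal(auc(sp^3, sb^3), a0)
})

test_that("Boyce index reads calibration and flips with reversed scores", {
  # monotone case: presences drawn proportionally to suitability itself
  r <- grid_raster(matrix(seq(0, 1, length.out = 2500), 50, 50), 100)
  cc <- cell_centers(r)
  set.seed(72)
  idx <- sample(nrow(cc), 4000, replace = TRUE,
                prob = as.vector(r$values)^2)
  pres <- cc[idx, c("x", "y")]
  b <- boyce_index(r, pres)
  expect_gt(b, 0.95)
  # reversing the surface flips the sign
  r_rev <- map_values(r, function(v) 1 - v)
  expect_lt(boyce_index(r_rev, pres), -0.95)
  # uniform draws from cells: no calibration signal
  idx_u <- sample(nrow(cc), 10000, replace = TRUE)
  b_u <- boyce_index(r, cc[idx_u, c("x", "y")])
  expect_lt(abs(b_u), 0.3)
  expect_error(boyce_index(map_values(r, function(v) v * 0 + 1), pres),
               "constant")
})

test_that("TSS identity holds over a grid of rate pairs", {
  for (s in seq(0, 1, by = 0.25)) for (p in seq(0, 1, by = 0.25)) {
    expect_equal(tss(s, p), s + p - 1, tolerance = 1e-12)
  }
  # the published worked-example rows
  expect_equal(tss(0.93, 0.93), 0.86, tolerance = 1e-12)
  expect_equal(tss(0.96, 0.87), 0.83, tolerance = 1e-12)
})

test_that("confusion statistics count presences and background correctly", {
  cs <- confusion_stats(list(presence = c(1, 1, 0, 1),
                             background = c(0, 0, 1, 0, 0)))
  expect_equal(cs$sensitivity, 0.75)
  expect_equal(cs$specificity, 0.8)
  expect_equal(cs$tss, 0.55, tolerance = 1e-12)
  # degenerate all-habitat prediction
  cs1 <- confusion_stats(list(presence = rep(1, 5), background = rep(1, 5)))
  expect_equal(cs1$tss, 0)
  # raster interface
  m <- matrix(0, 4, 4); m[1:2, ] <- 1
  r <- grid_raster(m, 100)
  pres <- data.frame(x = c(50, 150), y = c(350, 250))   # both in top rows
  bg <- data.frame(x = c(50, 150), y = c(50, 150))      # both in bottom
  cr <- confusion_stats(r, pres, bg)
  expect_equal(cr$sensitivity, 1)
  expect_equal(cr$specificity, 1)
})

test_that("max-SSS threshold matches an exhaustive scan and is stable", {
  set.seed(73)
  sp <- runif(50); sb <- runif(50)
  t_star <- max_sss_threshold(sp, sb)
  cand <- sort(unique(c(sp, sb)))
  sums <- sapply(cand, function(t) mean(sp >= t) + mean(sb < t))
  expect_equal(mean(sp >= t_star) + mean(sb < t_star), max(sums),
               tolerance = 1e-12)
  # smallest maximizer is returned
  expect_equal(t_star, cand[which(sums >= max(sums) - 1e-15)[1]])
  # duplicating every observation changes nothing
  expect_equal(max_sss_threshold(rep(sp, 2), rep(sb, 2)), t_star)
  # perfect separation: sens = spec = 1 at the returned cutoff
  t_sep <- max_sss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(mean(c(0.8, 0.9) >= t_sep), 1)
  expect_equal(mean(c(0.1, 0.2) < t_sep), 1)
})

test_that("evaluation reports satisfy the TSS identity by construction", {
  ls <- tiny_landscape()
  pres <- utils::head(tiny_presence(), 300)
  bg <- sample_background(map_values(ls$truth_suitability,
                                     function(v) v * 0 + 1), 1000,
                          seed = 74)
  rep <- evaluation_report(ls$truth_suitability, pres, bg,
                           model_tag = "truth")
  expect_equal(rep$tss, rep$sensitivity + rep$specificity - 1,
               tolerance = 1e-12)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$boyce >= -1 && rep$boyce <= 1)
})
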