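test_that("gaussian fields are seed-deterministic and standardized", {
  f1 <- gen_gaussian_field(80, 80, 15, seed = 4)
  f2 <- gen_gaussian_field(80, 80, 15, seed = 4)
  expect_identical(f1$values, f2$values)
  expect_equal(mean(f1$values), 0, tolerance = 1e-12)
  expect_equal(sd(f1$values), 1, tolerance = 1e-12)
  expect_false(identical(f1$values, gen_gaussian_field(80, 80, 15, 5)$values))
})

test_that("zero correlation range degenerates to white noise", {
  w <- gen_gaussian_field(100, 100, 0, seed = 3)$values
  lag1 <- cor(as.vector(w[, -100]), as.vector(w[, -1]))
  expect_lt(abs(lag1), 0.05)
})

test_that("field autocorrelation matches a dense Cholesky simulation", {
  # oracle: direct multivariate-normal simulation from the exponential
  # covariance on a 30 x 30 grid
  n <- 30; rng <- 6
  idx <- expand.grid(i = 1:n, j = 1:n)
  d <- as.matrix(dist(idx))
  L <- chol(exp(-d / rng) + diag(1e-8, n * n))
  set.seed(99)
  acs <- replicate(8, {
    z <- matrix(drop(crossprod(L, rnorm(n * n))), n, n)
    cor(as.vector(z[, -n]), as.vector(z[, -1]))
  })
  oracle_lag1 <- mean(acs)
  f <- gen_gaussian_field(200, 200, rng, seed = 12)$values
  lag1 <- cor(as.vector(f[, -200]), as.vector(f[, -1]))
  expect_lt(abs(lag1 - oracle_lag1), 0.1)
})

test_that("virtual species is the inverse-logit of the linear predictor", {
  ls <- tiny_landscape()
  # brute-force per-cell oracle
  beta <- c(greenness = 1, wetness = -1)
  s <- gen_virtual_species(ls, beta, intercept = 0.3)
  oracle <- plogis(0.3 + ls$covariates$greenness$values -
                     ls$covariates$wetness$values)
  expect_lt(max(abs(s$values - oracle)), 1e-12)
  # zero coefficients: uniform one half
  s0 <- gen_virtual_species(ls, c(greenness = 0), intercept = 0)
  expect_true(all(s0$values == 0.5))
  # deep negative intercept saturates to zero
  s_neg <- gen_virtual_species(ls, c(greenness = 0), intercept = -50)
  expect_true(all(s_neg$values < 1e-15))
  expect_error(gen_virtual_species(ls, c(nope = 1)), "unknown covariate")
})

test_that("telemetry bookkeeping: exact intervals, capture record, ages", {
  cfg <- tiny_config(fix_interval_h = 1, fixes_per_animal = 100,
                     frac_vhf = 0, seed = 21L)
  ls <- make_landscape(cfg)
  fx <- simulate_telemetry(ls, cfg)
  one <- fx[fx$animal_id == fx$animal_id[1], ]
  expect_equal(nrow(one), 100)
  expect_equal(as.numeric(diff(one$timestamp), units = "hours"),
               rep(1, 99))
  expect_equal(one$event[1], "capture")
  expect_true(all(fx$dop >= 0))
  expect_true(all(fx$age_years > 0))
})

test_that("telemetry is identically reproduced from one config", {
  cfg <- tiny_config(seed = 31L)
  ls <- make_landscape(cfg)
  f1 <- simulate_telemetry(ls, cfg)
  f2 <- simulate_telemetry(ls, cfg)
  expect_identical(f1, f2)
})

test_that("fixes are enriched in high-truth cells under strong selection", {
  ls <- tiny_landscape()
  fx <- tiny_fixes()
  suit <- extract_values(ls$truth_suitability, fx$x, fx$y)
  land_mean <- mean(ls$truth_suitability$values)
  t <- t.test(suit, mu = land_mean, alternative = "greater")
  expect_lt(t$p.value, 0.01)
})

test_that("flat truth surface gives no selection signal", {
  cfg <- tiny_config(seed = 41L, n_animals = 6, fixes_per_animal = 200)
  ls <- make_landscape(cfg)
  ls$truth_suitability <- map_values(ls$truth_suitability,
                                     function(v) v * 0 + 0.5)
  fx <- simulate_telemetry(ls, cfg)
  suit <- extract_values(ls$truth_suitability, fx$x, fx$y)
  expect_equal(mean(suit, na.rm = TRUE), 0.5, tolerance = 1e-9)
})

test_that("inundation masks nest across sea levels and respect elevation", {
  ls <- tiny_landscape()
  masks <- gen_threat_masks(ls, slr_levels_cm = c(0, 30, 305), seed = 5)
  m0 <- masks$slr_0cm$values
  land <- ls$elevation$values > 0
  expect_true(all(m0[land] == 0))
  expect_true(all(masks$slr_30cm$values <= masks$slr_305cm$values))
})

test_that("development covers the requested fraction of eligible cells", {
  ls <- tiny_landscape()
  masks <- gen_threat_masks(ls, dev_fraction = 0.2, seed = 6)
  eligible <- ls$landcover$values != 5
  n_elig <- sum(eligible)
  dev <- sum(masks$development$values[eligible])
  # binomial bound: expected fraction 0.2 with sd <= sqrt(0.25/n)
  expect_lt(abs(dev / n_elig - 0.2), 4 * sqrt(0.25 / n_elig))
  expect_error(gen_threat_masks(ls, dev_fraction = 1.5), "fractions")
})

test_that("units partition the extent without overlap", {
  ls <- tiny_landscape()
  lab <- ls$units$values
  expect_false(anyNA(lab))
  expect_setequal(unique(as.vector(lab)), seq_len(tiny_config()$n_units))
})

test_that("fix CSV round-trips timestamps in ISO-8601", {
  fx <- utils::head(tiny_fixes(), 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes_csv(fx, path)
  back <- read_fixes_csv(path)
  expect_equal(back$timestamp, fx$timestamp)
  expect_equal(back$x, fx$x, tolerance = 1e-8)
})
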