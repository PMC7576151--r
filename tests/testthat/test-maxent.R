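# Gibbs sampler used as the simulation oracle for recovery tests: presences
# drawn from background cells with probability proportional to exp(X lambda).
gibbs_presences <- function(X, lambda, n, seed) {
  set.seed(seed)
  eta <- drop(X %*% lambda)
  p <- exp(eta - max(eta)); p <- p / sum(p)
  X[sample.int(nrow(X), n, replace = TRUE, prob = p), , drop = FALSE]
}

test_that("no presence-background contrast gives zero coefficients", {
  set.seed(20)
  X <- cbind(a = rnorm(5000))
  pres <- X[sample.int(5000, 800), , drop = FALSE]
  m <- fit_maxent(pres, X, features = "linear", rescale = FALSE)
  expect_lt(abs(m$lambda), 0.1)
})

test_that("known Gibbs coefficients are recovered within 10%", {
  set.seed(21)
  X <- cbind(a = rnorm(10000), b = rnorm(10000))
  lam <- c(a = 1.0, b = -0.7)
  pres <- gibbs_presences(X, lam, 5000, seed = 22)
  m <- fit_maxent(pres, X, features = "linear", rescale = FALSE, beta = 0)
  expect_lt(abs(m$lambda[["a.linear"]] - 1.0) / 1.0, 0.10)
  expect_lt(abs(m$lambda[["b.linear"]] - (-0.7)) / 0.7, 0.10)
})

test_that("coefficient error shrinks as the presence sample grows", {
  set.seed(23)
  X <- cbind(a = rnorm(10000), b = rnorm(10000))
  lam <- c(a = 0.8, b = -0.5)
  rmse <- sapply(c(200, 1000, 5000), function(n) {
    err <- replicate(3, {
      pres <- gibbs_presences(X, lam, n, seed = sample.int(1e6, 1))
      m <- fit_maxent(pres, X, features = "linear", rescale = FALSE,
                      beta = 0)
      sqrt(mean((m$lambda - c(0.8, -0.5))^2))
    })
    mean(err)
  })
  expect_true(rmse[3] < rmse[1])
})

test_that("raw scores over the training background sum to one", {
  set.seed(24)
  X <- cbind(a = rnorm(3000), b = runif(3000))
  pres <- gibbs_presences(X, c(a = 1, b = 0.5), 500, seed = 25)
  m <- fit_maxent(pres, X)
  raw <- maxent_scores(m, X, transform = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-6)
})

test_that("cloglog output is bounded and rank-equivalent to raw", {
  set.seed(26)
  X <- cbind(a = rnorm(2000), b = rnorm(2000))
  pres <- gibbs_presences(X, c(a = 1.2, b = -0.4), 400, seed = 27)
  m <- fit_maxent(pres, X)
  Xnew <- cbind(a = rnorm(500), b = rnorm(500))
  raw <- maxent_scores(m, Xnew, "raw")
  cll <- maxent_scores(m, Xnew, "cloglog")
  lgs <- maxent_scores(m, Xnew, "logistic")
  expect_true(all(cll >= 0 & cll <= 1))
  expect_true(all(lgs >= 0 & lgs <= 1))
  expect_equal(cor(raw, cll, method = "spearman"), 1)
})

test_that("prediction clamps to training bounds and handles constants", {
  st <- tiny_stack()
  pres <- tiny_presence()
  bg <- sample_background(map_values(st$rasters[[1]],
                                     function(v) (!is.na(v)) * 1),
                          2000, seed = 28)
  vars <- c("greenness", "wetness")
  pm <- stack_extract(st, pres, vars)
  pm <- pm[stats::complete.cases(pm), ]   # observation noise can fall off-grid
  bm <- stack_extract(st, bg, vars)
  m <- fit_maxent(pm, bm, n_hinge = 8)
  surf <- predict_maxent(m, st)
  expect_true(all(surf$values >= 0 & surf$values <= 1, na.rm = TRUE))
  # constant covariates give a constant surface
  flat <- st
  flat$rasters <- lapply(st$rasters[vars], function(r)
    map_values(r, function(v) v * 0 + 0.2))
  surf_flat <- predict_maxent(m, flat)
  expect_equal(length(unique(as.vector(surf_flat$values))), 1)
  expect_error(predict_maxent(m, covariate_stack(st$rasters["greenness"])),
               "missing covariate")
})

test_that("percent contribution normalizes to 100 and isolates signal", {
  set.seed(29)
  X <- cbind(sig = rnorm(4000), noise = rnorm(4000))
  pres <- gibbs_presences(X, c(sig = 1.5, noise = 0), 1000, seed = 30)
  m <- fit_maxent(pres, X)
  pc <- percent_contribution(m, pres, X, seed = 31)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_lt(pc[["noise"]], 5)
  # single-variable model is 100% by normalization
  m1 <- fit_maxent(pres[, "sig", drop = FALSE], X[, "sig", drop = FALSE])
  pc1 <- percent_contribution(m1, pres[, "sig", drop = FALSE],
                              X[, "sig", drop = FALSE], seed = 32)
  expect_equal(unname(pc1), 100)
})

test_that("step-wise selection keeps one member of a correlated pair", {
  set.seed(33)
  f_sig <- gen_gaussian_field(50, 50, 6, seed = 34)
  dup <- map_values(f_sig, function(v) v * 2 + 0.01 * rnorm(length(v)))
  noise <- gen_gaussian_field(50, 50, 0, seed = 35)
  st <- correlation_screen(covariate_stack(list(sig = f_sig, dup = dup,
                                                noise = noise)))
  truth <- map_values(f_sig, function(v) plogis(3 * v - 2))
  cells <- cell_centers(f_sig)
  pres_idx <- sample(nrow(cells), 600, prob = as.vector(truth$values),
                     replace = TRUE)
  pres <- cells[pres_idx, c("x", "y")]
  region <- map_values(f_sig, function(v) v * 0 + 1)
  bg <- sample_background(region, 2000, seed = 36)
  sel <- stepwise_select(st, pres, bg, seed = 37, n_hinge = 8)
  expect_equal(sum(c("sig", "dup") %in% sel$variables), 1)
  expect_false("noise" %in% sel$variables)
})

test_that("cross-validation folds partition presences deterministically", {
  st <- tiny_stack()
  pres <- utils::head(tiny_presence(), 200)
  expect_gte(nrow(pres), 200)
  folds <- cross_validate(pres, st, k = 5, seed = 38,
                          variables = c("greenness", "wetness"),
                          n_background = 500, n_hinge = 6)
  hold <- do.call(rbind, lapply(folds, `[[`, "holdout"))
  expect_equal(nrow(hold), nrow(pres))          # cover
  expect_equal(sort(as.numeric(rownames(hold))),
               sort(as.numeric(rownames(pres)))) # disjoint cover
  sizes <- vapply(folds, function(f) nrow(f$holdout), numeric(1))
  expect_equal(sum(sizes), 200)
  expect_true(max(sizes) - min(sizes) <= 1)
  folds2 <- cross_validate(pres, st, k = 5, seed = 38,
                           variables = c("greenness", "wetness"),
                           n_background = 500, n_hinge = 6)
  expect_equal(folds[[1]]$holdout, folds2[[1]]$holdout)
  expect_equal(folds[[1]]$background, folds2[[1]]$background)
  expect_error(cross_validate(pres, st, k = 1), "k must be")
})

test_that("model JSON serialization captures the fit", {
  set.seed(39)
  X <- cbind(a = rnorm(1000), b = rnorm(1000))
  pres <- gibbs_presences(X, c(a = 1, b = 0), 200, seed = 40)
  m <- fit_maxent(pres, X, n_hinge = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$lambda), m$lambda[m$lambda != 0 | TRUE],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$H, m$H, tolerance = 1e-12)
})
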