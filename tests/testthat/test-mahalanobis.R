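test_that("fit recovers identity covariance from orthogonal samples", {
  set.seed(60)
  X <- cbind(a = rnorm(10000), b = rnorm(10000))
  m <- fit_mahalanobis(X)
  expect_equal(m$sigma, diag(2), tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(unname(m$mu), c(0, 0), tolerance = 0.05)
})

test_that("rank-deficient presences raise a singularity error", {
  set.seed(61)
  x <- rnorm(100)
  X <- cbind(a = x, b = x, c = rnorm(100))
  expect_error(fit_mahalanobis(X), "singular|collinear")
  expect_error(fit_mahalanobis(cbind(a = rep(1, 50), b = rnorm(50))),
               "constant")
  expect_error(fit_mahalanobis(cbind(a = rnorm(3), b = rnorm(3),
                                     c = rnorm(3), d = rnorm(3))),
               "more presence rows")
})

test_that("one variable reduces to the squared z-score", {
  set.seed(62)
  x <- cbind(a = rnorm(500, mean = 3, sd = 2))
  m <- fit_mahalanobis(x)
  new <- cbind(a = c(3, 5, 0))
  expect_equal(mahalanobis_d2(m, new),
               ((new[, 1] - mean(x)) / sd(x))^2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("D2 matches the dense linear-algebra oracle", {
  set.seed(63)
  X <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_mahalanobis(X)
  new <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  oracle <- stats::mahalanobis(new, colMeans(X), cov(X))
  expect_lt(max(abs(mahalanobis_d2(m, new) - oracle)), 1e-9)
})

test_that("suitability is 1 at the centroid and 0.5 at the chi2 median", {
  set.seed(64)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, letters[1:4]))
  m <- fit_mahalanobis(X)
  expect_equal(unname(mahalanobis_scores(m, t(m$mu))), 1)
  # a point engineered to sit exactly at the chi-square median distance:
  # walk from the centroid along a covariance eigenvector
  med <- qchisq(0.5, df = 4)
  eig <- eigen(m$sigma, symmetric = TRUE)
  pt <- m$mu + sqrt(med * eig$values[1]) * eig$vectors[, 1]
  d2 <- mahalanobis_d2(m, matrix(pt, 1, dimnames = list(NULL, letters[1:4])))
  expect_equal(unname(d2), med, tolerance = 1e-9)
  expect_equal(unname(pchisq(d2, 4, lower.tail = FALSE)), 0.5,
               tolerance = 1e-9)
})

test_that("suitability decreases strictly with D2 and is affine-invariant", {
  set.seed(65)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_mahalanobis(X)
  new <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  d2 <- mahalanobis_d2(m, new)
  s <- mahalanobis_scores(m, new)
  expect_equal(order(d2), order(-s))
  # rescale one covariate: refit leaves the D2 surface unchanged
  X2 <- X; X2[, "b"] <- X2[, "b"] * 1000 + 7
  new2 <- new; new2[, "b"] <- new2[, "b"] * 1000 + 7
  m2 <- fit_mahalanobis(X2)
  expect_lt(max(abs(mahalanobis_d2(m2, new2) - d2)), 1e-9)
})

test_that("chi-square probability output matches numeric integration", {
  # independent oracle: integrate the chi-square density directly
  set.seed(66)
  for (i in 1:20) {
    df <- sample(1:8, 1)
    d2 <- runif(1, 0, 3 * df)
    oracle <- stats::integrate(function(t) stats::dchisq(t, df), d2, Inf,
                               rel.tol = 1e-10)$value
    expect_equal(pchisq(d2, df, lower.tail = FALSE), oracle,
                 tolerance = 1e-8)
  }
})

test_that("PCA contributions are symmetric, normalized, and rank variance", {
  set.seed(67)
  x <- rnorm(400)
  X <- cbind(a = x, b = x + rnorm(400, sd = 1e-6), c = rnorm(400))
  pc <- pca_contribution(X)
  expect_equal(pc$contribution[["a"]], pc$contribution[["b"]],
               tolerance = 1e-3)
  expect_equal(sum(pc$contribution), pc$retained_share, tolerance = 1e-9)
  # eigendecomposition oracle: contributions equal summed squared loadings
  # weighted by variance share over the retained components
  Y <- matrix(rnorm(1500), 500, 3, dimnames = list(NULL, c("p", "q", "r")))
  Y[, "q"] <- Y[, "p"] * 0.7 + Y[, "q"] * 0.5
  pcy <- pca_contribution(Y)
  eg <- eigen(cor(Y), symmetric = TRUE)
  share <- eg$values / sum(eg$values)
  k <- which(cumsum(share) >= 0.80)[1]
  oracle <- drop(eg$vectors[, 1:k, drop = FALSE]^2 %*% share[1:k])
  expect_equal(unname(pcy$contribution), oracle, tolerance = 1e-9)
  # when the dominant component alone meets the retention target, the
  # variables carrying it outrank an orthogonal noise variable
  z <- rnorm(500)
  W <- sapply(1:5, function(i) z + rnorm(500, sd = 0.15))
  W <- cbind(W, noise = rnorm(500))
  colnames(W) <- c(paste0("f", 1:5), "noise")
  pcw <- pca_contribution(W)
  expect_equal(which.min(pcw$contribution), c(noise = 6L))
})

test_that("iterative removal stops at the contribution floor or df 2", {
  set.seed(68)
  X <- cbind(a = rnorm(300), b = rnorm(300), c = rnorm(300),
             d = rnorm(300))
  sel <- mahalanobis_select(X, floor = 0.05)
  expect_gte(length(sel$variables), 2)
  expect_s3_class(sel$model, "mahalanobis_model")
})
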