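#' Fit a Mahalanobis-distance habitat suitability model
#'
#' A true presence-only model: the "ideal" habitat is the multivariate mean
#' of the covariates at the presence locations, and suitability of any cell
#' decreases with its Mahalanobis distance
#' `D^2 = (x - mu)' Sigma^{-1} (x - mu)` from that mean, where `Sigma` is
#' the presence sample covariance (denominator `n - 1`).
#'
#' @param presence matrix/data.frame of covariates at presence locations
#'   (rows > columns, named columns, no constant column).
#' @return object of class `mahalanobis_model` with `mu`, `sigma`, `df`
#'   (number of variables), `chol` (upper Cholesky factor of `sigma`).
#' @export
fit_mahalanobis <- function(presence) {
  x <- as.matrix(presence)
  if (is.null(colnames(x))) stop("presence covariates must be named")
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more presence rows than variables")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    cm <- abs(stats::cor(x)); diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "singular covariance; near-collinear columns include '%s' and '%s' (|r| = %.4f)",
      colnames(x)[worst[1]], colnames(x)[worst[2]], max(cm)))
  }
  structure(list(mu = mu, sigma = sigma, df = p, chol = chol(sigma),
                 n = n, variables = colnames(x)),
            class = "mahalanobis_model")
}

#' @export
print.mahalanobis_model <- function(x, ...) {
  cat(sprintf("<mahalanobis_model> %d variables, %d presence rows\n",
              x$df, x$n))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Squared Mahalanobis distances for covariate rows
#'
#' Computed through the Cholesky factor of the covariance (no explicit
#' inverse), which is numerically stable for near-singular `Sigma`.
#'
#' @param model a `mahalanobis_model`.
#' @param x covariate matrix with the model's columns.
#' @return numeric vector of `D^2` values (>= 0).
#' @export
mahalanobis_d2 <- function(model, x) {
  x <- as.matrix(x)[, model$variables, drop = FALSE]
  centered <- sweep(x, 2L, model$mu)
  z <- backsolve(model$chol, t(centered), transpose = TRUE)
  colSums(z^2)
}

#' Predict a Mahalanobis suitability raster
#'
#' Suitability is the chi-square upper-tail probability of `D^2` with `df`
#' equal to the number of variables ("probability" output): 1 at the
#' presence centroid, strictly decreasing in `D^2`, and in `[0, 1]`
#' everywhere. The surface is affine-invariant: rescaling a covariate and
#' refitting leaves `D^2` unchanged.
#'
#' @param model a `mahalanobis_model`.
#' @param stack a [covariate_stack()] supplying the model variables.
#' @param region optional binary `grid_raster` restricting prediction.
#' @return a `grid_raster` of suitability in `[0, 1]`.
#' @export
predict_mahalanobis <- function(model, stack, region = NULL) {
  missing <- setdiff(model$variables, names(stack$rasters))
  if (length(missing))
    stop("stack is missing variable(s): ", paste(missing, collapse = ", "))
  ref <- stack$rasters[[1]]
  x <- sapply(stack$rasters[model$variables], function(r) as.vector(r$values))
  colnames(x) <- model$variables
  use <- stats::complete.cases(x)
  if (!is.null(region)) {
    stop_unless_same_grid(ref, region)
    use <- use & as.vector(region$values != 0) &
      !is.na(as.vector(region$values))
  }
  out <- rep(NA_real_, nrow(x))
  if (any(use)) {
    d2 <- mahalanobis_d2(model, x[use, , drop = FALSE])
    out[use] <- stats::pchisq(d2, df = model$df, lower.tail = FALSE)
  }
  grid_raster(matrix(out, nrow(ref$values), ncol(ref$values)),
              ref$cellsize, ref$xll, ref$yll, ref$crs)
}

#' Suitability scores at covariate rows
#'
#' @param model a `mahalanobis_model`.
#' @param x covariate matrix.
#' @return chi-square upper-tail probabilities in `[0, 1]`.
#' @export
mahalanobis_scores <- function(model, x) {
  stats::pchisq(mahalanobis_d2(model, x), df = model$df, lower.tail = FALSE)
}

#' Per-variable contribution from principal components analysis
#'
#' PCA on the standardized covariates; each variable's contribution is the
#' sum, over the components needed to reach at least `var_target` of the
#' total variance, of its squared loading times that component's variance
#' share. Contributions therefore sum to the retained variance share, and
#' they rank variables for iterative removal.
#'
#' @param x covariate matrix (>= 2 variables, no constant column).
#' @param var_target retained-variance target (default 0.80).
#' @return list with `contribution` (named, descending order not applied),
#'   `retained_components`, `retained_share`.
#' @export
pca_contribution <- function(x, var_target = 0.80) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two variables")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(share) >= var_target)[1]
  contr <- drop(pc$rotation[, seq_len(k), drop = FALSE]^2 %*%
                  share[seq_len(k)])
  list(contribution = stats::setNames(contr, colnames(x)),
       retained_components = k, retained_share = sum(share[seq_len(k)]))
}

#' Iterative PCA-guided variable removal for Mahalanobis models
#'
#' Repeatedly drops the variable with the lowest PCA contribution and
#' refits, stopping when all remaining contributions exceed
#' `floor * retained_share` of the retained variance or only two variables
#' remain.
#'
#' @param presence covariate matrix at presence locations.
#' @param floor relative contribution floor (default 0.05).
#' @return list with `variables`, `model` (`mahalanobis_model`),
#'   `contribution` (from the final round).
#' @export
mahalanobis_select <- function(presence, floor = 0.05) {
  x <- as.matrix(presence)
  vars <- colnames(x)
  repeat {
    pcs <- pca_contribution(x[, vars, drop = FALSE])
    rel <- pcs$contribution / sum(pcs$contribution)
    if (length(vars) <= 2L || min(rel) > floor) break
    vars <- setdiff(vars, names(which.min(rel)))
  }
  list(variables = vars,
       model = fit_mahalanobis(x[, vars, drop = FALSE]),
       contribution = pcs$contribution)
}

#' Serialize a Mahalanobis model to JSON
#'
#' @param model a `mahalanobis_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mahalanobis_json <- function(model, path) {
  obj <- list(type = "mahalanobis_model", variables = model$variables,
              mu = as.list(model$mu), sigma = model$sigma, df = model$df,
              n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
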