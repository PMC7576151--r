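#' Maxent feature expansion
#'
#' Builds the feature set used by the maximum-entropy model: per covariate a
#' linear term, a quadratic term, and forward/reverse hinge features with
#' knots at training quantiles (default 15 knots per direction). Covariates
#' are min-max normalized to `[0, 1]` using training bounds, and evaluation
#' on new data clamps to those bounds, as is standard for transferring a
#' Maxent model beyond its training range.
#'
#' @param train matrix or data.frame of training covariates (presence plus
#'   background rows), named columns.
#' @param types feature classes to build; subset of
#'   `c("linear", "quadratic", "hinge")`.
#' @param n_hinge hinge knots per direction per covariate.
#' @param rescale min-max normalize covariates to `[0, 1]` (the Maxent
#'   convention). Turning this off fits on raw covariate scales, which is the
#'   natural setting for recovering known Gibbs coefficients.
#' @return an object of class `maxent_features`.
#' @export
maxent_features <- function(train, types = c("linear", "quadratic", "hinge"),
                            n_hinge = 15, rescale = TRUE) {
  train <- as.matrix(train)
  if (is.null(colnames(train))) stop("training covariates must be named")
  if (!all(is.finite(train))) stop("non-finite covariate values in training data")
  vars <- colnames(train)
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  knots <- NULL
  if ("hinge" %in% types) {
    probs <- seq_len(n_hinge) / (n_hinge + 1)
    knots <- lapply(vars, function(v) {
      x <- train[, v]
      if (rescale && hi[v] > lo[v]) x <- (x - lo[v]) / (hi[v] - lo[v])
      stats::quantile(x, probs, names = FALSE, type = 7)
    })
    names(knots) <- vars
  }
  structure(list(vars = vars, lo = lo, hi = hi, types = types,
                 n_hinge = n_hinge, knots = knots, rescale = rescale),
            class = "maxent_features")
}

# Feature columns contributed by a single covariate, given its raw values.
# Returns a matrix plus a parallel class vector.
var_feature_cols <- function(fs, v, xv_raw) {
  xv <- pmin(pmax(xv_raw, fs$lo[v]), fs$hi[v])
  if (fs$rescale) {
    rng <- fs$hi[v] - fs$lo[v]
    xv <- if (rng > 0) (xv - fs$lo[v]) / rng else xv * 0
  }
  cols <- list(); cls <- character(0)
  if ("linear" %in% fs$types) {
    cols[[length(cols) + 1L]] <- xv; cls <- c(cls, "linear")
  }
  if ("quadratic" %in% fs$types) {
    cols[[length(cols) + 1L]] <- xv^2; cls <- c(cls, "quadratic")
  }
  if ("hinge" %in% fs$types) {
    hi_k <- if (fs$rescale) 1 else fs$hi[v]
    lo_k <- if (fs$rescale) 0 else fs$lo[v]
    for (k in fs$knots[[v]]) {
      if (hi_k > k) {
        cols[[length(cols) + 1L]] <- pmax(0, (xv - k) / (hi_k - k))
        cls <- c(cls, "hinge")
      }
      if (k > lo_k) {
        cols[[length(cols) + 1L]] <- pmax(0, (k - xv) / (k - lo_k))
        cls <- c(cls, "hinge")
      }
    }
  }
  list(mat = do.call(cbind, cols), class = cls)
}

#' Evaluate a feature set on covariate data
#'
#' @param fs a [maxent_features()] object.
#' @param x matrix or data.frame with (at least) the feature set's covariate
#'   columns; values are clamped to the training bounds.
#' @return numeric matrix, one column per feature, with a `feature_var`
#'   attribute mapping columns to source covariates and a `feature_class`
#'   attribute giving each column's class.
#' @export
eval_features <- function(fs, x) {
  x <- as.matrix(x)
  missing <- setdiff(fs$vars, colnames(x))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  parts <- lapply(fs$vars, function(v) var_feature_cols(fs, v, x[, v]))
  f <- do.call(cbind, lapply(parts, `[[`, "mat"))
  src <- rep(fs$vars, vapply(parts, function(p) ncol(p$mat), integer(1)))
  cls <- unlist(lapply(parts, `[[`, "class"))
  colnames(f) <- make.unique(paste(src, cls, sep = "."))
  attr(f, "feature_var") <- src
  attr(f, "feature_class") <- cls
  f
}

# Default per-class regularization parameter, interpolated on presence count
# after the published Maxent defaults (hinge is constant).
default_class_reg <- function(class, m) {
  lq_x <- c(0, 10, 30, 100); lq_y <- c(1, 1, 0.2, 0.05)
  switch(class,
         linear = ,
         quadratic = stats::approx(lq_x, lq_y, xout = min(m, 100),
                                   rule = 2)$y,
         hinge = 0.5,
         stop("unknown feature class: ", class))
}
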