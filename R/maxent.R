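#' Fit a regularized maximum-entropy (Gibbs) suitability model
#'
#' Implements the presence-background maximum-entropy model: a Gibbs
#' distribution over background locations,
#' `p(x) = exp(sum_j lambda_j f_j(x)) / Z`, fitted by maximizing the mean
#' presence log-probability minus an L1 penalty `sum_j beta_j |lambda_j|`.
#' Default per-feature penalties follow the published Maxent defaults: a
#' per-class regularization parameter interpolated on the presence count,
#' scaled by the feature's presence-sample standard error
#' (`beta_j = reg_multiplier * class_reg(m) * sd_j / sqrt(m)`). Optimization
#' is by accelerated proximal gradient (FISTA) with backtracking line search
#' and soft-threshold proximal steps; the penalized objective is monotone
#' under the restart rule and iteration stops when its relative change drops
#' below `tol`. The fit is deterministic given its inputs.
#'
#' @param presence matrix/data.frame of covariates at presence locations
#'   (>= 2 rows, named columns).
#' @param background matrix/data.frame of covariates at background
#'   locations (at least as many rows as presences).
#' @param features feature classes, subset of
#'   `c("linear", "quadratic", "hinge")`.
#' @param n_hinge hinge knots per direction.
#' @param rescale min-max normalize covariates (see [maxent_features()]).
#' @param reg_multiplier multiplier on the default regularization.
#' @param beta optional explicit per-feature penalty vector (recycled);
#'   `beta = 0` disables regularization.
#' @param tol relative-change convergence tolerance on the penalized
#'   objective.
#' @param max_iter iteration cap; exceeding it with `tol` unmet is an error
#'   carrying diagnostics.
#' @return an object of class `maxent_model` with elements `featureset`,
#'   `lambda`, `beta`, `logZ`, `H` (entropy of the fitted background
#'   distribution), `gain`, `m`, `n_bg`, `iterations`, `objective`.
#' @export
fit_maxent <- function(presence, background,
                       features = c("linear", "quadratic", "hinge"),
                       n_hinge = 15, rescale = TRUE, reg_multiplier = 1,
                       beta = NULL, tol = 1e-6, max_iter = 1000L) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  m <- nrow(presence)
  if (m < 2L) stop("need at least 2 presence locations")
  if (nrow(background) < 2L) stop("need at least 2 background locations")
  fs <- maxent_features(rbind(presence, background), types = features,
                        n_hinge = n_hinge, rescale = rescale)
  Fp <- eval_features(fs, presence)
  Fb <- eval_features(fs, background)
  if (!all(is.finite(Fp)) || !all(is.finite(Fb)))
    stop("non-finite feature values")
  J <- ncol(Fp)
  cls <- attr(Fp, "feature_class")
  if (is.null(beta)) {
    sdj <- apply(Fp, 2L, stats::sd)
    creg <- vapply(cls, default_class_reg, numeric(1), m = m)
    bet <- reg_multiplier * creg * pmax(sdj, 1e-6) / sqrt(m)
  } else {
    bet <- rep_len(beta, J)
  }
  fbar <- colMeans(Fp)

  logsumexp <- function(eta) { mx <- max(eta); mx + log(sum(exp(eta - mx))) }
  smooth_obj <- function(lam) {
    eta <- drop(Fb %*% lam)
    -sum(fbar * lam) + logsumexp(eta)
  }
  smooth_grad <- function(lam) {
    eta <- drop(Fb %*% lam)
    p <- exp(eta - logsumexp(eta))
    drop(crossprod(Fb, p)) - fbar
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  lam <- numeric(J); y <- lam; tk <- 1
  step <- 1
  obj <- smooth_obj(lam) + sum(bet * abs(lam))
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gy <- smooth_grad(y)
    fy <- smooth_obj(y)
    repeat {
      cand <- soft(y - step * gy, step * bet)
      dlt <- cand - y
      if (smooth_obj(cand) <=
          fy + sum(gy * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    new_obj <- smooth_obj(cand) + sum(bet * abs(cand))
    if (new_obj > obj) {       # restart acceleration; keeps objective monotone
      y <- lam; tk <- 1
      gy <- smooth_grad(y)
      fy <- smooth_obj(y)
      repeat {
        cand <- soft(y - step * gy, step * bet)
        dlt <- cand - y
        if (smooth_obj(cand) <=
            fy + sum(gy * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
        step <- step / 2
        if (step < 1e-12) break
      }
      new_obj <- smooth_obj(cand) + sum(bet * abs(cand))
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- cand + ((tk - 1) / tk_new) * (cand - lam)
    lam <- cand; tk <- tk_new
    step <- step * 2   # allow the step to grow back
    if (abs(obj - new_obj) <= tol * max(1, abs(new_obj))) {
      obj <- new_obj; converged <- TRUE; break
    }
    obj <- new_obj
  }
  if (!converged)
    stop(sprintf(
      "maxent fit did not converge in %d iterations (objective %.6g, last step %.3g)",
      max_iter, obj, step))
  eta_b <- drop(Fb %*% lam)
  lz <- logsumexp(eta_b)
  p <- exp(eta_b - lz)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  gain <- sum(fbar * lam) - lz + log(nrow(Fb))
  structure(list(featureset = fs, lambda = stats::setNames(lam, colnames(Fp)),
                 beta = bet, logZ = lz, H = H, gain = gain, m = m,
                 n_bg = nrow(Fb), iterations = it, objective = obj,
                 output = "cloglog"),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features over %d covariates; %d presences, %d background\n",
              length(x$lambda), length(x$featureset$vars), x$m, x$n_bg))
  cat(sprintf("  gain %.4f, entropy %.4f, %d nonzero coefficients, %d iterations\n",
              x$gain, x$H, sum(x$lambda != 0), x$iterations))
  invisible(x)
}

# Raw (Gibbs) scores for a covariate matrix: exp(eta - logZ_train), so that
# the scores of the training background sum to 1.
maxent_raw <- function(model, x) {
  f <- eval_features(model$featureset, x)
  exp(drop(f %*% model$lambda) - model$logZ)
}

# Transform raw scores to the requested output scale.
maxent_transform <- function(raw, H, transform) {
  switch(transform,
         raw = raw,
         cloglog = 1 - exp(-exp(H) * raw),
         logistic = exp(H) * raw / (1 + exp(H) * raw),
         stop("unknown output transform: ", transform))
}

#' Score covariate rows with a fitted maximum-entropy model
#'
#' @param model a `maxent_model`.
#' @param x covariate matrix/data.frame.
#' @param transform `"cloglog"` (default), `"logistic"`, or `"raw"`.
#' @return numeric score vector; cloglog/logistic lie in `[0, 1]`.
#' @export
maxent_scores <- function(model, x, transform = model$output) {
  maxent_transform(maxent_raw(model, x), model$H, transform)
}

#' Predict a suitability raster from a maximum-entropy model
#'
#' Evaluates the model on every non-nodata cell of the stack (optionally
#' restricted to a region mask), clamping covariates to the training bounds.
#' The default cloglog transform `1 - exp(-exp(H) * raw)` maps the Gibbs
#' scores into `[0, 1]`; raw and cloglog outputs are rank-equivalent.
#'
#' @param model a `maxent_model`.
#' @param stack a [covariate_stack()] supplying all model covariates.
#' @param transform output transform (see [maxent_scores()]).
#' @param region optional binary `grid_raster`; cells outside get `NA`.
#' @return a `grid_raster` of suitability.
#' @export
predict_maxent <- function(model, stack, transform = model$output,
                           region = NULL) {
  vars <- model$featureset$vars
  missing <- setdiff(vars, names(stack$rasters))
  if (length(missing))
    stop("stack is missing covariate(s): ", paste(missing, collapse = ", "))
  ref <- stack$rasters[[1]]
  x <- sapply(stack$rasters[vars], function(r) as.vector(r$values))
  colnames(x) <- vars
  use <- stats::complete.cases(x)
  if (!is.null(region)) {
    stop_unless_same_grid(ref, region)
    use <- use & as.vector(region$values != 0) & !is.na(as.vector(region$values))
  }
  out <- rep(NA_real_, nrow(x))
  if (any(use))
    out[use] <- maxent_scores(model, x[use, , drop = FALSE], transform)
  grid_raster(matrix(out, nrow(ref$values), ncol(ref$values)),
              ref$cellsize, ref$xll, ref$yll, ref$crs)
}

# Training gain of a model evaluated on given covariate rows.
maxent_gain <- function(model, presence, background) {
  fp <- eval_features(model$featureset, as.matrix(presence))
  fb <- eval_features(model$featureset, as.matrix(background))
  eta_p <- drop(fp %*% model$lambda)
  eta_b <- drop(fb %*% model$lambda)
  mx <- max(eta_b)
  mean(eta_p) - (mx + log(sum(exp(eta_b - mx)))) + log(nrow(fb))
}

#' Per-variable percent contribution by permutation
#'
#' Importance of each covariate as the drop in training gain when its values
#' are permuted across the presence and background rows jointly (mean over
#' `n_perm` permutations), with negative drops floored at zero and the
#' result normalized to sum to 100.
#'
#' @param model a `maxent_model`.
#' @param presence,background covariate matrices used in training.
#' @param seed integer seed for the permutations.
#' @param n_perm permutations per variable.
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model, presence, background, seed = 1L,
                                 n_perm = 10L) {
  set.seed(as.integer(seed))
  presence <- as.matrix(presence); background <- as.matrix(background)
  fs <- model$featureset
  vars <- fs$vars
  m <- nrow(presence)
  comb <- rbind(presence[, vars, drop = FALSE],
                background[, vars, drop = FALSE])
  Fc <- eval_features(fs, comb)
  src <- attr(Fc, "feature_var")
  eta <- drop(Fc %*% model$lambda)
  n_bg <- nrow(background)
  gain_from_eta <- function(e) {
    eb <- e[-seq_len(m)]
    mx <- max(eb)
    mean(e[seq_len(m)]) - (mx + log(sum(exp(eb - mx)))) + log(n_bg)
  }
  g0 <- gain_from_eta(eta)
  drops <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    idx <- which(src == v)
    lam_v <- model$lambda[idx]
    if (all(lam_v == 0)) next     # the variable cannot affect the gain
    base_part <- drop(var_feature_cols(fs, v, comb[, v])$mat %*% lam_v)
    d <- 0
    for (r in seq_len(n_perm)) {
      xp <- comb[sample.int(nrow(comb)), v]
      perm_part <- drop(var_feature_cols(fs, v, xp)$mat %*% lam_v)
      d <- d + (g0 - gain_from_eta(eta - base_part + perm_part))
    }
    drops[v] <- max(d / n_perm, 0)
  }
  if (sum(drops) == 0) drops[] <- 1
  100 * drops / sum(drops)
}

#' Reverse step-wise variable selection for maximum-entropy models
#'
#' Fits a model on all candidate variables, drops those whose percent
#' contribution falls at or below `contribution_floor`, resolves flagged
#' correlated pairs by keeping the member with the higher contribution,
#' refits, and iterates until the variable set is stable (at most
#' `max_rounds` rounds).
#'
#' @param stack a screened [covariate_stack()] (run [correlation_screen()]
#'   first).
#' @param presence data.frame of presence points with `x`, `y` columns.
#' @param background data.frame of background points with `x`, `y` columns
#'   (e.g. from [sample_background()]).
#' @param contribution_floor percent-contribution cutoff (default 1).
#' @param max_rounds iteration cap.
#' @param seed seed for the permutation importances.
#' @param ... passed to [fit_maxent()].
#' @return list with `variables`, `model`, `contribution`, `rounds`.
#' @export
stepwise_select <- function(stack, presence, background,
                            contribution_floor = 1, max_rounds = 5,
                            seed = 1L, ...) {
  if (is.null(stack$correlation)) stack <- correlation_screen(stack)
  vars <- setdiff(names(stack$rasters), stack$degenerate)
  pres_mat <- stack_extract(stack, presence, vars)
  bg_mat <- stack_extract(stack, background, vars)
  pres_mat <- pres_mat[stats::complete.cases(pres_mat), , drop = FALSE]
  bg_mat <- bg_mat[stats::complete.cases(bg_mat), , drop = FALSE]
  model <- NULL; pc <- NULL; rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    model <- fit_maxent(pres_mat[, vars, drop = FALSE],
                        bg_mat[, vars, drop = FALSE], ...)
    pc <- percent_contribution(model, pres_mat[, vars, drop = FALSE],
                               bg_mat[, vars, drop = FALSE], seed = seed)
    keep <- names(pc)[pc > contribution_floor]
    if (!length(keep)) stop("all variables dropped during step-wise selection")
    # among flagged correlated pairs, retain the higher-contribution member
    fp <- stack$flagged_pairs
    if (!is.null(fp) && nrow(fp)) {
      for (i in seq_len(nrow(fp))) {
        a <- fp$var1[i]; b <- fp$var2[i]
        if (a %in% keep && b %in% keep)
          keep <- setdiff(keep, if (pc[a] >= pc[b]) b else a)
      }
    }
    if (setequal(keep, vars) || rounds >= max_rounds) { vars <- keep; break }
    vars <- keep
  }
  model <- fit_maxent(pres_mat[, vars, drop = FALSE],
                      bg_mat[, vars, drop = FALSE], ...)
  list(variables = vars, model = model, contribution = pc, rounds = rounds)
}

#' Extract stack covariate values at point locations
#'
#' @param stack a [covariate_stack()].
#' @param points data.frame with `x`, `y` (m).
#' @param vars variables to extract (default all).
#' @return matrix with one named column per variable.
#' @export
stack_extract <- function(stack, points, vars = names(stack$rasters)) {
  out <- sapply(stack$rasters[vars], function(r)
    extract_values(r, points$x, points$y))
  out <- matrix(out, nrow = nrow(points),
                dimnames = list(NULL, vars))
  out
}

#' Random k-fold cross-validation partition and per-fold model fits
#'
#' Randomly partitions the presence points into `k` folds (seeded), trains a
#' maximum-entropy model on each set of `k - 1` folds with its own seeded
#' background sample, and retains the background for evaluation reuse.
#'
#' @param presence data.frame of presence points (`x`, `y`).
#' @param stack a [covariate_stack()].
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling both the partition and per-fold
#'   background samples.
#' @param variables covariates to use (default all non-degenerate).
#' @param region binary `grid_raster` from which background is sampled
#'   (default: all non-nodata cells of the stack).
#' @param n_background background points per fold.
#' @param ... passed to [fit_maxent()].
#' @return list of `k` folds, each with `model`, `holdout` (held-out
#'   presence points), `background` (points), `train_idx`, and `fold`.
#' @export
cross_validate <- function(presence, stack, k = 10, seed = 1L,
                           variables = NULL, region = NULL,
                           n_background = 10000, ...) {
  if (k < 2) stop("k must be at least 2")
  if (nrow(presence) < k) stop("need at least k presence points")
  if (is.null(variables))
    variables <- setdiff(names(stack$rasters),
                         if (is.null(stack$degenerate)) character(0) else
                           stack$degenerate)
  if (is.null(region)) {
    ref <- stack$rasters[[1]]
    region <- map_values(ref, function(v) (!is.na(v)) * 1)
  }
  set.seed(as.integer(seed))
  n <- nrow(presence)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    train_idx <- which(fold_id != i)
    bg <- sample_background(region, n = n_background,
                            seed = as.integer(seed) + 1000L + i)
    pres_mat <- stack_extract(stack, presence[train_idx, , drop = FALSE],
                              variables)
    bg_mat <- stack_extract(stack, bg, variables)
    ok_p <- stats::complete.cases(pres_mat)
    ok_b <- stats::complete.cases(bg_mat)
    model <- fit_maxent(pres_mat[ok_p, , drop = FALSE],
                        bg_mat[ok_b, , drop = FALSE], ...)
    folds[[i]] <- list(model = model,
                       holdout = presence[fold_id == i, , drop = FALSE],
                       background = bg[ok_b, , drop = FALSE],
                       train_idx = train_idx, fold = i)
  }
  folds
}

#' Serialize a maximum-entropy model to JSON
#'
#' Writes features (types, knots, clamp bounds), coefficients, penalties,
#' the normalizer and entropy, so a model can be stored alongside its run.
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maxent_json <- function(model, path) {
  fs <- model$featureset
  obj <- list(type = "maxent_model",
              variables = fs$vars,
              feature_types = fs$types,
              n_hinge = fs$n_hinge,
              rescale = fs$rescale,
              clamp_lo = as.list(fs$lo), clamp_hi = as.list(fs$hi),
              knots = fs$knots,
              lambda = as.list(model$lambda),
              beta = model$beta,
              logZ = model$logZ, H = model$H, gain = model$gain,
              m = model$m, n_bg = model$n_bg, output = model$output)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
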