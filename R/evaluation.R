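#' Area under the ROC curve for presence vs background scores
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence location outscores a randomly chosen background location, with
#' ties counted one half. With background standing in for absences, this is
#' the usual presence-background discrimination index.
#'
#' @param scores_presence,scores_background numeric score vectors
#'   (non-empty, finite).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("both score sets must be non-empty")
  if (!all(is.finite(scores_presence)) || !all(is.finite(scores_background)))
    stop("scores must be finite")
  m <- length(scores_presence); n <- length(scores_background)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Continuous Boyce index
#'
#' Calibration of a suitability surface against presence points: overlapping
#' suitability windows (default 101 windows of width one tenth of the
#' suitability range) each get a predicted-to-expected ratio
#' `P/E = (share of presences in window) / (share of study-area cells in
#' window)`; the index is the Spearman rank correlation between `P/E` and
#' the window midpoint over windows with `E > 0`. It ranges from -1 to 1;
#' positive values mean presences concentrate in high-suitability cells.
#'
#' @param suitability a `grid_raster`, or a numeric vector of cell
#'   suitabilities.
#' @param presence data.frame of points (`x`, `y`) when `suitability` is a
#'   raster, otherwise a numeric vector of presence suitabilities.
#' @param n_windows number of overlapping windows (default 101).
#' @param window_width window width; default one tenth of the suitability
#'   range.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(suitability, presence, n_windows = 101,
                        window_width = NULL) {
  if (inherits(suitability, "grid_raster")) {
    cells <- as.vector(suitability$values)
    cells <- cells[!is.na(cells)]
    sp <- extract_values(suitability, presence$x, presence$y)
    sp <- sp[!is.na(sp)]
  } else {
    cells <- suitability[!is.na(suitability)]
    sp <- presence[!is.na(presence)]
  }
  rng <- range(cells)
  if (diff(rng) == 0) stop("constant suitability surface")
  if (is.null(window_width)) window_width <- diff(rng) / 10
  lowers <- seq(rng[1], rng[2] - window_width, length.out = n_windows)
  P <- E <- mid <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    lo <- lowers[i]; hi <- lowers[i] + window_width
    P[i] <- mean(sp >= lo & sp <= hi)
    E[i] <- mean(cells >= lo & cells <= hi)
    mid[i] <- (lo + hi) / 2
  }
  keep <- E > 0
  if (sum(keep) < 2L) stop("fewer than two windows with nonzero expected frequency")
  suppressWarnings(stats::cor(P[keep] / E[keep], mid[keep],
                              method = "spearman"))
}

#' True skill statistic from sensitivity and specificity
#'
#' `TSS = sensitivity + specificity - 1`; ranges from -1 to 1, with 0 for a
#' model no better than random.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return TSS.
#' @export
tss <- function(sensitivity, specificity) sensitivity + specificity - 1

#' Sensitivity, specificity and TSS of a binary habitat map
#'
#' Evaluates a binary prediction against presence points (positives) and
#' background points (standing in for the negative class): sensitivity is
#' the fraction of presences predicted habitat, specificity the fraction of
#' background predicted non-habitat.
#'
#' @param binary a binary `grid_raster`, or a list with numeric elements
#'   `presence` and `background` of 0/1 predictions at the points.
#' @param presence,background point data.frames (`x`, `y`) when `binary` is
#'   a raster.
#' @return list with `sensitivity`, `specificity`, `tss`.
#' @export
confusion_stats <- function(binary, presence = NULL, background = NULL) {
  if (inherits(binary, "grid_raster")) {
    pp <- extract_values(binary, presence$x, presence$y)
    pb <- extract_values(binary, background$x, background$y)
    if (anyNA(pp) || anyNA(pb))
      stop("binary map is undefined at some evaluation points")
  } else {
    pp <- binary$presence; pb <- binary$background
  }
  if (!length(pp) || !length(pb)) stop("empty point sets")
  sens <- mean(pp == 1)
  spec <- mean(pb == 0)
  list(sensitivity = sens, specificity = spec, tss = tss(sens, spec))
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans every distinct observed score as a candidate cutoff under the rule
#' `score >= t` is habitat, and returns the smallest threshold maximizing
#' `sensitivity + specificity`. This is the binarization rule used to turn
#' continuous suitability into habitat maps.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return the selected threshold.
#' @export
max_sss_threshold <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("both score sets must be non-empty")
  cand <- sort(unique(c(scores_presence, scores_background)))
  best_t <- cand[1]; best <- -Inf
  for (t in cand) {
    s <- mean(scores_presence >= t) + mean(scores_background < t)
    if (s > best + 1e-15) { best <- s; best_t <- t }
  }
  best_t
}

#' Full accuracy report for one model iteration
#'
#' Computes the five accuracy measures of the workflow for one fitted
#' surface: AUC and Boyce (threshold-independent), then the maximum
#' sensitivity-plus-specificity threshold and the resulting sensitivity,
#' specificity, and TSS.
#'
#' @param suitability continuous `grid_raster`.
#' @param presence,background point data.frames (`x`, `y`).
#' @param threshold optional fixed threshold; default is the max-SSS value
#'   computed from these points.
#' @param model_tag,fold labels carried into the report.
#' @return one-row data.frame (an evaluation report): `model_tag`, `fold`,
#'   `auc`, `boyce`, `threshold`, `sensitivity`, `specificity`, `tss`,
#'   `n_presence`, `n_background`.
#' @export
evaluation_report <- function(suitability, presence, background,
                              threshold = NULL, model_tag = "", fold = NA) {
  sp <- extract_values(suitability, presence$x, presence$y)
  sb <- extract_values(suitability, background$x, background$y)
  okp <- !is.na(sp); okb <- !is.na(sb)
  sp <- sp[okp]; sb <- sb[okb]
  a <- auc(sp, sb)
  b <- boyce_index(suitability,
                   presence[okp, , drop = FALSE])
  if (is.null(threshold)) threshold <- max_sss_threshold(sp, sb)
  cs <- confusion_stats(list(presence = (sp >= threshold) * 1,
                             background = (sb >= threshold) * 1))
  data.frame(model_tag = model_tag, fold = fold, auc = a, boyce = b,
             threshold = threshold, sensitivity = cs$sensitivity,
             specificity = cs$specificity, tss = cs$tss,
             n_presence = length(sp), n_background = length(sb),
             stringsAsFactors = FALSE)
}
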