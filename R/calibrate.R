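# Output scaling to [-1, 1] and decision-threshold calibration.

#' Affine scaling of raw scores to \[-1, 1\]
#'
#' Maps `raw` by `2 * (raw - scale_min) / (scale_max - scale_min) - 1` and
#' clamps the result to \[-1, 1\]. The bounds are normally the min/max raw
#' score observed on the calibration split, so unseen scores outside the
#' range are clamped.
#'
#' @param raw numeric vector of raw scores.
#' @param scale_min,scale_max calibration bounds, `scale_min < scale_max`.
#' @return numeric vector in \[-1, 1\].
#' @examples
#' scale_output(c(0, 5, 10, 12), 0, 10)
#' @export
scale_output <- function(raw, scale_min, scale_max) {
  if (scale_max <= scale_min) {
    warnf("degenerate scaling range [%g, %g]: returning 0", scale_min,
          scale_max)
    return(rep(0, length(raw)))
  }
  pmin(1, pmax(-1, 2 * (raw - scale_min) / (scale_max - scale_min) - 1))
}

#' Calibrate the optimal decision threshold
#'
#' Scans the threshold grid formed by the midpoints of consecutive distinct
#' sorted scores, together with -1 and 1, and returns the threshold
#' maximising the G-mean of the decisions `score > th`. Ties are broken
#' towards the smallest threshold. G-mean is used regardless of the ensemble
#' objective because auROC/auPRC are threshold-free and cannot rank
#' thresholds.
#'
#' @param scores numeric vector of scaled scores in \[-1, 1\].
#' @param labels vector of labels in `{-1, +1}`; both classes must be
#'   present.
#' @return the optimal threshold `th_optimal` in \[-1, 1\].
#' @export
calibrate_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1) || !any(labels == -1))
    stop("both classes must be present to calibrate a threshold")
  s <- sort(unique(scores))
  if (length(s) < 2L) {
    warnf("degenerate calibration input (single distinct score): th = 0")
    return(0)
  }
  grid <- sort(unique(c(-1, (s[-1] + s[-length(s)]) / 2, 1)))
  npos <- sum(labels == 1)
  nneg <- sum(labels == -1)
  g <- vapply(grid, function(th) {
    dec <- scores > th
    sn <- sum(dec & labels == 1) / npos
    sp <- sum(!dec & labels == -1) / nneg
    sqrt(sn * sp)
  }, numeric(1))
  grid[which.max(g)]  # first = smallest threshold on ties
}

#' Calibrate a fitted scorer on held-out scores
#'
#' Wraps a fitted base scorer with the affine scaling to \[-1, 1\] and the
#' optimal decision threshold, both estimated from calibration scores
#' (normally pooled out-of-fold raw scores, see [fit_calibrated_scorer()]).
#'
#' @param base a fitted scorer from [fit_scorer()].
#' @param raw_scores raw calibration scores of `base`.
#' @param labels labels in `{-1, +1}` matching `raw_scores`.
#' @param objective the measure the scorer will be used to optimise
#'   (`"G_MEAN"`, `"AUROC"` or `"AUPRC"`); recorded on the object.
#' @return an object of class `calibrated_scorer` with fields `base`,
#'   `scale_min`, `scale_max`, `th_optimal` and `objective`. Its effective
#'   output is `scaled_score - th_optimal`, so positive values vote `+1`.
#' @export
calibrate_scorer <- function(base, raw_scores, labels,
                             objective = c("G_MEAN", "AUROC", "AUPRC")) {
  objective <- match.arg(objective)
  stopifnot(inherits(base, "site_scorer"))
  smin <- min(raw_scores)
  smax <- max(raw_scores)
  if (smax <= smin) {
    warnf("scorer %s has constant calibration scores", base$source_tag)
    smax <- smin + 1   # scaling then maps everything to -1
  }
  scaled <- scale_output(raw_scores, smin, smax)
  th <- if (any(labels == 1) && any(labels == -1) &&
              length(unique(scaled)) > 1L)
    calibrate_threshold(scaled, labels) else 0
  structure(list(base = base, scale_min = smin, scale_max = smax,
                 th_optimal = th, objective = objective),
            class = "calibrated_scorer")
}

#' Fit and calibrate a scorer by cross-validation
#'
#' Fits the requested scorer kind on the full (balanced) training set and
#' estimates its output scaling and optimal threshold from pooled
#' out-of-fold raw scores of a stratified k-fold cross-validation, so the
#' calibration is not biased by resubstitution.
#'
#' @inheritParams fit_scorer
#' @param folds number of cross-validation folds for calibration.
#' @param objective measure recorded on the calibrated scorer.
#' @return a `calibrated_scorer`.
#' @export
fit_calibrated_scorer <- function(kind, data, hyperparams = list(),
                                  folds = 5L, seed = 1L,
                                  objective = "G_MEAN", source_tag = NULL) {
  lab <- data$candidates$label
  base <- fit_scorer(kind, data, hyperparams, seed = seed,
                     source_tag = source_tag)
  if (kind == "STOP_CODON_METHOD") {
    # parameterless: scores do not depend on the fitted state
    raw <- raw_score(base, data$candidates$window_seq)
    return(calibrate_scorer(base, raw, lab, objective))
  }
  fold_id <- stratified_folds(lab, folds, derive_seed(seed, 13L))
  raw <- numeric(length(lab))
  for (f in seq_len(folds)) {
    tr <- data
    tr$candidates <- data$candidates[fold_id != f, , drop = FALSE]
    fit_f <- fit_scorer(kind, tr, hyperparams, seed = derive_seed(seed, f),
                        source_tag = source_tag)
    raw[fold_id == f] <-
      raw_score(fit_f, data$candidates$window_seq[fold_id == f])
  }
  calibrate_scorer(base, raw, lab, objective)
}

#' Effective output of a calibrated scorer
#'
#' The scaled raw score minus the scorer's optimal threshold; the sign of
#' the effective output is the scorer's vote.
#'
#' @param cal a `calibrated_scorer`.
#' @param windows character vector of window strings.
#' @return numeric vector of effective outputs in \[-2, 2\].
#' @export
effective_output <- function(cal, windows) {
  stopifnot(inherits(cal, "calibrated_scorer"))
  scale_output(raw_score(cal$base, windows), cal$scale_min, cal$scale_max) -
    cal$th_optimal
}

#' @export
print.calibrated_scorer <- function(x, ...) {
  cat(sprintf(
    "<calibrated_scorer> %s | scale [%.4g, %.4g], th_optimal %.4f (%s)\n",
    x$base$source_tag, x$scale_min, x$scale_max, x$th_optimal, x$objective))
  invisible(x)
}

#' @export
#' @param type `"effective"` (default), `"scaled"`, `"raw"` or `"decision"`.
#' @rdname effective_output
#' @param object a `calibrated_scorer`.
#' @param newdata character vector of window strings.
#' @param ... unused.
predict.calibrated_scorer <- function(object, newdata,
                                      type = c("effective", "scaled", "raw",
                                               "decision"), ...) {
  type <- match.arg(type)
  raw <- raw_score(object$base, newdata)
  if (type == "raw") return(raw)
  scaled <- scale_output(raw, object$scale_min, object$scale_max)
  if (type == "scaled") return(scaled)
  eff <- scaled - object$th_optimal
  if (type == "effective") eff else ifelse(eff > 0, 1L, -1L)
}

# Stratified fold assignment, deterministic given seed.
stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
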