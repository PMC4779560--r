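# Imbalance-aware evaluation: confusion counts, Sn/Sp/G-mean, auROC,
# auPRC, improvement arithmetic and the Wilcoxon signed-rank comparison.

#' Confusion counts from hard decisions
#'
#' @param decisions,labels vectors in `{-1, +1}` of equal length.
#' @return a list of class `confusion_counts` with fields `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion_counts <- function(decisions, labels) {
  if (length(decisions) != length(labels))
    stop("decisions and labels differ in length")
  structure(list(tp = sum(decisions == 1 & labels == 1),
                 fn = sum(decisions == -1 & labels == 1),
                 tn = sum(decisions == -1 & labels == -1),
                 fp = sum(decisions == 1 & labels == -1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and G-mean from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `G = sqrt(Sn * Sp)`. The G-mean is
#' the standard snapshot metric for heavily imbalanced recognition tasks:
#' it is high only when both classes are recognised well.
#'
#' @param counts a `confusion_counts` object, or a list/vector with fields
#'   `tp`, `fn`, `tn`, `fp`.
#' @return named numeric vector `c(sn, sp, g_mean)`.
#' @examples
#' rate_stats(list(tp = 1608, fn = 548, tn = 7693177, fp = 381413))
#' @export
rate_stats <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (tp + fn == 0 || tn + fp == 0)
    stop("rate_stats requires at least one instance of each class")
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  c(sn = sn, sp = sp, g_mean = sqrt(sn * sp))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counted 1/2. This
#' equals the trapezoidal area under the ROC curve and is invariant under
#' strictly increasing transforms of the scores.
#'
#' @param scores numeric ranking scores.
#' @param labels vector in `{-1, +1}`; both classes must be present.
#' @return the auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("auroc requires both classes")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average precision: each positive contributes the precision at its rank
#' in score-descending order, divided by the number of positives. Tied
#' scores are handled as a block: every positive in a tie group receives
#' the precision at the end of the group, which makes the value independent
#' of the arbitrary ordering within ties (the conservative step-function
#' convention). Under extreme imbalance the auPRC of a random ranker is
#' approximately the prevalence, hence very small.
#'
#' @param scores numeric ranking scores.
#' @param labels vector in `{-1, +1}`; at least one positive required.
#' @return the auPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  pos <- labels == 1
  np <- sum(pos)
  if (np == 0) stop("auprc requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))            # tie-group index, descending
  tp_g <- rowsum(as.integer(p), grp)[, 1]  # ordered by ascending group index
  n_g <- tabulate(grp)
  tp_end <- cumsum(tp_g)
  n_end <- cumsum(n_g)
  sum(tp_g * (tp_end / n_end)) / np
}

#' Relative improvement of a confusion count
#'
#' Percentage change of a count between a baseline method and a new
#' method: `100 * (new - old) / old` for counts that should increase
#' (TP, TN) and `100 * (old - new) / old` for counts that should shrink
#' (FN, FP).
#'
#' @param count_new,count_old non-negative counts; `count_old > 0`.
#' @param direction `"increase"` or `"reduction"`.
#' @return the improvement in percent, rounded to 2 decimal places.
#' @examples
#' relative_improvement(1965, 1608, "increase")  # TP gain
#' relative_improvement(191, 548, "reduction")   # FN cut
#' @export
relative_improvement <- function(count_new, count_old,
                                 direction = c("increase", "reduction")) {
  direction <- match.arg(direction)
  if (count_old <= 0) stop("baseline count must be positive")
  x <- if (direction == "increase") 100 * (count_new - count_old) / count_old
       else 100 * (count_old - count_new) / count_old
  round(x, 2)
}

#' Improvement of a \[0, 1\] performance measure, in percentage points
#'
#' Difference `100 * (value_new - value_old)`: the convention used when
#' reporting gains of G-mean, auROC or auPRC between methods.
#'
#' @param value_new,value_old measure values in \[0, 1\].
#' @return the gain in percentage points, rounded to 2 decimal places.
#' @export
measure_improvement <- function(value_new, value_old) {
  round(100 * (value_new - value_old), 2)
}

#' Wilcoxon signed-rank comparison of paired results
#'
#' Paired two-sided Wilcoxon signed-rank test using the normal
#' approximation without continuity correction: zero differences are
#' dropped, absolute differences are ranked with average ranks for ties,
#' `W+` is the rank sum of positive differences and
#' `z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)`.
#'
#' @param value_method,value_baseline paired numeric vectors (e.g. one
#'   G-mean per evaluation dataset for each method).
#' @return a list of class `paired_comparison` with `n` (pairs after
#'   dropping zero differences), `w_plus`, `z` and `p_two_sided`.
#' @export
wilcoxon_signed_rank <- function(value_method, value_baseline) {
  if (length(value_method) != length(value_baseline))
    stop("paired vectors differ in length")
  d <- value_method - value_baseline
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  r <- rank(abs(d))
  n <- length(d)
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (w_plus - mu) / sigma
  structure(list(n = n, w_plus = w_plus, z = z,
                 p_two_sided = 2 * pnorm(-abs(z))),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: n = %d, W+ = %g, z = %.4f, p = %.6f\n",
              x$n, x$w_plus, x$z, x$p_two_sided))
  invisible(x)
}

#' Full evaluation report for scored decisions
#'
#' Confusion counts plus Sn, Sp, G-mean, auROC and auPRC for one set of
#' ranking scores and hard decisions against true labels.
#'
#' @param scores numeric ranking scores.
#' @param decisions hard decisions in `{-1, +1}`.
#' @param labels true labels in `{-1, +1}`.
#' @return an object of class `evaluation_report`.
#' @export
evaluation_report <- function(scores, decisions, labels) {
  counts <- confusion_counts(decisions, labels)
  rates <- rate_stats(counts)
  structure(list(counts = counts, sn = unname(rates["sn"]),
                 sp = unname(rates["sp"]), g_mean = unname(rates["g_mean"]),
                 auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "auROC %.4f | auPRC %.4f | G %.4f | Sp %.4f | Sn %.4f | TP %d FN %d TN %d FP %d\n",
    x$auroc, x$auprc, x$g_mean, x$sp, x$sn,
    x$counts$tp, x$counts$fn, x$counts$tn, x$counts$fp))
  invisible(x)
}

# One report row in the canonical column order.
report_row <- function(report, objective, method, combination, n_models,
                       seconds) {
  data.frame(objective = objective, method = method,
             combination = combination,
             auROC = round(report$auroc, 4), auPRC = round(report$auprc, 4),
             G = round(report$g_mean, 4), Sp = round(report$sp, 4),
             Sn = round(report$sn, 4), TP = report$counts$tp,
             FN = report$counts$fn, TN = report$counts$tn,
             FP = report$counts$fp, n_models = n_models,
             seconds = round(seconds, 2), stringsAsFactors = FALSE)
}
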