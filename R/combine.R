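# Combination rules for effective outputs: sum, majority, maximum.

COMBINATION_RULES <- c("SUM", "MAJORITY", "MAXIMUM")

#' Combine effective outputs across an ensemble
#'
#' Combines one instance's effective outputs (one value per selected
#' scorer) into a single ranking score and a hard decision:
#'
#' * `combine_sum` — score is the sum of the outputs; decision `+1` iff
#'   the sum is strictly positive.
#' * `combine_majority` — each output votes by its sign (an exact 0 counts
#'   as a negative vote); the decision is the majority vote, with ties
#'   classified negative; the ranking score is the vote margin
#'   `(n+ - n-)/n`.
#' * `combine_max` — score is the output with the largest absolute value
#'   (ties broken towards the earliest scorer); decision `+1` iff that
#'   score is strictly positive.
#'
#' A combined score of exactly zero always classifies negative: under the
#' extreme class imbalance of site recognition this is the conservative
#' choice.
#'
#' @param effective numeric vector of effective outputs (length >= 1).
#' @return a list with elements `score` and `decision` (`+1`/`-1`).
#' @examples
#' combine_sum(c(0.2, 0.1, -0.9))
#' combine_majority(c(0.2, 0.1, -0.9))
#' combine_max(c(0.2, -0.9))
#' @export
combine_sum <- function(effective) {
  cmb <- combine_matrix(as_effective_matrix(effective), "SUM")
  list(score = cmb$score[1], decision = cmb$decision[1])
}

#' @rdname combine_sum
#' @export
combine_majority <- function(effective) {
  cmb <- combine_matrix(as_effective_matrix(effective), "MAJORITY")
  list(score = cmb$score[1], decision = cmb$decision[1])
}

#' @rdname combine_sum
#' @export
combine_max <- function(effective) {
  cmb <- combine_matrix(as_effective_matrix(effective), "MAXIMUM")
  list(score = cmb$score[1], decision = cmb$decision[1])
}

as_effective_matrix <- function(effective) {
  if (!length(effective)) stop("cannot combine an empty set of outputs")
  matrix(effective, ncol = 1L)
}

#' Vectorised combination over a score matrix
#'
#' Applies one combination rule column-wise to a matrix of effective
#' outputs (rows = scorers, columns = instances).
#'
#' @param E numeric matrix of effective outputs.
#' @param rule `"SUM"`, `"MAJORITY"` or `"MAXIMUM"`.
#' @return list with numeric `score` and integer `decision` vectors, one
#'   entry per column.
#' @export
combine_matrix <- function(E, rule = COMBINATION_RULES) {
  rule <- match.arg(rule)
  if (!is.matrix(E) || nrow(E) < 1L)
    stop("cannot combine an empty set of outputs")
  score <- switch(rule,
    SUM = colSums(E),
    MAJORITY = colMeans(ifelse(E > 0, 1, -1)),
    MAXIMUM = {
      idx <- max.col(t(abs(E)), ties.method = "first")
      E[cbind(idx, seq_len(ncol(E)))]
    })
  list(score = unname(score), decision = ifelse(score > 0, 1L, -1L))
}
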