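# Greedy stepwise ensemble selection over a pool of calibrated scorers.

OBJECTIVES <- c("G_MEAN", "AUROC", "AUPRC")

#' Cache effective outputs of a scorer pool on a dataset
#'
#' Evaluates every pool scorer once on every instance so that subsequent
#' subset evaluations reduce to vector arithmetic. Each scorer's window is
#' re-extracted from the dataset's records according to its own window
#' specification; instances for which any scorer's window overflows a
#' sequence boundary are dropped consistently across the whole pool.
#'
#' @param pool list of `calibrated_scorer` objects.
#' @param data a `window_set` (typically the untouched validation or test
#'   split).
#' @return an object of class `score_matrix`: list with `E` (matrix of
#'   effective outputs, rows = scorers, columns = instances), `labels`,
#'   `tags` and `kept` (row indices of `data$candidates` retained).
#' @export
cache_effective_outputs <- function(pool, data) {
  stopifnot(length(pool) >= 1L, inherits(data, "window_set"))
  cand <- data$candidates
  wins <- lapply(pool, function(cal) {
    spec <- cal$base$window
    if (spec$lo == data$window$lo && spec$hi == data$window$hi)
      return(cand$window_seq)  # already extracted at this window
    out <- rep(NA_character_, nrow(cand))
    for (id in unique(cand$seq_id)) {
      sel <- cand$seq_id == id
      out[sel] <- extract_windows(data$records[[id]], cand$position[sel],
                                  cand$strand[sel], spec)
    }
    out
  })
  keep <- Reduce(`&`, lapply(wins, function(w) !is.na(w)))
  if (!all(keep))
    warnf("%d instance(s) dropped: window out of bounds for some scorer",
          sum(!keep))
  if (!any(keep)) stop("no instance is in bounds for every scorer")
  E <- do.call(rbind, lapply(seq_along(pool), function(i) {
    effective_output(pool[[i]], wins[[i]][keep])
  }))
  tags <- vapply(pool, function(cal) cal$base$source_tag, character(1))
  structure(list(E = E, labels = cand$label[keep], tags = tags,
                 kept = which(keep)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d scorers x %d instances (%d positives)\n",
              nrow(x$E), ncol(x$E), sum(x$labels == 1L)))
  invisible(x)
}

objective_value <- function(score, decision, labels, objective) {
  switch(objective,
         G_MEAN = {
           sn <- sum(decision == 1 & labels == 1) / sum(labels == 1)
           sp <- sum(decision == -1 & labels == -1) / sum(labels == -1)
           sqrt(sn * sp)
         },
         AUROC = auroc(score, labels),
         AUPRC = auprc(score, labels))
}

#' Evaluate a scorer subset on cached outputs
#'
#' Combines the subset's effective outputs per instance under the given
#' rule and computes the objective on the unmodified (imbalanced) labels.
#'
#' @param sm a `score_matrix` from [cache_effective_outputs()].
#' @param subset non-empty integer vector of scorer (row) indices.
#' @param rule combination rule (`"SUM"`, `"MAJORITY"`, `"MAXIMUM"`).
#' @param objective `"G_MEAN"`, `"AUROC"` or `"AUPRC"`.
#' @return the objective value.
#' @export
evaluate_subset <- function(sm, subset, rule = "SUM", objective = "G_MEAN") {
  stopifnot(inherits(sm, "score_matrix"))
  if (!length(subset)) stop("cannot evaluate an empty subset")
  rule <- match.arg(rule, COMBINATION_RULES)
  objective <- match.arg(objective, OBJECTIVES)
  cmb <- combine_matrix(sm$E[subset, , drop = FALSE], rule)
  objective_value(cmb$score, cmb$decision, sm$labels, objective)
}

new_stepwise_ensemble <- function(selected, rule, objective, method, value,
                                  trace, n_evaluations, sm) {
  structure(list(selected = selected, rule = rule, objective = objective,
                 method = method, validation_value = value, trace = trace,
                 n_evaluations = n_evaluations, n_pool = nrow(sm$E),
                 tags = sm$tags[selected]),
            class = "stepwise_ensemble")
}

#' Greedy stepwise ensemble selection
#'
#' `constructive_selection` implements forward selection: starting from the
#' empty set, at each step the candidate scorer whose addition maximises
#' the validation objective is added; the process stops as soon as the best
#' addition no longer *strictly* improves the objective. `destructive_selection`
#' implements backward elimination: starting from the full pool, each round
#' evaluates every single removal and performs the one yielding the highest
#' after-removal objective, provided it does not decrease the current value;
#' it stops when every scorer has a positive effect (or one scorer is left).
#' Both evaluate at most `n(n+1)/2` subsets — against the `2^n - 1` of
#' exhaustive search — and break ties towards the lowest scorer index.
#'
#' @param sm a `score_matrix` over the validation split.
#' @param rule combination rule.
#' @param objective validation objective to maximise.
#' @return an object of class `stepwise_ensemble` with the ordered selected
#'   indices, the achieved `validation_value`, the selection `trace`
#'   (action, scorer index, objective after the step) and the number of
#'   subset evaluations spent.
#' @export
constructive_selection <- function(sm, rule = "SUM", objective = "G_MEAN") {
  n <- nrow(sm$E)
  selected <- integer(0)
  current <- -Inf
  trace <- list()
  evals <- 0L
  repeat {
    cand <- setdiff(seq_len(n), selected)
    if (!length(cand)) break
    vals <- vapply(cand, function(c)
      evaluate_subset(sm, c(selected, c), rule, objective), numeric(1))
    evals <- evals + length(cand)
    best <- which.max(vals)  # first max = lowest index (cand is ascending)
    if (length(selected) && vals[best] <= current) break
    selected <- c(selected, cand[best])
    current <- vals[best]
    trace[[length(trace) + 1L]] <-
      data.frame(action = "add", index = cand[best], value = current)
  }
  new_stepwise_ensemble(selected, rule, objective, "constructive", current,
                        do.call(rbind, trace), evals, sm)
}

#' @rdname constructive_selection
#' @export
destructive_selection <- function(sm, rule = "SUM", objective = "G_MEAN") {
  n <- nrow(sm$E)
  selected <- seq_len(n)
  current <- evaluate_subset(sm, selected, rule, objective)
  evals <- 1L
  trace <- list(data.frame(action = "start", index = NA_integer_,
                           value = current))
  while (length(selected) > 1L) {
    vals <- vapply(seq_along(selected), function(i)
      evaluate_subset(sm, selected[-i], rule, objective), numeric(1))
    evals <- evals + length(selected)
    best <- which.max(vals)
    if (vals[best] < current) break  # every scorer has a positive effect
    removed <- selected[best]
    selected <- selected[-best]
    current <- vals[best]
    trace[[length(trace) + 1L]] <-
      data.frame(action = "remove", index = removed, value = current)
  }
  new_stepwise_ensemble(selected, rule, objective, "destructive", current,
                        do.call(rbind, trace), evals, sm)
}

#' Best of the six stepwise/combination variants
#'
#' Runs both stepwise algorithms under each of the three combination rules
#' and returns the ensemble with the highest validation objective. Ties are
#' broken in the fixed order constructive before destructive and SUM,
#' MAJORITY, MAXIMUM within each method.
#'
#' @inheritParams constructive_selection
#' @return the winning `stepwise_ensemble`; the attribute `"candidates"`
#'   holds a data frame summarising all six runs.
#' @export
best_of_six <- function(sm, objective = "G_MEAN") {
  runs <- list()
  for (method in c("constructive", "destructive"))
    for (rule in COMBINATION_RULES) {
      fn <- if (method == "constructive") constructive_selection
            else destructive_selection
      runs[[paste(method, rule, sep = ":")]] <- fn(sm, rule, objective)
    }
  vals <- vapply(runs, `[[`, numeric(1), "validation_value")
  best <- runs[[which.max(vals)]]
  attr(best, "candidates") <- data.frame(
    method = sub(":.*", "", names(runs)), rule = sub(".*:", "", names(runs)),
    n_models = vapply(runs, function(r) length(r$selected), integer(1)),
    validation_value = unname(vals), stringsAsFactors = FALSE)
  attr(best, "all_runs") <- runs
  best
}

#' Exhaustive subset oracle
#'
#' Evaluates every one of the `2^n - 1` non-empty subsets and returns the
#' true optimum. Exponential: only feasible for small pools, and used as a
#' reference to bound the greedy algorithms in tests.
#'
#' @inheritParams constructive_selection
#' @param max_n guard on the pool size (default 15).
#' @return list with the optimal `subset` and its `value`.
#' @export
exhaustive_subset_oracle <- function(sm, rule = "SUM", objective = "G_MEAN",
                                     max_n = 15L) {
  n <- nrow(sm$E)
  if (n > max_n) stopf("pool too large for exhaustive search (%d > %d)",
                       n, max_n)
  best_val <- -Inf
  best_sub <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    v <- evaluate_subset(sm, subset, rule, objective)
    if (v > best_val) {
      best_val <- v
      best_sub <- subset
    }
  }
  list(subset = best_sub, value = best_val)
}

#' @export
print.stepwise_ensemble <- function(x, ...) {
  cat(sprintf(
    "<stepwise_ensemble> %s/%s, objective %s = %.4f\n  %d of %d scorers: %s\n",
    x$method, x$rule, x$objective, x$validation_value, length(x$selected),
    x$n_pool, paste(x$tags, collapse = ", ")))
  invisible(x)
}

#' @export
summary.stepwise_ensemble <- function(object, ...) {
  print(object)
  cat(sprintf("  %d subset evaluations (greedy bound %d)\n",
              object$n_evaluations,
              object$n_pool * (object$n_pool + 1) / 2))
  if (!is.null(object$trace)) {
    cat("  trace:\n")
    print(object$trace, row.names = FALSE)
  }
  invisible(object)
}

#' Predict with a selected ensemble
#'
#' Applies the ensemble's combination rule to the selected rows of a score
#' matrix (or plain matrix of effective outputs aligned with the original
#' pool).
#'
#' @param object a `stepwise_ensemble`.
#' @param newdata a `score_matrix` or a numeric matrix with one row per
#'   pool scorer.
#' @param ... unused.
#' @return data frame with columns `score` and `decision`.
#' @export
predict.stepwise_ensemble <- function(object, newdata, ...) {
  E <- if (inherits(newdata, "score_matrix")) newdata$E else newdata
  if (nrow(E) != object$n_pool)
    stopf("score matrix has %d rows but the pool had %d", nrow(E),
          object$n_pool)
  cmb <- combine_matrix(E[object$selected, , drop = FALSE], object$rule)
  data.frame(score = cmb$score, decision = cmb$decision)
}

#' Plot a stepwise selection trace
#'
#' Objective value after each accepted step of the greedy selection.
#'
#' @param x a `stepwise_ensemble`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stepwise_ensemble <- function(x, ...) {
  tr <- x$trace
  graphics::plot(seq_len(nrow(tr)), tr$value, type = "b", pch = 19,
                 xlab = "step", ylab = x$objective,
                 main = sprintf("%s selection (%s)", x$method, x$rule), ...)
  invisible(x)
}
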