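# Window and hyperparameter selection by stratified cross-validation.

#' Default hyperparameter grids
#'
#' The full grids explored when training a pool at scale: SVM cost
#' `C in {1, 10, 100, 1000}` and weighted-degree `d in {12, 24}`; k-NN
#' `k in 1..100`; the 13-window grid of [default_window_grid()] (plus the
#' long one-sided windows of [extra_stop_windows()] for the stop-codon
#' method). Scaled-down studies pass smaller grids explicitly.
#'
#' @param site_type `"TIS"` or `"STOP"`.
#' @return named list with `svm_C`, `svm_d`, `knn_k`, `window_grid` and
#'   `extra_stop_windows`.
#' @export
default_hyperparam_grid <- function(site_type = c("TIS", "STOP")) {
  site_type <- match.arg(site_type)
  list(svm_C = c(1, 10, 100, 1000), svm_d = c(12L, 24L), knn_k = 1:100,
       window_grid = default_window_grid(),
       extra_stop_windows = extra_stop_windows(site_type))
}

# expand the kind-relevant hyperparameter combinations of a grid
expand_hyperparams <- function(kind, grid) {
  switch(kind,
    WD_SVM = {
      combos <- expand.grid(svm_C = grid$svm_C %||% 10,
                            svm_d = grid$svm_d %||% 12L)
      lapply(seq_len(nrow(combos)), function(i)
        list(svm_C = combos$svm_C[i], svm_d = combos$svm_d[i]))
    },
    KNN = lapply(grid$knn_k %||% 5L, function(k) list(knn_k = k)),
    list(list()))  # PWM, tree, stop-codon method: no grid
}

# mean cross-validated objective of one (kind, dataset, hyperparams) choice
cv_objective <- function(kind, data, hyperparams, folds, seed, objective) {
  lab <- data$candidates$label
  fold_id <- stratified_folds(lab, folds, seed)
  vals <- numeric(0)
  for (f in sort(unique(fold_id))) {
    tr <- data; tr$candidates <- data$candidates[fold_id != f, , drop = FALSE]
    te_idx <- fold_id == f
    if (!any(lab[te_idx] == 1L) || !any(lab[te_idx] == -1L)) next
    fit <- try(fit_scorer(kind, tr, hyperparams, seed = derive_seed(seed, f)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(-Inf)
    raw_tr <- raw_score(fit, tr$candidates$window_seq)
    raw_te <- raw_score(fit, data$candidates$window_seq[te_idx])
    v <- if (objective == "G_MEAN") {
      rng <- range(raw_tr)
      if (diff(rng) == 0) {
        0
      } else {
        th <- calibrate_threshold(scale_output(raw_tr, rng[1], rng[2]),
                                  tr$candidates$label)
        dec <- ifelse(scale_output(raw_te, rng[1], rng[2]) > th, 1L, -1L)
        objective_value(NULL, dec, lab[te_idx], "G_MEAN")
      }
    } else objective_value(raw_te, NULL, lab[te_idx], objective)
    vals <- c(vals, v)
  }
  if (!length(vals)) -Inf else mean(vals)
}

#' Select a scorer's window and hyperparameters by cross-validation
#'
#' Evaluates every (window, hyperparameter) combination of the grid by
#' stratified k-fold cross-validation on the training data and returns the
#' combination with the best mean objective. Ties are broken towards the
#' earlier grid entry; a single-combination grid is returned immediately
#' without any cross-validation.
#'
#' @param kind scorer kind, see [fit_scorer()].
#' @param datasets named list of `window_set`s, one per candidate window
#'   (as built by [build_dataset()] at each window of the grid).
#' @param grid hyperparameter grid, see [default_hyperparam_grid()].
#' @param folds number of cross-validation folds (10 at full scale).
#' @param seed integer seed.
#' @param objective cross-validation objective.
#' @return list with elements `window` (a [window_spec()]), `hyperparams`
#'   and `cv_value` (`NA` when no search was needed).
#' @export
select_window_and_hyperparams <- function(kind, datasets, grid = list(),
                                          folds = 10L, seed = 1L,
                                          objective = "G_MEAN") {
  if (!length(datasets)) stop("empty window grid")
  combos <- list()
  for (w in seq_along(datasets)) {
    for (hp in expand_hyperparams(kind, grid)) {
      combos[[length(combos) + 1L]] <- list(w = w, hp = hp)
    }
  }
  if (length(combos) == 1L)
    return(list(window = datasets[[1]]$window,
                hyperparams = combos[[1]]$hp, cv_value = NA_real_))
  vals <- vapply(combos, function(cmb) {
    cv_objective(kind, datasets[[cmb$w]], cmb$hp, folds,
                 derive_seed(seed, 31L), objective)
  }, numeric(1))
  best <- combos[[which.max(vals)]]  # first max = earliest grid entry
  list(window = datasets[[best$w]]$window, hyperparams = best$hp,
       cv_value = max(vals))
}
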