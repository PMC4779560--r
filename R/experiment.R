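# End-to-end experiment driver: train and calibrate a scorer pool from
# source genomes, run stepwise selection per objective on the validation
# split, and evaluate winners and the single-best baseline on the test
# split.

#' Configure a site-recognition experiment
#'
#' @param sources named list of sources; each element is a list with
#'   `fasta` and `sites` paths, or pre-loaded `records` (list of
#'   [genome_record()]) and `annotations`.
#' @param validation,test like a source entry: the target's validation and
#'   test splits (used unmodified, never undersampled).
#' @param site_type `"TIS"` or `"STOP"`.
#' @param objectives subset of `c("G_MEAN", "AUROC", "AUPRC")`.
#' @param kinds scorer kinds to include in the pool.
#' @param window_grid list of candidate [window_spec()]s explored per
#'   scorer; a single window skips the search.
#' @param stop_window_grid window grid for the stop-codon method (defaults
#'   to the coding-side window `[0, 50]` for TIS, `[-50, 0]` for STOP).
#' @param grid hyperparameter grid (see [default_hyperparam_grid()]).
#' @param folds cross-validation folds for window/hyperparameter search.
#' @param calib_folds folds for output calibration.
#' @param seed master seed for undersampling, folds and tree pruning.
#' @param out_dir optional directory for report files.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(sources, validation, test,
                              site_type = c("TIS", "STOP"),
                              objectives = "G_MEAN",
                              kinds = SCORER_KINDS,
                              window_grid = list(window_spec(-10, 15)),
                              stop_window_grid = NULL,
                              grid = list(svm_C = 10, svm_d = 4L, knn_k = 5L),
                              folds = 10L, calib_folds = 5L, seed = 1L,
                              out_dir = NULL) {
  site_type <- match.arg(site_type)
  stopifnot(all(objectives %in% OBJECTIVES), all(kinds %in% SCORER_KINDS))
  if (is.null(stop_window_grid))
    stop_window_grid <- list(if (site_type == "TIS") window_spec(0, 50)
                             else window_spec(-50, 0))
  structure(list(sources = sources, validation = validation, test = test,
                 site_type = site_type, objectives = objectives,
                 kinds = kinds, window_grid = window_grid,
                 stop_window_grid = stop_window_grid, grid = grid,
                 folds = as.integer(folds),
                 calib_folds = as.integer(calib_folds),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Configure an experiment from a generated study directory
#'
#' Convenience constructor reading the `manifest.json` written by
#' [generate_study()]: every `source` entry becomes a training source and
#' the target validation/test splits are wired up.
#'
#' @param dir directory produced by [generate_study()].
#' @param ... further arguments passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
study_experiment_config <- function(dir, ...) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  entry <- function(e) list(fasta = file.path(dir, e$fasta),
                            sites = file.path(dir, e$sites))
  sources <- list()
  validation <- test <- NULL
  for (e in manifest$files) {
    if (e$role == "source") sources[[e$tag]] <- entry(e)
    else if (e$role == "validation") validation <- entry(e)
    else if (e$role == "test") test <- entry(e)
  }
  experiment_config(sources = sources, validation = validation, test = test,
                    site_type = manifest$site_type, ...)
}

load_source <- function(src, tag = NULL) {
  if (!is.null(src$records)) {
    records <- src$records
    if (!is.null(tag))
      records <- lapply(records, function(r) { r$species_tag <- tag; r })
    list(records = records, annotations = src$annotations)
  } else {
    list(records = read_genome_fasta(src$fasta, species_tag = tag),
         annotations = read_site_annotations(src$sites))
  }
}

#' Run a site-recognition experiment end to end
#'
#' For every source and scorer kind: selects the window and hyperparameters
#' by cross-validation (skipped for single-combination grids), fits on the
#' randomly undersampled source dataset and calibrates output scaling and
#' optimal threshold. The calibrated pool's effective outputs are cached on
#' the validation split; per objective, the six stepwise/combination
#' variants are run and the best is kept. The winning ensembles and the
#' single best-validating scorer (the "standard approach" baseline) are
#' then evaluated once on the untouched test split.
#'
#' @param cfg an [experiment_config()].
#' @return an object of class `site_experiment` with the pool, the chosen
#'   ensembles, the test report table and diagnostic counters. When
#'   `cfg$out_dir` is set, the report table, selection traces and scorer
#'   files are also written there.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  src_names <- names(cfg$sources)
  if (is.null(src_names) || any(!nzchar(src_names)))
    stop("sources must be a named list")

  ## stage 1: train and calibrate the pool -----------------------------
  pool <- list()
  selections <- list()
  for (s in seq_along(cfg$sources)) {
    tag <- src_names[s]
    src <- load_source(cfg$sources[[s]], tag)
    src_seed <- derive_seed(cfg$seed, s)
    for (kind in cfg$kinds) {
      wgrid <- if (kind == "STOP_CODON_METHOD") cfg$stop_window_grid
               else cfg$window_grid
      datasets <- lapply(wgrid, function(w) {
        d <- build_dataset(src$records, src$annotations, cfg$site_type, w)
        random_undersample(d, seed = derive_seed(src_seed, 3L))
      })
      names(datasets) <- vapply(wgrid, format, character(1))
      sel <- select_window_and_hyperparams(kind, datasets, cfg$grid,
                                           folds = cfg$folds,
                                           seed = src_seed)
      data <- datasets[[format(sel$window)]]
      cal <- fit_calibrated_scorer(kind, data, sel$hyperparams,
                                   folds = cfg$calib_folds, seed = src_seed,
                                   source_tag = paste0(tag, ":", kind))
      pool[[paste0(tag, ":", kind)]] <- cal
      selections[[paste0(tag, ":", kind)]] <-
        list(window = format(sel$window), hyperparams = sel$hyperparams,
             cv_value = sel$cv_value)
    }
  }
  t_train <- proc.time()[["elapsed"]] - t0

  ## stage 2: cache validation outputs ---------------------------------
  val <- load_source(cfg$validation)
  val_set <- build_dataset(val$records, val$annotations, cfg$site_type,
                           window_spec(0, 2))
  sm_val <- cache_effective_outputs(pool, val_set)

  ## stage 3: stepwise selection per objective -------------------------
  ensembles <- list()
  baselines <- list()
  sel_seconds <- list()
  for (obj in cfg$objectives) {
    t1 <- proc.time()[["elapsed"]]
    ensembles[[obj]] <- best_of_six(sm_val, obj)
    sel_seconds[[obj]] <- proc.time()[["elapsed"]] - t1
    single_vals <- vapply(seq_along(pool), function(i)
      evaluate_subset(sm_val, i, "SUM", obj), numeric(1))
    baselines[[obj]] <- list(index = which.max(single_vals),
                             validation_value = max(single_vals))
  }

  ## stage 4: single evaluation pass on the test split ------------------
  te <- load_source(cfg$test)
  test_set <- build_dataset(te$records, te$annotations, cfg$site_type,
                            window_spec(0, 2))
  sm_test <- cache_effective_outputs(pool, test_set)
  test_cache_builds <- 1L

  rows <- list()
  test_reports <- list()
  for (obj in cfg$objectives) {
    bi <- baselines[[obj]]$index
    base_cmb <- combine_matrix(sm_test$E[bi, , drop = FALSE], "SUM")
    base_rep <- evaluation_report(base_cmb$score, base_cmb$decision,
                                  sm_test$labels)
    rows[[paste0(obj, ":std")]] <-
      report_row(base_rep, obj, "Std", "-", 1L, NA_real_)
    ens <- ensembles[[obj]]
    pred <- predict(ens, sm_test)
    ens_rep <- evaluation_report(pred$score, pred$decision, sm_test$labels)
    rows[[paste0(obj, ":ens")]] <-
      report_row(ens_rep, obj,
                 if (ens$method == "constructive") "Cons" else "Dest",
                 c(SUM = "Sum", MAJORITY = "Majority",
                   MAXIMUM = "Maximum")[[ens$rule]],
                 length(ens$selected), sel_seconds[[obj]])
    test_reports[[obj]] <- list(ensemble = ens_rep, standard = base_rep,
                                standard_tag = sm_test$tags[bi])
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  result <- structure(list(
    pool = pool, selections = selections, ensembles = ensembles,
    baselines = baselines, validation_matrix = sm_val,
    test_matrix = sm_test, report = report, test_reports = test_reports,
    counters = list(
      pool_size = length(pool),
      test_cache_builds = test_cache_builds,
      subset_evaluations = vapply(ensembles, function(e)
        sum(vapply(attr(e, "all_runs"), `[[`, integer(1), "n_evaluations")),
        integer(1))),
    seconds = proc.time()[["elapsed"]] - t0, train_seconds = t_train,
    site_type = cfg$site_type, seed = cfg$seed),
    class = "site_experiment")

  if (!is.null(cfg$out_dir)) write_report(result, cfg$out_dir)
  result
}

#' Write experiment reports to disk
#'
#' Writes the tabular test report (`report.tsv`, one row per
#' objective/method in the canonical column order), a JSON trace per
#' winning ensemble and a serialised JSON file per calibrated pool scorer.
#'
#' @param result a `site_experiment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "site_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(result$report, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (obj in names(result$ensembles))
    write_ensemble_trace(result$ensembles[[obj]],
                         file.path(dir, sprintf("trace_%s.json", obj)))
  sdir <- file.path(dir, "scorers")
  dir.create(sdir, showWarnings = FALSE)
  for (tag in names(result$pool))
    write_calibrated_scorer(result$pool[[tag]],
                            file.path(sdir, paste0(gsub(":", "_", tag),
                                                   ".json")))
  invisible(dir)
}

#' @export
print.site_experiment <- function(x, ...) {
  cat(sprintf("<site_experiment> %s: pool of %d scorers, seed %d\n",
              x$site_type, length(x$pool), x$seed))
  print(x$report)
  invisible(x)
}

#' Published benchmark results bundled with the package
#'
#' Reference test-set performance of the standard single-classifier
#' approach and of the stepwise ensembles (one per optimised objective)
#' for TIS and stop codon recognition on five human test chromosomes.
#' Used for worked examples of the metric and comparison utilities.
#'
#' @return data frame with columns `task`, `chromosome`, `objective`,
#'   `method`, `combination`, `auroc`, `auprc`, `g`, `sp`, `sn`, `tp`,
#'   `fn`, `tn`, `fp`, `n_models`.
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_site_results.tsv",
                      package = "stepsite", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
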