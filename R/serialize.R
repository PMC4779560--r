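# Versioned JSON serialisation of calibrated scorers and ensembles.

SERIAL_VERSION <- 1L

scorer_params_out <- function(base) {
  switch(base$kind,
    PWM = list(logodds = base$logodds, pseudocount = base$pseudocount),
    KNN = list(train = decode_windows(base$train), labels = base$labels,
               k = base$k),
    DECISION_TREE = list(root = base$root, prune_frac = base$prune_frac),
    WD_SVM = list(sv = decode_windows(base$sv), coef = base$coef, b = base$b,
                  orient = base$orient, C = base$C, degree = base$degree),
    STOP_CODON_METHOD = list())
}

scorer_params_in <- function(kind, p) {
  cls <- switch(kind, PWM = "pwm_scorer", KNN = "knn_scorer",
                DECISION_TREE = "tree_scorer", WD_SVM = "wd_svm_scorer",
                STOP_CODON_METHOD = "stop_codon_scorer")
  fields <- switch(kind,
    PWM = list(logodds = matrix(unlist(p$logodds), nrow = 5L),
               pseudocount = p$pseudocount),
    KNN = list(train = encode_windows(unlist(p$train)),
               labels = as.integer(unlist(p$labels)), k = as.integer(p$k)),
    DECISION_TREE = list(root = rebuild_tree_node(p$root),
                         prune_frac = p$prune_frac),
    WD_SVM = list(sv = encode_windows(unlist(p$sv)),
                  coef = as.numeric(unlist(p$coef)), b = p$b,
                  orient = p$orient, C = p$C, degree = as.integer(p$degree)),
    STOP_CODON_METHOD = list())
  structure(fields, class = cls)
}

rebuild_tree_node <- function(nd) {
  out <- list(n_pos = nd$n_pos, n_neg = nd$n_neg, score = nd$score,
              leaf = isTRUE(nd$leaf))
  if (!out$leaf) {
    out$split_pos <- as.integer(nd$split_pos)
    out$children <- lapply(nd$children, rebuild_tree_node)
  }
  out
}

#' Serialise a calibrated scorer to JSON
#'
#' Writes (and reads back) a self-contained, versioned JSON description of
#' a calibrated scorer: kind, window, fitted parameters, output scaling,
#' optimal threshold and source tag. Round-tripping reproduces identical
#' effective outputs.
#'
#' @param cal a `calibrated_scorer`.
#' @param path output file path.
#' @return `path` invisibly (`write`), or the restored `calibrated_scorer`
#'   (`read`).
#' @export
write_calibrated_scorer <- function(cal, path) {
  stopifnot(inherits(cal, "calibrated_scorer"))
  b <- cal$base
  obj <- list(format = "stepsite-scorer", version = SERIAL_VERSION,
              kind = b$kind, site_type = b$site_type,
              source_tag = b$source_tag,
              window = c(b$window$lo, b$window$hi),
              scale_min = cal$scale_min, scale_max = cal$scale_max,
              th_optimal = cal$th_optimal, objective = cal$objective,
              params = scorer_params_out(b))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibrated_scorer
#' @export
read_calibrated_scorer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "stepsite-scorer"))
    stopf("%s is not a serialised scorer", path)
  base <- scorer_params_in(obj$kind, obj$params)
  base$kind <- obj$kind
  base$window <- window_spec(obj$window[1], obj$window[2])
  base$site_type <- obj$site_type
  base$source_tag <- obj$source_tag
  class(base) <- c(class(base), "site_scorer")
  structure(list(base = base, scale_min = obj$scale_min,
                 scale_max = obj$scale_max, th_optimal = obj$th_optimal,
                 objective = obj$objective),
            class = "calibrated_scorer")
}

write_ensemble_trace <- function(ensemble, path) {
  obj <- list(format = "stepsite-ensemble", version = SERIAL_VERSION,
              method = ensemble$method, rule = ensemble$rule,
              objective = ensemble$objective,
              validation_value = ensemble$validation_value,
              selected = ensemble$selected, tags = ensemble$tags,
              n_evaluations = ensemble$n_evaluations,
              trace = ensemble$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
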