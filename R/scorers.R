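# The five base scorer families with a uniform fit/score contract.

SCORER_KINDS <- c("STOP_CODON_METHOD", "DECISION_TREE", "KNN", "PWM", "WD_SVM")

#' Fit a base scorer
#'
#' Fits one of the five base scorer families on a balanced labelled window
#' set. All scorers share a uniform contract: [raw_score()] maps a window
#' string to a real-valued confidence, larger = more site-like.
#'
#' * `PWM` — per-position log-odds of positive vs negative base
#'   frequencies, pseudocount 1.
#' * `DECISION_TREE` — gain-ratio categorical tree over window positions
#'   with reduced-error pruning on a held-out fraction of the training data.
#' * `KNN` — stored training windows, Hamming distance; score
#'   `(k+ - k-)/k` over the `k` nearest neighbours.
#' * `WD_SVM` — soft-margin SVM with the weighted-degree string kernel
#'   ([wd_kernel()]); the quadratic program is solved by
#'   [kernlab::ksvm()] on the precomputed Gram matrix.
#' * `STOP_CODON_METHOD` — parameterless; score is minus the number of
#'   in-frame stop codons in the coding-side flank
#'   ([in_frame_stop_count()]).
#'
#' @param kind one of `r paste0('"', SCORER_KINDS, '"', collapse = ", ")`.
#' @param data a `window_set` (normally balanced by [random_undersample()])
#'   with at least one example of each class.
#' @param hyperparams named list of kind-specific hyperparameters
#'   (`svm_C`, `svm_d`, `knn_k`, `tree_prune_frac`, `pwm_pseudocount`).
#' @param seed integer seed (used for the tree's pruning hold-out split).
#' @param source_tag text recording the dataset of origin, e.g. `"MaM:WD_SVM"`.
#' @return an object inheriting from class `site_scorer`.
#' @export
fit_scorer <- function(kind, data, hyperparams = list(), seed = 1L,
                       source_tag = NULL) {
  kind <- match.arg(kind, SCORER_KINDS)
  stopifnot(inherits(data, "window_set"))
  lab <- data$candidates$label
  if (kind != "STOP_CODON_METHOD" &&
      (!any(lab == 1L) || !any(lab == -1L)))
    stop("training data must contain both classes")
  hp <- hyperparams
  scorer <- switch(kind,
    PWM = fit_pwm(data, pseudocount = hp$pwm_pseudocount %||% 1),
    KNN = fit_hamming_knn(data, k = hp$knn_k %||% 5L),
    DECISION_TREE = fit_gain_ratio_tree(
      data, prune_frac = hp$tree_prune_frac %||% 0.2, seed = seed),
    WD_SVM = fit_wd_svm(data, C = hp$svm_C %||% 10,
                        D = hp$svm_d %||% 12L),
    STOP_CODON_METHOD = fit_stop_codon_method(data))
  scorer$kind <- kind
  scorer$window <- data$window
  scorer$site_type <- data$site_type
  scorer$source_tag <- source_tag %||%
    paste0(data$records[[1]]$species_tag, ":", kind)
  class(scorer) <- c(class(scorer), "site_scorer")
  scorer
}

#' Raw score of a fitted scorer
#'
#' Deterministic real-valued confidence for each window string; larger
#' values are more site-like. Window lengths must match the scorer's
#' window specification.
#'
#' @param scorer a fitted scorer from [fit_scorer()].
#' @param windows character vector of window strings.
#' @return numeric vector of raw scores.
#' @export
raw_score <- function(scorer, windows) {
  stopifnot(inherits(scorer, "site_scorer"))
  L <- window_length(scorer$window)
  if (any(nchar(windows) != L))
    stopf("window length mismatch: scorer expects %d bases", L)
  UseMethod("raw_score")
}

#' @export
print.site_scorer <- function(x, ...) {
  cat(sprintf("<site_scorer:%s> %s, window %s [%s]\n",
              x$kind, x$site_type, format(x$window), x$source_tag))
  invisible(x)
}

#' @export
predict.site_scorer <- function(object, newdata, ...) raw_score(object, newdata)

## ---- PWM -------------------------------------------------------------

fit_pwm <- function(data, pseudocount = 1) {
  cand <- data$candidates
  pos <- encode_windows(cand$window_seq[cand$label == 1L])
  neg <- encode_windows(cand$window_seq[cand$label == -1L])
  L <- ncol(pos)
  logodds <- matrix(0, nrow = 5L, ncol = L)
  for (j in seq_len(L)) {
    cp <- tabulate(pos[, j][pos[, j] <= 4L], nbins = 4L)
    cn <- tabulate(neg[, j][neg[, j] <= 4L], nbins = 4L)
    pp <- (c(cp, 0) + pseudocount) / (sum(cp) + 4 * pseudocount)
    pn <- (c(cn, 0) + pseudocount) / (sum(cn) + 4 * pseudocount)
    logodds[, j] <- log(pp / pn)
  }
  rownames(logodds) <- DNA_ALPHABET
  structure(list(logodds = logodds, pseudocount = pseudocount),
            class = "pwm_scorer")
}

#' @export
raw_score.pwm_scorer <- function(scorer, windows) {
  enc <- encode_windows(windows)
  n <- nrow(enc); L <- ncol(enc)
  idx <- cbind(as.vector(enc), rep(seq_len(L), each = n))
  rowSums(matrix(scorer$logodds[idx], nrow = n, ncol = L))
}

## ---- Hamming k-NN ----------------------------------------------------

#' Hamming distance between equal-length strings
#'
#' Number of mismatching positions. `N` mismatches every base, including
#' another `N`.
#'
#' @param x,y DNA strings of equal length.
#' @return integer mismatch count.
#' @examples
#' hamming_distance("AAAA", "TTTT")
#' hamming_distance("AN", "AN")  # 1: N never matches
#' @export
hamming_distance <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("sequence lengths differ")
  a <- encode_windows(x); b <- encode_windows(y)
  sum(a != b | a == 5L | b == 5L)
}

fit_hamming_knn <- function(data, k = 5L) {
  cand <- data$candidates
  k <- as.integer(k)
  if (k < 1L || k > nrow(cand))
    stopf("knn_k must be in [1, %d]", nrow(cand))
  structure(list(train = encode_windows(cand$window_seq),
                 labels = cand$label, k = k),
            class = "knn_scorer")
}

#' @export
raw_score.knn_scorer <- function(scorer, windows) {
  enc <- encode_windows(windows)
  tr <- scorer$train
  lab <- scorer$labels
  k <- scorer$k
  n_tr <- nrow(tr)
  vapply(seq_len(nrow(enc)), function(i) {
    q <- enc[i, ]
    qm <- matrix(q, nrow = n_tr, ncol = length(q), byrow = TRUE)
    d <- rowSums(tr != qm | tr == 5L | qm == 5L)
    # stable order: ties at the k-th distance broken by training order
    sel <- order(d)[seq_len(k)]
    (sum(lab[sel] == 1L) - sum(lab[sel] == -1L)) / k
  }, numeric(1))
}

## ---- Stop codon method ----------------------------------------------

#' Count in-frame stop codons in a candidate window
#'
#' Counts TAA/TAG/TGA occurrences at offsets that are multiples of 3
#' relative to the candidate codon, restricted to the coding side: strictly
#' downstream of the codon for TIS candidates (a true start is followed by
#' stop-free coding sequence) and strictly upstream for stop-codon
#' candidates (a true stop terminates stop-free coding sequence).
#'
#' @param windows character vector of window strings.
#' @param site_type `"TIS"` or `"STOP"`.
#' @param spec the [window_spec()] the windows were extracted with (needed
#'   to locate offset 0, the frame anchor).
#' @return integer vector of in-frame stop counts.
#' @examples
#' in_frame_stop_count("ATGAAATGA", "TIS", window_spec(0, 8))
#' @export
in_frame_stop_count <- function(windows, site_type = c("TIS", "STOP"), spec) {
  site_type <- match.arg(site_type)
  stopifnot(inherits(spec, "window_spec"))
  enc <- encode_windows(windows)
  L <- ncol(enc)
  offsets <- spec$lo:spec$hi
  starts <- which(offsets %% 3L == 0L)            # candidate frame
  starts <- starts[starts + 2L <= L]              # codon fits in window
  o <- offsets[starts]
  starts <- if (site_type == "TIS") starts[o >= 3L] else starts[o <= -3L]
  if (!length(starts)) return(rep(0L, nrow(enc)))
  counts <- rep(0L, nrow(enc))
  Tc <- 4L; Ac <- 1L; Gc <- 3L
  for (s in starts) {
    c1 <- enc[, s]; c2 <- enc[, s + 1L]; c3 <- enc[, s + 2L]
    is_stop <- c1 == Tc & ((c2 == Ac & (c3 == Ac | c3 == Gc)) |
                             (c2 == Gc & c3 == Ac))
    counts <- counts + as.integer(is_stop)
  }
  counts
}

fit_stop_codon_method <- function(data) {
  structure(list(), class = "stop_codon_scorer")
}

#' @export
raw_score.stop_codon_scorer <- function(scorer, windows) {
  -as.numeric(in_frame_stop_count(windows, scorer$site_type, scorer$window))
}
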