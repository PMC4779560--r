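# Weighted-degree string-kernel SVM. The soft-margin quadratic program is
# solved by kernlab's SMO on the precomputed Gram matrix; the fitted model
# is stored self-contained (support-vector windows, dual coefficients and
# offset) so scoring and serialisation need no external state.

fit_wd_svm <- function(data, C = 10, D = 12L) {
  cand <- data$candidates
  enc <- encode_windows(cand$window_seq)
  D <- as.integer(D)
  if (ncol(enc) < D)
    stopf("window length (%d) must be >= WD kernel degree D (%d)",
          ncol(enc), D)
  y <- cand$label
  K <- wd_kernel_matrix(enc, enc, D)
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                     factor(y, levels = c(-1, 1)),
                     type = "C-svc", C = C, scaled = FALSE)
  svi <- kernlab::SVindex(m)
  cf <- kernlab::coef(m)[[1]]       # alpha_i * y_i (up to global sign)
  b <- kernlab::b(m)
  f <- as.vector(K[, svi, drop = FALSE] %*% cf) - b
  # kernlab's internal class coding can flip the decision sign; orient so
  # that larger decision values mean the positive class
  orient <- if (mean(f[y == 1L]) >= mean(f[y == -1L])) 1 else -1
  structure(list(sv = enc[svi, , drop = FALSE], coef = cf, b = b,
                 orient = orient, C = C, degree = D),
            class = "wd_svm_scorer")
}

#' @export
raw_score.wd_svm_scorer <- function(scorer, windows) {
  enc <- encode_windows(windows)
  K <- wd_kernel_matrix(enc, scorer$sv, scorer$degree)
  scorer$orient * (as.vector(K %*% scorer$coef) - scorer$b)
}
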