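# The five base scorer families.

test_that("PWM log-odds favour the positive bases and peak at the consensus", {
  ws <- toy_window_set(c("ATG", "CCC"), c(1L, -1L))
  pwm <- fit_scorer("PWM", ws)
  lo <- pwm$logodds
  expect_true(lo["A", 1] > 0 && lo["T", 2] > 0 && lo["G", 3] > 0)
  expect_true(lo["C", 1] < 0)

  train <- motif_training_set(n_per_class = 50, L = 12, seed = 2)
  pwm2 <- fit_scorer("PWM", train)
  # consensus of the positive class scores at least as high as any
  # single-mutation neighbour
  cons_chars <- strsplit("ACGTACGTACGT", "")[[1]]
  cons <- paste(cons_chars, collapse = "")
  s_cons <- raw_score(pwm2, cons)
  for (pos in 1:12) {
    for (b in setdiff(c("A", "C", "G", "T"), cons_chars[pos])) {
      mut <- cons_chars
      mut[pos] <- b
      expect_lte(raw_score(pwm2, paste(mut, collapse = "")), s_cons)
    }
  }
})

test_that("kNN scores are signed neighbour fractions under Hamming distance", {
  ws <- toy_window_set(c("AAAA", "AAAT", "TTTT", "TTTA"),
                       c(1L, 1L, -1L, -1L))
  knn1 <- fit_scorer("KNN", ws, list(knn_k = 1L))
  expect_equal(raw_score(knn1, "AAAA"), 1)   # nearest is itself
  expect_equal(raw_score(knn1, "TTTT"), -1)
  knn3 <- fit_scorer("KNN", ws, list(knn_k = 3L))
  # neighbours of AAAA at k=3: AAAA(0), AAAT(1), then TTTA(3): {+,+,-}
  expect_equal(raw_score(knn3, "AAAA"), 1 / 3)
})

test_that("hamming distance counts mismatches and treats N as unmatched", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4)
  expect_equal(hamming_distance("AN", "AN"), 1)
  expect_error(hamming_distance("AA", "AAA"), "length")
})

test_that("decision tree separates learnable data and scores by leaf purity", {
  train <- motif_training_set(n_per_class = 50, L = 12, seed = 5)
  tree <- fit_scorer("DECISION_TREE", train, seed = 1L)
  sc <- raw_score(tree, train$candidates$window_seq)
  dec <- ifelse(sc > 0, 1L, -1L)
  expect_gt(mean(dec == train$candidates$label), 0.9)
  expect_true(all(sc >= -1 & sc <= 1))
  # refitting with the same seed is deterministic
  tree2 <- fit_scorer("DECISION_TREE", train, seed = 1L)
  expect_identical(raw_score(tree2, train$candidates$window_seq), sc)
})

test_that("in-frame stop counting respects frame and coding side", {
  expect_equal(in_frame_stop_count("ATGAAATGA", "TIS", window_spec(0, 8)), 1L)
  expect_equal(in_frame_stop_count("ATGAAAAAA", "TIS", window_spec(0, 8)), 0L)
  # STOP: strictly upstream, in frame
  expect_equal(in_frame_stop_count("TAACCCTAA", "STOP", window_spec(-6, 2)),
               1L)
  # downstream TGA of a STOP candidate is not counted
  expect_equal(in_frame_stop_count("TAATGA", "STOP", window_spec(0, 5)), 0L)
  # off-frame stops are not counted
  expect_equal(in_frame_stop_count("ATGCTAAC", "TIS", window_spec(0, 7)), 0L)
})

test_that("the stop-codon method ranks stop-depleted flanks above decoys", {
  # positives: start codon followed by stop-free codons; negatives random
  set.seed(8)
  pos <- paste0("ATG", vapply(1:20, function(i)
    paste(rep("GCA", 5), collapse = ""), character(1)))
  neg <- paste0("ATG", vapply(1:20, function(i)
    paste(sample(c("TAA", "TGA", "GCA", "TAG"), 5, replace = TRUE),
          collapse = ""), character(1)))
  ws <- toy_window_set(c(pos, neg), rep(c(1L, -1L), each = 20))
  scm <- fit_scorer("STOP_CODON_METHOD", ws)
  expect_gt(auroc(raw_score(scm, c(pos, neg)),
                  rep(c(1, -1), each = 20)), 0.9)
})

test_that("WD-SVM separates toy data and matches an explicit QP solution", {
  train <- motif_training_set(n_per_class = 25, L = 16, seed = 3)
  svm <- fit_scorer("WD_SVM", train, list(svm_C = 10, svm_d = 4L))
  f <- raw_score(svm, train$candidates$window_seq)
  y <- train$candidates$label
  expect_true(all(sign(f) == y))  # linearly separable toy problem

  # oracle: solve the dual soft-margin QP on the explicit Gram matrix with
  # a generic interior-point solver and compare decision values
  K <- wd_kernel_matrix(train$candidates$window_seq,
                        train$candidates$window_seq, 4L)
  n <- length(y); C <- 10
  sol <- kernlab::ipop(c = rep(-1, n), H = (y %o% y) * K + diag(1e-8, n),
                       A = matrix(as.numeric(y), 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0)
  a <- kernlab::primal(sol)
  f_qp <- as.vector(K %*% (a * y))
  margin <- which(a > 1e-4 & a < C - 1e-4)
  b0 <- mean(y[margin] - f_qp[margin])
  expect_gt(cor(f, f_qp + b0), 0.999)
  expect_true(all(sign(f_qp + b0) == y))
})

test_that("WD-SVM with D = 1 ranks like a linear SVM on one-hot encodings", {
  skip_if_not_installed("e1071")
  train <- motif_training_set(n_per_class = 25, L = 10, seed = 4)
  y <- train$candidates$label
  svm <- fit_scorer("WD_SVM", train, list(svm_C = 1, svm_d = 1L))
  f <- raw_score(svm, train$candidates$window_seq)
  # one-hot encoding: <x, y> = number of matching positions = WD(D=1)
  enc <- t(vapply(strsplit(train$candidates$window_seq, ""), function(ch)
    as.numeric(outer(ch, c("A", "C", "G", "T"), "==")), numeric(40)))
  m <- e1071::svm(enc, factor(y, levels = c(-1, 1)), kernel = "linear",
                  cost = 1, scale = FALSE)
  g <- as.numeric(attr(predict(m, enc, decision.values = TRUE),
                       "decision.values"))
  if (cor(g, y) < 0) g <- -g
  expect_gt(cor(f, g, method = "spearman"), 0.99)
})

test_that("fitting requires both classes and windows long enough for D", {
  ws <- toy_window_set(c("AAAA", "AAAT"), c(1L, 1L))
  expect_error(fit_scorer("PWM", ws), "both classes")
  ws2 <- toy_window_set(c("AAAA", "TTTT"), c(1L, -1L))
  expect_error(fit_scorer("WD_SVM", ws2, list(svm_d = 12L)), ">=")
})
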