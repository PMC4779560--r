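# Shared fixtures and independent oracles used across the test files.

# window_set built directly from window strings (no genome needed)
toy_window_set <- function(windows, labels, site_type = "TIS", lo = 0L) {
  L <- nchar(windows[1])
  structure(list(
    candidates = data.frame(seq_id = "toy", position = seq_along(windows),
                            strand = "+",
                            codon = substr(windows, 1L, 3L),
                            label = as.integer(labels), window_seq = windows,
                            stringsAsFactors = FALSE),
    window = window_spec(lo, lo + L - 1L), site_type = site_type,
    records = list(toy = list(id = "toy", species_tag = "TOY"))),
    class = "window_set")
}

rand_windows <- function(n, L, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

# brute-force weighted-degree kernel: compare every substring explicitly
wd_kernel_oracle <- function(x, y, D) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  ys <- strsplit(y, "", fixed = TRUE)[[1]]
  L <- length(xs)
  beta <- 2 * (D - seq_len(D) + 1) / (D * (D + 1))
  total <- 0
  for (d in seq_len(D)) {
    for (i in seq_len(L - d + 1)) {
      xa <- xs[i:(i + d - 1)]
      ya <- ys[i:(i + d - 1)]
      if (all(xa == ya) && !any(xa == "N")) total <- total + beta[d]
    }
  }
  total
}

# O(n^2) pair-counting auROC
auroc_oracle <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == -1]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

# explicit PR-curve construction: walk distinct thresholds in descending
# order and accumulate rectangles delta-recall x precision
auprc_oracle <- function(scores, labels) {
  np <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(sel & labels == 1)
    prec <- tp / sum(sel)
    recall <- tp / np
    area <- area + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  area
}

# exact two-sided signed-rank p by full sign enumeration
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws >= w), mean(ws <= w)))
}

# random score matrix for stepwise-selection property tests
rand_score_matrix <- function(n_scorers, n_instances, seed,
                              prevalence = 0.3) {
  set.seed(seed)
  labels <- ifelse(runif(n_instances) < prevalence, 1L, -1L)
  if (!any(labels == 1L)) labels[1] <- 1L
  if (!any(labels == -1L)) labels[1] <- -1L
  quality <- runif(n_scorers, -0.2, 0.8)
  E <- t(vapply(seq_len(n_scorers), function(i) {
    quality[i] * labels + rnorm(n_instances, sd = 0.6)
  }, numeric(n_instances)))
  structure(list(E = E, labels = labels,
                 tags = paste0("S", seq_len(n_scorers)),
                 kept = seq_len(n_instances)),
            class = "score_matrix")
}

# balanced, learnable toy training set with a planted consensus core
motif_training_set <- function(n_per_class = 40, L = 20, seed = 1,
                               site_type = "TIS") {
  set.seed(seed)
  consensus <- strsplit(paste(rep("ACGT", ceiling(L / 4)), collapse = ""),
                        "")[[1]][seq_len(L)]
  pos <- vapply(seq_len(n_per_class), function(i) {
    s <- consensus
    flip <- runif(L) < 0.1
    s[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  neg <- rand_windows(n_per_class, L, seed + 1)
  toy_window_set(c(pos, neg), rep(c(1L, -1L), each = n_per_class),
                 site_type = site_type)
}
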