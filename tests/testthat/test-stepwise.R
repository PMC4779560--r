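# Score-matrix caching and greedy stepwise selection.

make_pool <- function(ws, kinds = c("PWM", "KNN"), seed = 1L) {
  lapply(kinds, function(k)
    fit_calibrated_scorer(k, ws, list(knn_k = 3L), seed = seed,
                          source_tag = paste0("TOY:", k)))
}

test_that("cached score matrices have pool x instance shape and are stable", {
  ws <- motif_training_set(n_per_class = 20, L = 10, seed = 10)
  pool <- make_pool(ws)
  sm1 <- cache_effective_outputs(pool, ws)
  expect_equal(dim(sm1$E), c(2L, 40L))
  expect_equal(sm1$labels, ws$candidates$label)
  sm2 <- cache_effective_outputs(pool, ws)
  expect_identical(sm1$E, sm2$E)
})

test_that("instances that overflow any scorer's window are dropped for all", {
  # an ATG flush against the 5' end plus interior ATGs
  seq <- paste0("ATG", rand_windows(1, 60, 20), "ATG", rand_windows(1, 60, 23))
  rec <- genome_record("g", seq)
  cand <- enumerate_candidates(rec, "TIS", "+")
  ann <- data.frame(seq_id = "g", position = 0L, strand = "+",
                    site_type = "TIS")
  ds <- build_dataset(list(rec), ann, "TIS", window_spec(0, 2))
  train <- motif_training_set(n_per_class = 10, L = 9, seed = 21)
  narrow <- fit_calibrated_scorer("PWM", train, seed = 1L)        # [0, 8]
  wide_train <- motif_training_set(n_per_class = 10, L = 31, seed = 22)
  wide_train$window <- window_spec(-15, 15)
  wide <- fit_calibrated_scorer("PWM", wide_train, seed = 1L)
  expect_warning(sm <- cache_effective_outputs(list(narrow, wide), ds),
                 "dropped")
  # the boundary candidate is gone and every kept one is in bounds for BOTH
  kept_pos <- ds$candidates$position[sm$kept]
  expect_false(0L %in% kept_pos)
  expect_true(all(kept_pos >= 15 & kept_pos + 15 <= nchar(seq) - 1))
  expect_equal(nrow(sm$E), 2L)
})

test_that("singleton subsets reproduce the scorer's own validation metric", {
  sm <- rand_score_matrix(4, 120, seed = 30)
  for (i in 1:4) {
    dec <- ifelse(sm$E[i, ] > 0, 1L, -1L)
    g <- sqrt(mean(dec[sm$labels == 1] == 1) *
                mean(dec[sm$labels == -1] == -1))
    expect_equal(evaluate_subset(sm, i, "SUM", "G_MEAN"), g)
    expect_equal(evaluate_subset(sm, i, "SUM", "AUROC"),
                 auroc(sm$E[i, ], sm$labels))
  }
  expect_error(evaluate_subset(sm, integer(0)), "empty")
  # a perfect scorer subset reaches G-mean 1
  smp <- sm
  smp$E[1, ] <- sm$labels
  expect_equal(evaluate_subset(smp, 1, "SUM", "G_MEAN"), 1)
})

test_that("constructive selection follows the designed greedy trace", {
  # hand-built matrix: scorer 1 good, scorer 2 complements it, scorer 3 bad
  labels <- rep(c(1L, -1L), each = 4)
  E <- rbind(c(0.9, 0.9, 0.9, -0.1, -0.9, -0.9, -0.9, 0.4),
             c(0.2, -0.3, 0.2, 0.3, -0.2, -0.2, 0.1, -0.6),
             c(-0.5, -0.5, 0.5, -0.5, 0.5, 0.5, -0.5, 0.5))
  sm <- structure(list(E = E, labels = labels, tags = c("A", "B", "C"),
                       kept = 1:8), class = "score_matrix")
  ens <- constructive_selection(sm, "SUM", "G_MEAN")
  expect_equal(ens$selected[1], 1L)           # best single first
  expect_true(2L %in% ens$selected)           # complement added
  expect_false(3L %in% ens$selected)          # harmful scorer excluded
  expect_true(all(diff(ens$trace$value) > 0)) # strictly increasing
  # pool of one is always selected
  sm1 <- structure(list(E = E[3, , drop = FALSE], labels = labels,
                        tags = "C", kept = 1:8), class = "score_matrix")
  expect_equal(constructive_selection(sm1, "SUM", "G_MEAN")$selected, 1L)
})

test_that("destructive selection removes harmful scorers and stops at one", {
  labels <- rep(c(1L, -1L), each = 4)
  E <- rbind(c(0.9, 0.9, 0.9, 0.9, -0.9, -0.9, -0.9, -0.9),
             c(0.8, 0.8, 0.8, 0.8, -0.8, -0.8, -0.8, -0.8),
             c(-2, -2, -2, -2, 2, 2, 2, 2))  # anti-correlated, dominant
  sm <- structure(list(E = E, labels = labels, tags = c("A", "B", "C"),
                       kept = 1:8), class = "score_matrix")
  ens <- destructive_selection(sm, "SUM", "G_MEAN")
  expect_false(3L %in% ens$selected)
  expect_equal(ens$validation_value, 1)
  # all-useful pool: nothing is removed
  sm2 <- structure(list(E = E[1:2, ], labels = labels, tags = c("A", "B"),
                        kept = 1:8), class = "score_matrix")
  ens2 <- destructive_selection(sm2, "SUM", "G_MEAN")
  expect_gte(length(ens2$selected), 1L)
  expect_gte(ens2$validation_value,
             evaluate_subset(sm2, 1:2, "SUM", "G_MEAN"))
})

test_that("greedy results never beat the exhaustive oracle and stay cheap", {
  for (seed in 1:12) {
    n <- sample(2:4, 1)
    sm <- rand_score_matrix(n, 60, seed = 1000 + seed)
    for (rule in c("SUM", "MAJORITY")) {
      oracle <- exhaustive_subset_oracle(sm, rule, "G_MEAN")
      cons <- constructive_selection(sm, rule, "G_MEAN")
      dest <- destructive_selection(sm, rule, "G_MEAN")
      expect_lte(cons$validation_value, oracle$value + 1e-12)
      expect_lte(dest$validation_value, oracle$value + 1e-12)
      expect_lte(cons$n_evaluations, n * (n + 1) / 2)
      expect_lte(dest$n_evaluations, n * (n + 1) / 2)
      # destructive never does worse than keeping the whole pool
      expect_gte(dest$validation_value,
                 evaluate_subset(sm, seq_len(n), rule, "G_MEAN") - 1e-12)
    }
  }
  expect_error(exhaustive_subset_oracle(rand_score_matrix(16, 10, 1)),
               "too large")
})

test_that("best_of_six returns the maximum of the six variants in tie order", {
  sm <- rand_score_matrix(5, 100, seed = 77)
  best <- best_of_six(sm, "G_MEAN")
  cands <- attr(best, "candidates")
  expect_equal(nrow(cands), 6L)
  expect_equal(best$validation_value, max(cands$validation_value))
  first_max <- which.max(cands$validation_value)
  expect_equal(best$method, cands$method[first_max])
  expect_equal(best$rule, cands$rule[first_max])
  expect_equal(cands$method, rep(c("constructive", "destructive"), each = 3))
  expect_equal(cands$rule, rep(c("SUM", "MAJORITY", "MAXIMUM"), 2))
  # predictions re-derive the validation value
  pred <- predict(best, sm)
  expect_equal(objective <- evaluate_subset(sm, best$selected, best$rule,
                                            "G_MEAN"),
               best$validation_value)
  expect_equal(nrow(pred), ncol(sm$E))
})

test_that("selection is invariant to relabelling scorers (up to tie-breaks)", {
  sm <- rand_score_matrix(4, 80, seed = 55)
  perm <- c(3L, 1L, 4L, 2L)
  smp <- sm
  smp$E <- sm$E[perm, ]
  smp$tags <- sm$tags[perm]
  a <- constructive_selection(sm, "SUM", "G_MEAN")
  b <- constructive_selection(smp, "SUM", "G_MEAN")
  expect_equal(sort(perm[b$selected]), sort(a$selected))
  expect_equal(a$validation_value, b$validation_value)
})
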