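# Synthetic multi-species generator.

test_that("motif models are normalised, anchored and deterministic", {
  m <- make_motif_model("TIS", span = c(-6, 8), concentration = 5, seed = 3)
  expect_equal(colSums(m$probs), rep(1, length(m$offsets)))
  anchor_cols <- match(0:2, m$offsets)
  expect_equal(m$probs[, anchor_cols],
               matrix(c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0), nrow = 4,
                      dimnames = list(c("A", "C", "G", "T"), NULL)))  # A,T,G
  m2 <- make_motif_model("TIS", span = c(-6, 8), concentration = 5, seed = 3)
  expect_identical(m, m2)
  expect_error(make_motif_model("TIS", span = c(3, 10)), "codon")
  # concentration -> infinity approaches a hard consensus
  hard <- make_motif_model("TIS", span = c(-4, 4), concentration = 1e9,
                           seed = 1)
  expect_true(all(apply(hard$probs, 2, max) > 0.999))
})

test_that("generated genomes contain exactly the planted, enumerable sites", {
  m <- make_motif_model("TIS", seed = 2)
  cfg <- species_config("SP1", divergence = 0.2, genome_length = 8000,
                        n_true_sites = 12, seed = 5)
  gen <- generate_species_genome(m, cfg)
  expect_equal(nrow(gen$annotations), 12L)
  cand <- enumerate_candidates(gen$record, "TIS", "+")
  expect_true(all(gen$annotations$position %in% cand$position))
  expect_gt(nrow(cand), 12L)  # decoys occur naturally
  # determinism
  gen2 <- generate_species_genome(m, cfg)
  expect_identical(gen$record$sequence, gen2$record$sequence)
  # zero divergence with a hard motif: planted windows share the consensus
  hard <- make_motif_model("TIS", span = c(-5, 7), concentration = 1e9,
                           seed = 9)
  cfg0 <- species_config("SP0", divergence = 0, genome_length = 6000,
                         n_true_sites = 8, seed = 6)
  gen0 <- generate_species_genome(hard, cfg0)
  ds <- build_dataset(list(gen0$record), gen0$annotations, "TIS",
                      window_spec(-5, 2))  # clear of the repaired flank
  wins <- ds$candidates$window_seq[ds$candidates$label == 1L]
  expect_equal(length(unique(wins)), 1L)
})

test_that("stop-type genomes deplete in-frame stops upstream of true sites", {
  m <- make_motif_model("STOP", seed = 4)
  cfg <- species_config("SS", divergence = 0, genome_length = 9000,
                        n_true_sites = 10, coding_flank_length = 60,
                        seed = 7)
  gen <- generate_species_genome(m, cfg)
  ds <- build_dataset(list(gen$record), gen$annotations, "STOP",
                      window_spec(-60, 2))
  counts <- in_frame_stop_count(ds$candidates$window_seq, "STOP",
                                window_spec(-60, 2))
  expect_true(all(counts[ds$candidates$label == 1L] == 0L))
  expect_gt(mean(counts[ds$candidates$label == -1L]), 0.5)
})

test_that("a PWM learns the planted signal and degrades with divergence", {
  aucs <- vapply(c(0, 0.3, 0.7), function(eps) {
    mean(vapply(1:3, function(seed) {
      m <- make_motif_model("TIS", concentration = 5, seed = 11)
      tr <- generate_species_genome(
        m, species_config("TR", eps, 12000, 25, seed = seed))
      te <- generate_species_genome(
        m, species_config("TE", eps, 12000, 25, seed = seed + 50))
      spec <- window_spec(-10, 12)
      dtr <- random_undersample(
        build_dataset(list(tr$record), tr$annotations, "TIS", spec),
        seed = seed)
      dte <- build_dataset(list(te$record), te$annotations, "TIS", spec)
      pwm <- fit_scorer("PWM", dtr)
      auroc(raw_score(pwm, dte$candidates$window_seq),
            dte$candidates$label)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(aucs[1], 0.95)
  expect_true(all(diff(aucs) < 0))  # monotone decay in divergence
})

test_that("study generation writes a complete, reproducible file tree", {
  cfg <- default_study_config(seed = 21, genome_length = 6000,
                              n_true_sites = 8)
  d1 <- withr::local_tempdir()
  manifest <- generate_study(cfg, d1)
  files <- list.files(d1)
  expect_equal(sum(grepl("\\.fasta$", files)), 8L)     # 5 sources + 3 splits
  expect_equal(sum(grepl("\\.sites\\.tsv$", files)), 8L)
  expect_true("manifest.json" %in% files)
  roles <- vapply(manifest$files, `[[`, character(1), "role")
  expect_equal(sum(roles == "source"), 5L)
  expect_setequal(c("train", "validation", "test"),
                  roles[roles != "source"])
  # byte-identical re-run
  d2 <- withr::local_tempdir()
  generate_study(cfg, d2)
  for (f in setdiff(files, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # duplicate tags are rejected
  expect_error(study_config(list(species_config("A"), species_config("A"))),
               "duplicate")
})

test_that("candidate imbalance grows with genome length at fixed site count", {
  m <- make_motif_model("TIS", seed = 13)
  ratio <- vapply(c(4000, 8000, 16000), function(len) {
    g <- generate_species_genome(
      m, species_config("X", 0.1, len, 10, seed = 3))
    ds <- build_dataset(list(g$record), g$annotations, "TIS",
                        window_spec(-5, 7))
    sum(ds$candidates$label == -1L) / sum(ds$candidates$label == 1L)
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})
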