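# Genome/annotation IO, candidate enumeration, window extraction and
# dataset assembly.

test_that("FASTA round trip normalises case and preserves multi-record files", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chrA test", "acgtACGT", "AACC", ">chrB", "TTTTGGG"), fa)
  recs <- read_genome_fasta(fa)
  expect_length(recs, 2L)
  expect_equal(recs$chrA$sequence, "ACGTACGTAACC")
  expect_equal(recs$chrB$sequence, "TTTTGGG")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(recs, out)
  expect_equal(read_genome_fasta(out)$chrA$sequence, "ACGTACGTAACC")
})

test_that("FASTA reading rejects missing, empty and corrupt input", {
  expect_error(read_genome_fasta(tempfile()), "not found")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_error(read_genome_fasta(fa), "no records")
  writeLines(c(">x", "ACGU"), fa)
  expect_error(read_genome_fasta(fa), "U")
})

test_that("site annotation files parse and validate field by field", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#seq_id\tposition\tstrand\tsite_type",
               "chrS\t10\t+\tTIS"), f)
  sites <- read_site_annotations(f)
  expect_equal(sites$seq_id, "chrS")
  expect_equal(sites$position, 10L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$site_type, "TIS")

  writeLines("chrS\t-4\t+\tTIS", f)
  expect_error(read_site_annotations(f), "non-negative")
  writeLines("chrS\t4\t+\tDONOR", f)
  expect_error(read_site_annotations(f), "TIS, STOP")
  writeLines("chrS\t4\t+", f)
  expect_error(read_site_annotations(f), "line 1")
})

test_that("candidate enumeration finds every site codon in order", {
  r <- genome_record("s", "ATGAAATGA")
  tis <- enumerate_candidates(r, "TIS", "+")
  expect_equal(tis$position, c(0L, 5L))
  expect_true(all(tis$codon == "ATG"))
  stp <- enumerate_candidates(r, "STOP", "+")
  expect_equal(stp$position, c(1L, 6L))
  expect_true(all(stp$codon == "TGA"))
  none <- enumerate_candidates(genome_record("c", "CCCCCCCC"), "TIS", "both")
  expect_equal(nrow(none), 0L)
})

test_that("enumeration commutes with reverse complement (strand swap)", {
  for (seed in 1:5) {
    seq <- paste(rand_windows(1, 60, seed), collapse = "")
    r <- genome_record("f", seq)
    rc <- genome_record("r", revcomp(seq))
    for (type in c("TIS", "STOP")) {
      fwd <- enumerate_candidates(r, type, "both")
      bwd <- enumerate_candidates(rc, type, "both")
      # map forward candidates into the coordinates of the reverse strand
      n <- nchar(seq)
      mapped <- data.frame(position = n - 3L - fwd$position,
                           strand = ifelse(fwd$strand == "+", "-", "+"),
                           codon = fwd$codon)
      mapped <- mapped[order(mapped$position, mapped$strand), ]
      expect_equal(bwd$position, mapped$position)
      expect_equal(bwd$strand, mapped$strand)
      expect_equal(bwd$codon, mapped$codon)
    }
  }
})

test_that("window extraction honours offsets, strand and boundaries", {
  r <- genome_record("s", "AAATGCC")
  expect_equal(extract_window(r, 2, "+", window_spec(-2, 2)), "AAATG")
  expect_true(is.na(extract_window(genome_record("s", "ATG"), 0, "+",
                                   window_spec(-1, 1))))
  expect_error(window_spec(3, 1), "lo")
  # offset-0 window is always the candidate codon, on either strand
  seq <- paste(rand_windows(1, 50, 99), collapse = "")
  rec <- genome_record("s", seq)
  for (type in c("TIS", "STOP")) {
    cand <- enumerate_candidates(rec, type, "both")
    for (i in seq_len(nrow(cand))) {
      expect_equal(extract_window(rec, cand$position[i], cand$strand[i],
                                  window_spec(0, 2)),
                   cand$codon[i])
    }
  }
  # minus-strand windows read 5' upstream on the reverse complement
  rec2 <- genome_record("s", "TTCATGG")  # revcomp CCATGAA: ATG at fwd pos 2, strand -
  cand2 <- enumerate_candidates(rec2, "TIS", "-")
  expect_equal(cand2$position, 2L)
  expect_equal(extract_window(rec2, 2L, "-", window_spec(-2, 3)),
               substr(revcomp("TTCATGG"), 1, 6))
})

test_that("dataset assembly labels annotated candidates and drops overflow", {
  # two annotated ATGs and three decoys
  seq <- "CCATGCCCATGCCCATGCCCATGCCCATGCC"
  rec <- genome_record("g", seq)
  cand <- enumerate_candidates(rec, "TIS", "+")
  expect_equal(nrow(cand), 5L)
  ann <- data.frame(seq_id = "g", position = cand$position[c(1, 3)],
                    strand = "+", site_type = "TIS")
  ds <- build_dataset(list(rec), ann, "TIS", window_spec(-2, 4))
  expect_equal(sum(ds$candidates$label == 1L), 2L)
  expect_equal(sum(ds$candidates$label == -1L), 3L)
  expect_true(all(nchar(ds$candidates$window_seq) == 7L))

  bad <- data.frame(seq_id = "g", position = 0L, strand = "+",
                    site_type = "TIS")  # codon CC... not ATG
  expect_error(build_dataset(list(rec), bad, "TIS", window_spec(0, 2)),
               "legal site codon")

  expect_warning(
    empty <- build_dataset(list(genome_record("t", "ATGAA")),
                           data.frame(seq_id = character(),
                                      position = integer(),
                                      strand = character(),
                                      site_type = character()),
                           "TIS", window_spec(-50, 50)),
    "dropped")
  expect_equal(nrow(empty$candidates), 0L)
})

test_that("shared positives are removed from training, negatives kept", {
  train <- toy_window_set(c("ATGAA", "ATGCC", "CCCCC", "GGGGG"),
                          c(1L, 1L, -1L, -1L))
  test <- toy_window_set(c("ATGAA", "TTTTT"), c(1L, -1L))
  filt <- remove_shared_sites(train, test)
  expect_equal(filt$candidates$window_seq, c("ATGCC", "CCCCC", "GGGGG"))
  # no overlap: identity
  test2 <- toy_window_set(c("AAAAA"), c(1L))
  expect_equal(remove_shared_sites(train, test2)$candidates,
               train$candidates)
  # all shared: warning and empty positive set
  test3 <- toy_window_set(c("ATGAA", "ATGCC"), c(1L, 1L))
  expect_warning(all_gone <- remove_shared_sites(train, test3), "shared")
  expect_equal(sum(all_gone$candidates$label == 1L), 0L)
})

test_that("random undersampling balances classes deterministically", {
  set.seed(42)
  ws <- toy_window_set(rand_windows(110, 8, 7),
                       c(rep(1L, 10), rep(-1L, 100)))
  bal <- random_undersample(ws, seed = 3L)
  expect_equal(sum(bal$candidates$label == 1L), 10L)
  expect_equal(sum(bal$candidates$label == -1L), 10L)
  expect_identical(random_undersample(ws, seed = 3L)$candidates,
                   bal$candidates)
  # already balanced input is unchanged
  ws2 <- toy_window_set(rand_windows(10, 8, 8), rep(c(1L, -1L), 5))
  expect_identical(random_undersample(ws2, seed = 1L)$candidates,
                   ws2$candidates)
  # fewer negatives than positives: keep all, warn
  ws3 <- toy_window_set(rand_windows(5, 8, 9), c(1L, 1L, 1L, -1L, -1L))
  expect_warning(out <- random_undersample(ws3, seed = 1L), "fewer negatives")
  expect_equal(nrow(out$candidates), 5L)
  # union over disjoint seeds stays within the input
  u <- unique(c(random_undersample(ws, 1L)$candidates$window_seq,
                random_undersample(ws, 2L)$candidates$window_seq))
  expect_true(all(u %in% ws$candidates$window_seq))
})
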