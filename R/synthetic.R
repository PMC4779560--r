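# Synthetic multi-species genomes with planted functional sites: a fully
# controlled stand-in for real multi-genome studies, with a shared mutable
# consensus motif, coding-like (in-frame stop-depleted) flanks and a large
# natural excess of decoy candidate codons.

#' Random positional motif model for planted sites
#'
#' Draws a per-offset base-probability table over a span of offsets around
#' the candidate codon. Each offset gets a random preferred base whose
#' probability grows with `concentration`; the anchor codon (ATG for TIS,
#' a stop codon for STOP) is forced with probability 1 at offsets 0..2.
#'
#' @param site_type `"TIS"` or `"STOP"`.
#' @param span integer vector `c(lo, hi)` of covered offsets; must include
#'   offsets 0..2.
#' @param concentration non-negative peakedness: base probabilities are
#'   `(1 + concentration * [b == preferred]) / (4 + concentration)`, so 0
#'   is uniform background and large values approach a hard consensus.
#' @param seed integer seed.
#' @param anchor_codon the codon forced at offsets 0..2 (defaults to ATG
#'   for TIS, TAA for STOP).
#' @return an object of class `motif_model` with the 4 x span probability
#'   matrix (`probs`), the offsets and the anchor codon.
#' @export
make_motif_model <- function(site_type = c("TIS", "STOP"), span = c(-10, 12),
                             concentration = 5, seed = 1L,
                             anchor_codon = NULL) {
  site_type <- match.arg(site_type)
  if (span[1] > 0L || span[2] < 2L)
    stop("motif span must cover the candidate codon offsets 0..2")
  anchor_codon <- anchor_codon %||% if (site_type == "TIS") "ATG" else "TAA"
  if (!anchor_codon %in% site_codons(site_type))
    stopf("anchor codon %s is not a legal %s codon", anchor_codon, site_type)
  offsets <- span[1]:span[2]
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  probs <- vapply(offsets, function(o) {
    peak <- sample.int(4L, 1L)
    (1 + concentration * (seq_len(4L) == peak)) / (4 + concentration)
  }, numeric(4))
  anchor <- strsplit(anchor_codon, "", fixed = TRUE)[[1]]
  for (i in 0:2) {
    col <- which(offsets == i)
    probs[, col] <- as.numeric(DNA_BASES == anchor[i + 1L])
  }
  rownames(probs) <- DNA_BASES
  structure(list(site_type = site_type, offsets = offsets, probs = probs,
                 anchor_codon = anchor_codon, concentration = concentration),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s, offsets [%d, %d], anchor %s\n",
              x$site_type, min(x$offsets), max(x$offsets), x$anchor_codon))
  invisible(x)
}

#' Configuration for one synthetic species genome
#'
#' @param species_tag short unique label.
#' @param divergence per-offset probability in \[0, 1\] that a planted
#'   site replaces the motif column with a uniform background draw
#'   (the anchor codon is never diverged, so planted sites always remain
#'   enumerable candidates). 0 reproduces the shared motif exactly.
#' @param genome_length background sequence length in bases.
#' @param n_true_sites number of planted sites.
#' @param coding_flank_length length (bases) of the stop-depleted in-frame
#'   flank on the coding side of each planted site.
#' @param gc_content background GC fraction.
#' @param seed integer seed.
#' @return a list of class `species_config`.
#' @export
species_config <- function(species_tag, divergence = 0, genome_length = 50000L,
                           n_true_sites = 50L, coding_flank_length = 60L,
                           gc_content = 0.42, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1, genome_length > 0,
            n_true_sites >= 0, coding_flank_length %% 3 == 0)
  structure(list(species_tag = species_tag, divergence = divergence,
                 genome_length = as.integer(genome_length),
                 n_true_sites = as.integer(n_true_sites),
                 coding_flank_length = as.integer(coding_flank_length),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "species_config")
}

sample_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

non_stop_codons <- function() {
  all3 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES,
                          paste0))
  setdiff(all3, STOP_CODONS)
}

#' Generate one synthetic species genome with planted sites
#'
#' Draws an i.i.d. background sequence with the configured GC content and
#' plants `n_true_sites` non-overlapping sites sampled from the
#' epsilon-diverged motif. On the coding side of each planted site (the
#' downstream flank for TIS, the upstream flank for STOP) all in-frame stop
#' codons are resampled to non-stop codons, emulating the stop depletion of
#' real coding sequence that the stop-codon method exploits. Decoy candidate
#' codons arise naturally in the background.
#'
#' @param motif a [make_motif_model()] object.
#' @param cfg a [species_config()].
#' @return list with `record` (a [genome_record()]) and `annotations`
#'   (data frame of planted sites, forward strand).
#' @export
generate_species_genome <- function(motif, cfg) {
  stopifnot(inherits(motif, "motif_model"), inherits(cfg, "species_config"))
  offsets <- motif$offsets
  span_lo <- min(offsets); span_hi <- max(offsets)
  flank <- cfg$coding_flank_length
  left_margin <- -span_lo + (if (motif$site_type == "STOP") flank else 0L)
  right_margin <- span_hi + (if (motif$site_type == "TIS") flank else 0L)
  footprint <- left_margin + right_margin + 1L
  if (cfg$n_true_sites * (footprint + 2L) >= cfg$genome_length)
    stop("genome too short for the requested number of planted sites")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  seq_chars <- sample_bases(cfg$genome_length, cfg$gc_content)
  # non-overlapping anchor placements (0-based anchor positions)
  positions <- integer(0)
  tries <- 0L
  lo_ok <- left_margin
  hi_ok <- cfg$genome_length - 1L - right_margin - 2L
  while (length(positions) < cfg$n_true_sites) {
    tries <- tries + 1L
    if (tries > 1000L * max(1L, cfg$n_true_sites))
      stop("could not place planted sites without overlap; ",
           "reduce n_true_sites or enlarge the genome")
    p <- sample(lo_ok:hi_ok, 1L)
    if (!any(abs(positions - p) <= footprint)) positions <- c(positions, p)
  }
  positions <- sort(positions)
  for (p in positions) {
    # motif columns, with per-offset divergence towards uniform background
    for (j in seq_along(offsets)) {
      o <- offsets[j]
      anchor <- o >= 0L && o <= 2L
      base <- if (!anchor && runif(1) < cfg$divergence)
        sample(DNA_BASES, 1L)
      else sample(DNA_BASES, 1L, prob = motif$probs[, j])
      seq_chars[p + o + 1L] <- base
    }
    # stop-depleted in-frame coding flank (plus in-frame repair across the
    # motif span on the coding side)
    if (motif$site_type == "TIS") {
      frame_starts <- seq(3L, span_hi + flank, by = 3L)
    } else {
      frame_starts <- seq(-3L, span_lo - flank, by = -3L)
    }
    for (o in frame_starts) {
      i <- p + o + 1L
      cod <- paste0(seq_chars[i], seq_chars[i + 1L], seq_chars[i + 2L])
      if (cod %in% STOP_CODONS) {
        repl <- strsplit(sample(non_stop_codons(), 1L), "", fixed = TRUE)[[1]]
        seq_chars[i:(i + 2L)] <- repl
      }
    }
  }
  record <- genome_record(cfg$species_tag, paste(seq_chars, collapse = ""),
                          species_tag = cfg$species_tag)
  annotations <- data.frame(seq_id = cfg$species_tag, position = positions,
                            strand = "+", site_type = motif$site_type,
                            stringsAsFactors = FALSE)
  list(record = record, annotations = annotations)
}

#' Configuration of a full synthetic study
#'
#' Defines the source species whose genomes supply training evidence and a
#' target species split into disjoint train/validation/test sequences.
#'
#' @param sources list of [species_config()]s (tags must be unique).
#' @param target_tag tag of the target species.
#' @param target_divergence motif divergence of the target (default 0: the
#'   target carries the undiverged motif).
#' @param site_type `"TIS"` or `"STOP"`.
#' @param genome_length,n_true_sites,coding_flank_length,gc_content sizes
#'   for each target split, as in [species_config()].
#' @param seed master seed; all per-genome seeds derive from it.
#' @return a list of class `study_config`.
#' @export
study_config <- function(sources, target_tag = "TGT", target_divergence = 0,
                         site_type = c("TIS", "STOP"),
                         genome_length = 50000L, n_true_sites = 50L,
                         coding_flank_length = 60L, gc_content = 0.42,
                         seed = 1L) {
  site_type <- match.arg(site_type)
  tags <- vapply(sources, `[[`, character(1), "species_tag")
  if (anyDuplicated(tags))
    stopf("duplicate species_tag: %s", tags[duplicated(tags)][1])
  if (target_tag %in% tags)
    stopf("target tag '%s' collides with a source tag", target_tag)
  structure(list(sources = sources, target_tag = target_tag,
                 target_divergence = target_divergence,
                 site_type = site_type,
                 genome_length = as.integer(genome_length),
                 n_true_sites = as.integer(n_true_sites),
                 coding_flank_length = as.integer(coding_flank_length),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "study_config")
}

#' The default five-source benchmark study
#'
#' One low-divergence source, a duplicate of it (same divergence, an
#' independent genome), and three high-divergence sources, each a 50 kb
#' genome with 50 planted sites; the target carries the undiverged motif.
#' This emulates the situation where a few source genomes carry a signal
#' close to the target's and most are distant relatives, and where one
#' source is informationally redundant.
#'
#' @param seed master seed.
#' @param site_type `"TIS"` or `"STOP"`.
#' @param genome_length,n_true_sites per-genome sizes.
#' @return a `study_config`.
#' @export
default_study_config <- function(seed = 1L, site_type = "TIS",
                                 genome_length = 50000L, n_true_sites = 50L) {
  mk <- function(tag, eps, i)
    species_config(tag, divergence = eps, genome_length = genome_length,
                   n_true_sites = n_true_sites,
                   seed = derive_seed(seed, 100L + i))
  # high-divergence sources first, so that index-order tie-breaks never
  # favour the informative sources by accident
  sources <- list(mk("HIA", 0.7, 1L), mk("HIB", 0.7, 2L), mk("HIC", 0.7, 3L),
                  mk("LOW", 0.1, 4L), mk("DUP", 0.1, 5L))
  study_config(sources, target_tag = "TGT", target_divergence = 0,
               site_type = site_type, genome_length = genome_length,
               n_true_sites = n_true_sites, seed = seed)
}

#' Generate a synthetic study on disk
#'
#' Writes one FASTA and one site-annotation file per source genome, plus
#' three target files (train/validation/test splits, disjoint sequences),
#' and a JSON manifest listing every file and its role. Byte-identical
#' across runs with the same configuration.
#'
#' @param cfg a [study_config()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
generate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  motif <- make_motif_model(cfg$site_type, seed = derive_seed(cfg$seed, 1L))
  entries <- list()
  emit <- function(tag, role, gen) {
    fa <- file.path(dir, paste0(tag, ".fasta"))
    st <- file.path(dir, paste0(tag, ".sites.tsv"))
    write_genome_fasta(list(gen$record), fa)
    write_site_annotations(gen$annotations, st)
    list(tag = tag, role = role, fasta = basename(fa), sites = basename(st),
         n_sites = nrow(gen$annotations))
  }
  for (i in seq_along(cfg$sources)) {
    sc <- cfg$sources[[i]]
    gen <- generate_species_genome(motif, sc)
    entries[[length(entries) + 1L]] <- c(emit(sc$species_tag, "source", gen),
                                         divergence = sc$divergence)
  }
  for (split in c("train", "validation", "test")) {
    tag <- paste0(cfg$target_tag, "_", split)
    sc <- species_config(tag, divergence = cfg$target_divergence,
                         genome_length = cfg$genome_length,
                         n_true_sites = cfg$n_true_sites,
                         coding_flank_length = cfg$coding_flank_length,
                         gc_content = cfg$gc_content,
                         seed = derive_seed(cfg$seed, 200L + match(
                           split, c("train", "validation", "test"))))
    gen <- generate_species_genome(motif, sc)
    entries[[length(entries) + 1L]] <- c(emit(tag, split, gen),
                                         divergence = cfg$target_divergence)
  }
  manifest <- list(site_type = cfg$site_type, seed = cfg$seed,
                   files = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
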