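# Candidate-site enumeration, window extraction and dataset assembly.

#' Window specification around a candidate codon
#'
#' Offsets are relative to the first base of the candidate codon (offset 0),
#' inclusive at both ends, so the window length is `hi - lo + 1`. Negative
#' offsets are upstream (5') on the candidate's strand. The bounds need not
#' bracket zero: `[0, 25]` and `[-100, 0]` are both valid.
#'
#' @param lo,hi integer offsets, `lo <= hi`.
#' @return an object of class `window_spec`.
#' @examples
#' window_spec(-10, 15)
#' @export
window_spec <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (is.na(lo) || is.na(hi)) stop("window bounds must be integers")
  if (lo > hi) stopf("invalid window: lo (%d) > hi (%d)", lo, hi)
  structure(list(lo = lo, hi = hi), class = "window_spec")
}

#' @export
format.window_spec <- function(x, ...) sprintf("[%d,%d]", x$lo, x$hi)

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s (length %d)\n", format(x), window_length(x)))
  invisible(x)
}

#' @rdname window_spec
#' @param spec a `window_spec`.
#' @export
window_length <- function(spec) spec$hi - spec$lo + 1L

#' The canonical 13-window grid plus stop-codon-method extensions
#'
#' Returns the default grid of candidate windows explored when selecting a
#' scorer's window by cross-validation. The stop-codon method additionally
#' explores long one-sided windows (downstream for TIS, upstream for stop
#' codons), where the in-frame stop-depletion signal lives.
#'
#' @param site_type `"TIS"` or `"STOP"`; only used for `extra_stop_windows`.
#' @return for `default_window_grid`, a list of [window_spec()]s.
#' @export
default_window_grid <- function() {
  bounds <- list(c(-100, 0), c(-75, 25), c(-50, 0), c(-50, 50), c(-25, 0),
                 c(-25, 25), c(-25, 75), c(-10, 15), c(-10, 40), c(-10, 90),
                 c(0, 25), c(0, 50), c(0, 100))
  lapply(bounds, function(b) window_spec(b[1], b[2]))
}

#' @rdname default_window_grid
#' @export
extra_stop_windows <- function(site_type = c("TIS", "STOP")) {
  site_type <- match.arg(site_type)
  spans <- c(200L, 300L, 400L, 500L)
  if (site_type == "TIS") lapply(spans, function(s) window_spec(0L, s))
  else lapply(spans, function(s) window_spec(-s, 0L))
}

#' Codons defining each site type
#'
#' @param site_type `"TIS"` or `"STOP"`.
#' @return character vector of codons (`"ATG"`, or the three stop codons).
#' @export
site_codons <- function(site_type = c("TIS", "STOP")) {
  site_type <- match.arg(site_type)
  if (site_type == "TIS") "ATG" else STOP_CODONS
}

#' Enumerate candidate site codons in a genome record
#'
#' Finds every occurrence of ATG (TIS) or TAA/TAG/TGA (STOP) on the
#' requested strands, in any reading frame. Minus-strand candidates are
#' reported on forward coordinates: position `p` with strand `-` means the
#' reverse complement of the forward triplet starting at `p` is a site
#' codon (its first base, in reading order, sits at forward coordinate
#' `p + 2`). Results are sorted by `(position, strand)`.
#'
#' @param record a [genome_record()].
#' @param site_type `"TIS"` or `"STOP"`.
#' @param strands `"+"`, `"-"` or `"both"`.
#' @return data frame with columns `position` (0-based), `strand`, `codon`.
#' @examples
#' r <- genome_record("s", "ATGAAATGA")
#' enumerate_candidates(r, "TIS", "+")
#' @export
enumerate_candidates <- function(record, site_type = c("TIS", "STOP"),
                                 strands = c("+", "-", "both")) {
  site_type <- match.arg(site_type)
  strands <- match.arg(strands)
  codons <- site_codons(site_type)
  n <- nchar(record$sequence)
  res <- list()
  if (n >= 3L) {
    starts <- seq_len(n - 2L)  # 1-based
    trip <- substring(record$sequence, starts, starts + 2L)
    if (strands %in% c("+", "both")) {
      hit <- trip %in% codons
      if (any(hit))
        res[["+"]] <- data.frame(position = starts[hit] - 1L, strand = "+",
                                 codon = trip[hit], stringsAsFactors = FALSE)
    }
    if (strands %in% c("-", "both")) {
      rc <- revcomp(codons)
      hit <- trip %in% rc
      if (any(hit))
        res[["-"]] <- data.frame(position = starts[hit] - 1L, strand = "-",
                                 codon = revcomp(trip[hit]),
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(position = integer(), strand = character(),
                      codon = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the window around a candidate codon
#'
#' Returns the bases at offsets `lo..hi` relative to the first base of the
#' candidate codon (offset 0), read on the candidate's strand. For
#' minus-strand candidates the window is read on the reverse complement, so
#' negative offsets are always biologically upstream (5'). Returns `NA` if
#' any offset falls outside the sequence.
#'
#' @param record a [genome_record()].
#' @param position 0-based position of the candidate codon (forward
#'   coordinates, see [enumerate_candidates()]).
#' @param strand `"+"` or `"-"`.
#' @param spec a [window_spec()].
#' @return the window string, or `NA_character_` on boundary overflow.
#' @examples
#' r <- genome_record("s", "AAATGCC")
#' extract_window(r, 2, "+", window_spec(-2, 2))
#' @export
extract_window <- function(record, position, strand, spec) {
  stopifnot(inherits(spec, "window_spec"))
  n <- nchar(record$sequence)
  if (strand == "+") {
    from <- position + spec$lo      # 0-based
    to <- position + spec$hi
    if (from < 0L || to > n - 1L) return(NA_character_)
    substr(record$sequence, from + 1L, to + 1L)
  } else if (strand == "-") {
    # first codon base in reading order sits at forward coordinate position+2;
    # offset o maps to forward coordinate (position + 2 - o)
    from <- position + 2L - spec$hi
    to <- position + 2L - spec$lo
    if (from < 0L || to > n - 1L) return(NA_character_)
    revcomp(substr(record$sequence, from + 1L, to + 1L))
  } else stop("strand must be '+' or '-'")
}

# Vectorised window extraction for one record; returns NA where out of bounds.
extract_windows <- function(record, positions, strands, spec) {
  n <- nchar(record$sequence)
  out <- rep(NA_character_, length(positions))
  plus <- strands == "+"
  if (any(plus)) {
    from <- positions[plus] + spec$lo
    to <- positions[plus] + spec$hi
    ok <- from >= 0L & to <= n - 1L
    if (any(ok))
      out[plus][ok] <- substring(record$sequence, from[ok] + 1L, to[ok] + 1L)
  }
  if (any(!plus)) {
    from <- positions[!plus] + 2L - spec$hi
    to <- positions[!plus] + 2L - spec$lo
    ok <- from >= 0L & to <= n - 1L
    if (any(ok))
      out[!plus][ok] <- revcomp(substring(record$sequence, from[ok] + 1L,
                                          to[ok] + 1L))
  }
  out
}

#' Assemble a labelled candidate-window dataset
#'
#' Enumerates every candidate codon of the requested type in the given
#' records, extracts the window of each candidate, labels a candidate `+1`
#' iff `(seq_id, position, strand)` appears in the annotations and `-1`
#' otherwise, and drops candidates whose window overflows the sequence
#' boundary. Annotated sites whose codon is not a legal site codon raise an
#' error.
#'
#' @param records list of [genome_record()]s (named by id or carrying ids).
#' @param annotations data frame as from [read_site_annotations()].
#' @param site_type `"TIS"` or `"STOP"`.
#' @param spec a [window_spec()].
#' @param strands strand policy passed to [enumerate_candidates()].
#' @return an object of class `window_set`: a list with elements
#'   `candidates` (data frame `seq_id`, `position`, `strand`, `codon`,
#'   `label`, `window_seq`), `window`, `site_type` and `records`.
#' @export
build_dataset <- function(records, annotations, site_type = c("TIS", "STOP"),
                          spec = window_spec(-10, 15),
                          strands = c("+", "-", "both")) {
  site_type <- match.arg(site_type)
  strands <- match.arg(strands)
  if (inherits(records, "genome_record")) records <- list(records)
  ids <- vapply(records, `[[`, character(1), "id")
  names(records) <- ids
  ann <- annotations[annotations$site_type == site_type, , drop = FALSE]
  unknown <- setdiff(ann$seq_id, ids)
  if (length(unknown))
    stopf("annotations refer to unknown sequence id(s): %s",
          paste(unique(unknown), collapse = ", "))
  parts <- list()
  n_dropped <- 0L
  for (id in ids) {
    rec <- records[[id]]
    cand <- enumerate_candidates(rec, site_type, strands)
    if (!nrow(cand)) next
    key <- paste(cand$position, cand$strand)
    a <- ann[ann$seq_id == id, , drop = FALSE]
    akey <- paste(a$position, a$strand)
    miss <- !(akey %in% key)
    if (any(miss))
      stopf("annotated %s site at %s:%d(%s) does not sit on a legal site codon",
            site_type, id, a$position[miss][1], a$strand[miss][1])
    lab <- ifelse(key %in% akey, 1L, -1L)
    win <- extract_windows(rec, cand$position, cand$strand, spec)
    keep <- !is.na(win)
    n_dropped <- n_dropped + sum(!keep)
    if (any(keep))
      parts[[id]] <- data.frame(seq_id = id, position = cand$position[keep],
                                strand = cand$strand[keep],
                                codon = cand$codon[keep],
                                label = lab[keep], window_seq = win[keep],
                                stringsAsFactors = FALSE)
  }
  cands <- if (length(parts)) do.call(rbind, parts) else
    data.frame(seq_id = character(), position = integer(),
               strand = character(), codon = character(), label = integer(),
               window_seq = character(), stringsAsFactors = FALSE)
  rownames(cands) <- NULL
  if (!nrow(cands))
    warnf("no candidates with in-bounds windows (%d dropped at boundaries)",
          n_dropped)
  structure(list(candidates = cands, window = spec, site_type = site_type,
                 records = records, n_boundary_dropped = n_dropped),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  n <- nrow(x$candidates)
  np <- sum(x$candidates$label == 1L)
  cat(sprintf("<window_set> %s, window %s: %d candidates (%d +, %d -)\n",
              x$site_type, format(x$window), n, np, n - np))
  invisible(x)
}

#' Remove training positives shared with a test set
#'
#' Drops training positives whose window sequence exactly matches the window
#' of any test positive, so that test sites duplicated in other source
#' genomes (e.g. shared genes) cannot leak into training. Negatives are
#' untouched.
#'
#' @param train,test `window_set` objects of the same site type.
#' @return the filtered training `window_set`.
#' @export
remove_shared_sites <- function(train, test) {
  stopifnot(inherits(train, "window_set"), inherits(test, "window_set"))
  if (train$site_type != test$site_type)
    stop("train and test sets have different site types")
  test_pos <- test$candidates$window_seq[test$candidates$label == 1L]
  shared <- train$candidates$label == 1L &
    train$candidates$window_seq %in% test_pos
  out <- train
  out$candidates <- train$candidates[!shared, , drop = FALSE]
  rownames(out$candidates) <- NULL
  if (!any(out$candidates$label == 1L) && any(train$candidates$label == 1L))
    warnf("all %d training positives were shared with the test set",
          sum(train$candidates$label == 1L))
  out
}

#' Randomly undersample negatives to balance a training set
#'
#' Keeps all positives and draws, uniformly without replacement, as many
#' negatives as there are positives. Only ever applied to training data;
#' validation and test sets are used unmodified.
#'
#' @param data a `window_set` with at least one positive.
#' @param seed integer seed making the draw deterministic.
#' @return the balanced `window_set`.
#' @export
random_undersample <- function(data, seed = 1L) {
  stopifnot(inherits(data, "window_set"))
  lab <- data$candidates$label
  npos <- sum(lab == 1L)
  if (npos == 0L) stop("cannot undersample a set with no positives")
  neg_idx <- which(lab == -1L)
  if (length(neg_idx) < npos) {
    warnf("fewer negatives (%d) than positives (%d): keeping all negatives",
          length(neg_idx), npos)
    return(data)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  keep_neg <- sort(sample(neg_idx, npos))
  keep <- sort(c(which(lab == 1L), keep_neg))
  out <- data
  out$candidates <- data$candidates[keep, , drop = FALSE]
  rownames(out$candidates) <- NULL
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", value, envir = globalenv())
  invisible(value)
}
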