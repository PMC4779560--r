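# Genome and site-annotation input/output.

#' Construct a genome record
#'
#' A genome record bundles a sequence identifier, an uppercase DNA sequence
#' over the alphabet A/C/G/T/N and a short species tag (for example `"HS"`
#' or `"MaM"`) used to label the scorers trained from it.
#'
#' @param id non-empty sequence identifier.
#' @param sequence DNA string; lowercase is accepted and uppercased.
#' @param species_tag short text label for the source species/dataset.
#' @return an object of class `genome_record`.
#' @examples
#' genome_record("chr1", "acgtACGT", species_tag = "HS")
#' @export
genome_record <- function(id, sequence, species_tag = id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty string")
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad))
    stopf("sequence '%s' contains invalid character(s): %s",
          id, paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, species_tag = species_tag),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s [%s], %d bp\n",
              x$id, x$species_tag, nchar(x$sequence)))
  invisible(x)
}

#' Read genome sequences from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file into a list of
#' [genome_record()] objects. Sequences are uppercased; any character outside
#' A/C/G/T/N triggers an error naming the offender.
#'
#' @param path path to a FASTA file.
#' @param species_tag species tag applied to every record; defaults to the
#'   first whitespace-separated token of each header.
#' @return named list of `genome_record` objects.
#' @export
read_genome_fasta <- function(path, species_tag = NULL) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("no records in FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  records <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]),
                  species_tag = species_tag %||% ids[i])
  })
  names(records) <- ids
  records
}

#' Write genome records to a FASTA file
#'
#' @param records list of [genome_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read site annotations
#'
#' Parses a tab-separated annotation file with columns
#' `seq_id`, `position` (0-based offset of the first base of the site codon),
#' `strand` (`+`/`-`) and `site_type` (`TIS`/`STOP`). A `#`-prefixed header
#' line is allowed.
#'
#' @param path path to the annotation file.
#' @return data frame with columns `seq_id`, `position`, `strand`,
#'   `site_type`.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) stopf("site file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      stopf("line %d of %s: expected 4 tab-separated fields, got %d",
            i, path, length(f))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 0L)
      stopf("line %d of %s: position must be a non-negative integer", i, path)
    if (!f[3] %in% c("+", "-"))
      stopf("line %d of %s: strand must be '+' or '-'", i, path)
    if (!f[4] %in% c("TIS", "STOP"))
      stopf("line %d of %s: site_type '%s' unknown (allowed: TIS, STOP)",
            i, path, f[4])
    out[[length(out) + 1L]] <-
      data.frame(seq_id = f[1], position = pos, strand = f[3],
                 site_type = f[4], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seq_id = character(), position = integer(),
                      strand = character(), site_type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write site annotations
#'
#' @param sites data frame as returned by [read_site_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#seq_id\tposition\tstrand\tsite_type", con)
  if (nrow(sites))
    writeLines(sprintf("%s\t%d\t%s\t%s", sites$seq_id, sites$position,
                       sites$strand, sites$site_type), con)
  invisible(path)
}
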