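DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the A/C/G/T/N alphabet
#' (N complements to N).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AACGT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Encode windows to an integer matrix, rows = windows, A,C,G,T,N -> 1..5.
encode_windows <- function(windows) {
  stopifnot(is.character(windows), length(windows) >= 1L)
  L <- nchar(windows[1])
  if (any(nchar(windows) != L)) stop("all windows must have equal length")
  ch <- unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE)
  code <- match(ch, DNA_ALPHABET)
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop("invalid character(s) in sequence window: ",
         paste(bad, collapse = ", "))
  }
  matrix(code, nrow = length(windows), ncol = L, byrow = TRUE)
}

decode_windows <- function(mat) {
  apply(mat, 1L, function(r) paste(DNA_ALPHABET[r], collapse = ""))
}

# Deterministic child seed derivation; keeps results below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1103515245 + p + 12345) %% 2147483647
  as.integer(s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
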