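# Weighted-degree string kernel.

#' Weighted-degree string kernel
#'
#' Computes the weighted-degree (WD) kernel between equal-length DNA
#' strings:
#' \deqn{k(x, y) = \sum_{d=1}^{D} \beta_d \sum_{i=1}^{L-d+1}
#'       \mathbf{1}[x_{i..i+d-1} = y_{i..i+d-1}]}
#' with weights \eqn{\beta_d = 2 (D - d + 1) / (D (D + 1))}, i.e. a
#' positionally aligned count of shared substrings of lengths 1..D with
#' linearly decreasing weights. Positions containing `N` never match,
#' not even against another `N`.
#'
#' @param x,y DNA strings of equal length `L >= D`.
#' @param D maximum substring degree, `1 <= D <= L`.
#' @return the kernel value (a single number).
#' @examples
#' wd_kernel("ACGTA", "ACGTA", D = 2)  # (2/3)*5 + (1/3)*4
#' wd_kernel("ACGT", "ACGA", D = 1)    # 3 matching positions
#' @export
wd_kernel <- function(x, y, D) {
  if (nchar(x) != nchar(y)) stop("sequence lengths differ")
  wd_kernel_matrix(encode_windows(x), encode_windows(y), D)[1L, 1L]
}

#' @rdname wd_kernel
#' @param X,Y character vectors of windows, or integer matrices as produced
#'   internally (rows = windows, A,C,G,T,N coded 1..5).
#' @return for `wd_kernel_matrix`, the `length(X) x length(Y)` kernel matrix.
#' @export
wd_kernel_matrix <- function(X, Y, D) {
  if (is.character(X)) X <- encode_windows(X)
  if (is.character(Y)) Y <- encode_windows(Y)
  wd_kernel_matrix_cpp(X, Y, as.integer(D))
}

#' Weighted-degree kernel weights
#'
#' @param D maximum degree.
#' @return the vector \eqn{\beta_1, \ldots, \beta_D}.
#' @export
wd_weights <- function(D) 2 * (D - seq_len(D) + 1) / (D * (D + 1))
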