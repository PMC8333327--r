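# Dynamic time warping of multivariate response-curve series.

#' Dynamic time warping distance
#'
#' Accumulated-cost DTW between two multivariate series (rows = ordered
#' index, columns = dimensions), with Euclidean local cost across
#' dimensions, the symmetric step pattern
#' `D(i,j) = c(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`, no warping
#' window and no path-length normalization.  Both series must have the same
#' number of dimensions; the dimensions share one warping path.
#'
#' @param a,b Numeric matrices (or vectors, treated as univariate series).
#' @return The accumulated DTW distance.
#' @export
#' @examples
#' dtw_distance(c(0, 0), c(1, 1))  # 2
dtw_distance <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  if (ncol(a) != ncol(b))
    abort("series must have the same number of dimensions",
          class = "zoopcurves_input_error")
  stopifnot_finite(a, "series a"); stopifnot_finite(b, "series b")
  dtw_dist_cpp(a, b)
}

#' Pairwise DTW distance matrix
#'
#' @param series A `zc_series` or plain list of matrices with equal column
#'   counts.
#' @return Symmetric matrix with zero diagonal; dimnames from the series
#'   names.
#' @export
dtw_matrix <- function(series) {
  n <- length(series)
  if (n < 3)
    abort("need at least 3 series", class = "zoopcurves_input_error")
  ids <- names(series) %||% as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- dtw_distance(series[[i]], series[[j]])
    }
  }
  D
}
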