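#' Overlap between two ternary response patterns
#'
#' Fraction of nodes in exactly the same state, \eqn{h(j,j') = \sum_i
#' \pi(r_i^j, r_i^{j'})/N} with \eqn{\pi = 1} on equality. Two inactive (0)
#' nodes count as a match -- the comparison is between states, not between
#' activations -- which is why the overlap rises toward 1 on over-thresholded
#' (mostly silent) networks. Equals 1 minus the normalized Hamming distance.
#'
#' @param ra,rb ternary state vectors of equal length.
#' @return overlap in [0, 1].
#' @export
overlap_pair <- function(ra, rb) {
  if (length(ra) != length(rb))
    stop("patterns have different lengths", call. = FALSE)
  mean(ra == rb)
}

#' Mean pairwise overlap of a response batch
#'
#' Average of \code{\link{overlap_pair}} over all K(K-1)/2 unordered response
#' pairs, computed via per-state indicator cross-products (three K x K
#' matrix multiplies).
#'
#' @param responses a \code{\link{simulate_transfer}} batch (or any object
#'   with a K x N integer \code{states} matrix), K >= 2.
#' @return an object of class \code{overlap_summary} with \code{mean_overlap}
#'   in [0, 1] and \code{pair_count} = K(K-1)/2.
#' @export
mean_overlap <- function(responses) {
  R <- if (is.matrix(responses)) responses else responses$states
  K <- nrow(R)
  if (is.null(K) || K < 2L)
    stop("need at least K = 2 patterns", call. = FALSE)
  N <- ncol(R)
  matches <- matrix(0, K, K)
  for (v in c(-1L, 0L, 1L)) {
    iv <- (R == v) * 1
    matches <- matches + iv %*% t(iv)
  }
  up <- upper.tri(matches)
  structure(
    list(mean_overlap = mean(matches[up]) / N,
         pair_count = as.integer(K * (K - 1) / 2)),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> mean overlap %.4f over %d pattern pairs\n",
              x$mean_overlap, x$pair_count))
  invisible(x)
}
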