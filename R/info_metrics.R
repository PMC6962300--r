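#' Plug-in entropy of a ternary variable
#'
#' \eqn{-\sum \hat p \log_2 \hat p} over the three state frequencies, with
#' \eqn{0 \log 0 = 0}. Reported in bits.
#'
#' @param counts length-3 vector of non-negative counts (states -1, 0, +1).
#' @return entropy in bits.
#' @export
ternary_entropy <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("`counts` must be three non-negative counts", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all-zero counts: entropy undefined", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Plug-in mutual information of one (stimulus, response) pair
#'
#' \eqn{m(i,j) = H(s_i) + H(r_j) - H(s_i, r_j)} from the empirical 3 x 3
#' joint table. Tiny negative values from floating-point cancellation are
#' clamped to 0 (plug-in MI is non-negative in exact arithmetic).
#'
#' @param joint 3 x 3 non-negative count table, rows = stimulus state
#'   (-1, 0, +1), columns = response state.
#' @return mutual information in bits.
#' @export
pair_mi <- function(joint) {
  if (!is.matrix(joint) || any(dim(joint) != c(3L, 3L)) || any(joint < 0))
    stop("`joint` must be a 3 x 3 non-negative count table", call. = FALSE)
  total <- sum(joint)
  if (total <= 0) stop("empty joint table", call. = FALSE)
  h_s <- ternary_entropy(rowSums(joint))
  h_r <- ternary_entropy(colSums(joint))
  p <- joint[joint > 0] / total
  h_sr <- -sum(p * log2(p))
  mi <- h_s + h_r - h_sr
  if (mi < -1e-12)
    stop(sprintf("plug-in MI came out %.3e < 0; corrupt counts?", mi),
         call. = FALSE)
  max(mi, 0)
}

#' Network-level mutual information between stimuli and responses
#'
#' Estimates the pairwise plug-in MI \eqn{m(i,j)} for every ordered pair
#' \eqn{i \ne j} from the K paired samples, then averages per target node
#' over its \eqn{N - 1} possible sources,
#' \eqn{\langle m(j)\rangle = \sum_{i \ne j} m(i,j)/(N-1)}, and over the
#' network, \eqn{m = \sum_j \langle m(j)\rangle / N}.
#'
#' The N^2 pairwise joint tables are accumulated with nine indicator
#' cross-products, so the cost is nine K x N by N x K matrix multiplies.
#'
#' @param stimuli a \code{\link{sample_stimuli}} batch.
#' @param responses the matching \code{\link{simulate_transfer}} batch.
#' @return an object of class \code{mi_summary}: \code{pair_mi} (N x N matrix
#'   in bits, diagonal NA), \code{node_means} (length N), \code{network_mi}
#'   (scalar, bits).
#' @export
network_mi <- function(stimuli, responses) {
  stopifnot(inherits(stimuli, "stimulus_batch"),
            inherits(responses, "response_batch"))
  S <- stimuli$states
  R <- responses$states
  if (!all(dim(S) == dim(R)))
    stop("stimulus and response batches are not aligned", call. = FALSE)
  K <- nrow(S)
  if (K < 2L) stop("need K >= 2 samples to estimate MI", call. = FALSE)
  N <- ncol(S)
  vals <- c(-1L, 0L, 1L)
  Is <- lapply(vals, function(v) (S == v) * 1)
  Ir <- lapply(vals, function(v) (R == v) * 1)
  # marginal entropies per node
  ent_from_counts <- function(cnt_mat) {
    # cnt_mat: 3 x N counts
    p <- cnt_mat / K
    colSums(ifelse(p > 0, -p * log2(p), 0))
  }
  h_s <- ent_from_counts(do.call(rbind, lapply(Is, colSums)))
  h_r <- ent_from_counts(do.call(rbind, lapply(Ir, colSums)))
  # joint entropy for all (i, j) pairs
  h_joint <- matrix(0, N, N)
  for (a in 1:3) {
    tIsa <- t(Is[[a]])
    for (b in 1:3) {
      p <- (tIsa %*% Ir[[b]]) / K
      nz <- p > 0
      h_joint[nz] <- h_joint[nz] - p[nz] * log2(p[nz])
    }
  }
  m <- outer(h_s, rep(1, N)) + outer(rep(1, N), h_r) - h_joint
  m[m < 0 & m > -1e-9] <- 0
  if (any(m < 0))
    stop("pairwise MI below numerical tolerance of 0", call. = FALSE)
  diag(m) <- NA_real_
  node_means <- colSums(m, na.rm = TRUE) / (N - 1)
  structure(
    list(pair_mi = m, node_means = node_means,
         network_mi = mean(node_means)),
    class = "mi_summary")
}

#' @export
print.mi_summary <- function(x, ...) {
  cat(sprintf("<mi_summary> network MI m = %.5f bits over %d nodes (node means %.5f..%.5f)\n",
              x$network_mi, length(x$node_means),
              min(x$node_means), max(x$node_means)))
  invisible(x)
}
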