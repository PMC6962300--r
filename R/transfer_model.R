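#' Sample a batch of random ternary stimulus patterns
#'
#' Each of the K stimuli is a length-N vector over \{-1, 0, +1\}: every entry
#' is independently +1 with probability \code{p}, -1 with probability \code{p}
#' (positive and negative activation are equiprobable) and inactive (0) with
#' probability \eqn{1 - 2p}.
#'
#' @param N number of nodes.
#' @param p activation probability per sign, in [0, 0.5].
#' @param K number of stimulus patterns (>= 1).
#' @param seed integer seed.
#' @return an object of class \code{stimulus_batch}: \code{states} is a K x N
#'   integer matrix (one stimulus per row), plus \code{p}, \code{K}, \code{N},
#'   \code{seed}.
#' @export
sample_stimuli <- function(N, p, K, seed) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 0.5)
    stop("`p` must be in [0, 0.5]", call. = FALSE)
  stopifnot(N >= 1, K >= 1)
  set.seed(as.integer(seed %% 2147483647))
  states <- matrix(
    sample(c(1L, -1L, 0L), size = K * N, replace = TRUE,
           prob = c(p, p, 1 - 2 * p)),
    nrow = K, ncol = N)
  structure(list(states = states, p = p, K = K, N = N, seed = seed),
            class = "stimulus_batch")
}

#' @export
print.stimulus_batch <- function(x, ...) {
  cat(sprintf("<stimulus_batch> K = %d stimuli on N = %d nodes, p = %g (non-zero fraction %.3f)\n",
              x$K, x$N, x$p, mean(x$states != 0)))
  invisible(x)
}

# classify pre-activations against the effective response threshold t* >= 0:
# +1 above t*, -1 below -t*, 0 in the closed band [-t*, t*]
classify_response <- function(r_hat, t_star) {
  r <- integer(length(r_hat))
  r[r_hat > t_star] <- 1L
  r[r_hat < -t_star] <- -1L
  r
}

#' One-step ternary response of a thresholded network
#'
#' Computes the pre-activation \eqn{\hat r_j = \sum_{i \ne j} \tilde w_{ij} s_i}
#' over the retained (thresholded, signed) weights and classifies it:
#' \eqn{r_j = +1} if \eqn{\hat r_j > t^*}, \eqn{-1} if \eqn{\hat r_j < -t^*},
#' else 0, with \eqn{t^* = \max(w_t, 0)}. For a negative cut-off the
#' classification degenerates to the plain sign (0 maps to 0).
#'
#' @param net a \code{\link{thresholded_network}}.
#' @param s ternary stimulus vector of length N (values in \{-1, 0, +1\}).
#' @return a list with \code{state} (integer ternary response vector) and
#'   \code{pre_activation} (numeric \eqn{\hat r}).
#' @export
respond <- function(net, s) {
  stopifnot(inherits(net, "thresholded_network"))
  if (length(s) != net$N)
    stop(sprintf("stimulus length %d does not match network size %d",
                 length(s), net$N), call. = FALSE)
  if (!all(s %in% c(-1L, 0L, 1L)))
    stop("stimulus entries must be in {-1, 0, +1}", call. = FALSE)
  r_hat <- as.vector(net$weights %*% s)
  list(state = classify_response(r_hat, net$t_star), pre_activation = r_hat)
}

#' Simulate one-step transfer for a whole stimulus batch
#'
#' Applies \code{\link{respond}} to every stimulus in the batch (order
#' preserved), vectorized as one matrix product.
#'
#' @param net a \code{\link{thresholded_network}}.
#' @param batch a \code{\link{sample_stimuli}} batch on the same N.
#' @return an object of class \code{response_batch}: \code{states} and
#'   \code{pre_activation} are K x N matrices, \code{network} keeps the
#'   generating network.
#' @export
simulate_transfer <- function(net, batch) {
  stopifnot(inherits(net, "thresholded_network"),
            inherits(batch, "stimulus_batch"))
  if (batch$N != net$N)
    stop("stimulus batch and network sizes differ", call. = FALSE)
  # (S W)_{kj} = sum_i s_{ki} w_{ij}; W symmetric with zero diagonal
  r_hat <- batch$states %*% net$weights
  states <- matrix(0L, nrow(r_hat), ncol(r_hat))
  states[r_hat > net$t_star] <- 1L
  states[r_hat < -net$t_star] <- -1L
  structure(list(states = states, pre_activation = r_hat, network = net,
                 K = batch$K, N = batch$N),
            class = "response_batch")
}

#' @export
print.response_batch <- function(x, ...) {
  cat(sprintf("<response_batch> K = %d responses on N = %d nodes (non-zero fraction %.3f)\n",
              x$K, x$N, mean(x$states != 0)))
  invisible(x)
}

#' Deterministic seed streams for nested simulation loops
#'
#' Maps a root seed plus up to four loop indices to a derived seed below
#' 2^31, so every (subject, threshold, probability) condition gets its own
#' reproducible stimulus stream.
#'
#' @param root integer root seed.
#' @param ... up to four non-negative integer indices.
#' @return a single integer seed.
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  if (length(idx) > 4L) stop("at most four indices are supported", call. = FALSE)
  primes <- c(7919, 104729, 1299709, 15485863)
  val <- as.numeric(root) %% 2147483629
  for (k in seq_along(idx))
    val <- (val + primes[k] * as.numeric(idx[k])) %% 2147483629
  as.integer(val)
}
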