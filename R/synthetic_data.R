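#' Single uniform-weight null matrix
#'
#' Null-model matrix: i.i.d. weights uniform on [-1, 1] on the upper triangle,
#' mirrored to the lower triangle, zero diagonal. The null ensemble is the
#' baseline against which the correlation-structured matrices are compared
#' (its one-step responses carry no weight structure, so the Hopfield energy
#' cancels in the ensemble mean).
#'
#' @param N number of nodes.
#' @param seed integer seed for this matrix.
#' @param subject_id identifier (default derived from the seed).
#' @return a \code{\link{connectivity_matrix}}.
#' @export
random_null_matrix <- function(N, seed, subject_id = sprintf("null_%d", seed)) {
  stopifnot(N >= 2)
  set.seed(as.integer(seed %% 2147483647))
  w <- matrix(0, N, N)
  up <- upper.tri(w)
  w[up] <- stats::runif(sum(up), -1, 1)
  w <- w + t(w)
  connectivity_matrix(w, subject_id = subject_id)
}

#' Ensemble of uniform-weight null matrices
#'
#' Seed policy: matrix \code{i} uses the stream \code{seed + i}, so any member
#' can be regenerated independently with \code{\link{random_null_matrix}}.
#'
#' @param N number of nodes.
#' @param count ensemble size (>= 1).
#' @param seed root integer seed.
#' @return a list of \code{\link{connectivity_matrix}} objects.
#' @export
random_null_matrices <- function(N, count, seed) {
  stopifnot(count >= 1)
  lapply(seq_len(count), function(i)
    random_null_matrix(N, seed = seed + i, subject_id = sprintf("null_%04d", i)))
}

#' Brain-like correlation matrix from a latent factor model
#'
#' Simulates node time series
#' \deqn{x_i(t) = a_i\,g(t) + b_i\,f_{c(i)}(t) + \epsilon_i(t)}
#' with a standard-normal global signal \eqn{g}, independent standard-normal
#' community signals \eqn{f_c} (nodes assigned to \code{n_communities}
#' contiguous blocks), and Gaussian noise of sd \code{noise_sd}. A random
#' fraction \code{hub_fraction} of nodes carries the global loading
#' (\eqn{a_i =} \code{hub_loading}, otherwise 0); every node carries its
#' community loading (\eqn{b_i =} \code{community_loading}). The returned
#' matrix is the Pearson correlation matrix of the series with its diagonal
#' zeroed. Hubs pick up correlation with every other hub through \eqn{g}, so
#' the node-strength distribution is right-skewed, mimicking the heavy-tailed
#' strengths of functional connectomes.
#'
#' @param N number of nodes.
#' @param T_len number of time points (>= 10).
#' @param n_communities number of communities (<= N).
#' @param hub_fraction fraction of hub nodes in (0, 1); \code{hub_fraction * N}
#'   must be >= 1.
#' @param hub_loading global-signal loading of hub nodes (>= 0).
#' @param community_loading community-signal loading (>= 0).
#' @param noise_sd noise standard deviation (> 0).
#' @param seed integer seed.
#' @param subject_id identifier.
#' @return a \code{\link{connectivity_matrix}}.
#' @export
factor_model_matrix <- function(N = 120, T_len = 200, n_communities = 4,
                                hub_fraction = 0.1, hub_loading = 0.8,
                                community_loading = 0.5, noise_sd = 1.0,
                                seed = 1,
                                subject_id = sprintf("factor_%d", seed)) {
  stopifnot(N >= 2, n_communities >= 1, n_communities <= N,
            hub_fraction > 0, hub_fraction < 1, hub_loading >= 0,
            community_loading >= 0, noise_sd > 0)
  if (T_len < 10)
    stop("degenerate input: need at least 10 time points", call. = FALSE)
  if (hub_fraction * N < 1)
    stop("hub_fraction * N must be >= 1", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  community <- sort(rep(seq_len(n_communities), length.out = N))  # contiguous blocks
  n_hubs <- max(1L, round(hub_fraction * N))
  hubs <- sample.int(N, n_hubs)
  a <- numeric(N); a[hubs] <- hub_loading
  g <- stats::rnorm(T_len)
  f <- matrix(stats::rnorm(T_len * n_communities), T_len, n_communities)
  eps <- matrix(stats::rnorm(T_len * N, sd = noise_sd), T_len, N)
  x <- sweep(f[, community, drop = FALSE], 2L, rep(community_loading, N), `*`) +
    outer(g, a) + eps
  w <- stats::cor(x)
  out <- connectivity_matrix(w, subject_id = subject_id)
  attr(out, "hubs") <- sort(hubs)
  out
}

#' Sample node strengths from the upper-truncated power law
#'
#' Direct i.i.d. draws from the density \eqn{p(ns) \propto (ns_{max} - ns)^\gamma}
#' on \eqn{[ns_{min}, ns_{max}]}, used for estimator-recovery tests of
#' \code{\link{fit_strength_model}}. Sampling is by inverse CDF on the mirrored
#' variable \eqn{u = ns_{max} - ns}, which follows a power-function law:
#' \eqn{u = (ns_{max} - ns_{min})\,U^{1/(\gamma+1)}} for uniform \eqn{U}.
#'
#' @param n number of draws.
#' @param gamma exponent, must exceed -1 (otherwise non-normalizable).
#' @param ns_max upper strength limit.
#' @param ns_min lower support bound, \code{ns_min < ns_max}.
#' @param seed integer seed.
#' @return numeric vector of length \code{n} in \code{[ns_min, ns_max]}.
#' @export
sample_strengths <- function(n, gamma, ns_max, ns_min, seed) {
  if (gamma <= -1)
    stop("gamma <= -1: density is non-normalizable", call. = FALSE)
  stopifnot(ns_min < ns_max, n >= 1)
  set.seed(as.integer(seed %% 2147483647))
  u <- (ns_max - ns_min) * stats::runif(n)^(1 / (gamma + 1))
  ns_max - u
}
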