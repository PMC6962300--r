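adjacency_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Largest-connected-component fraction
#'
#' Size of the largest connected component of the (undirected) thresholded
#' adjacency graph, divided by N. Isolated nodes are components of size 1, so
#' the fraction never drops below 1/N; 1 means the graph is fully connected.
#'
#' @param net a \code{\link{thresholded_network}}.
#' @return real in (0, 1].
#' @export
largest_component_fraction <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  comp <- igraph::components(adjacency_graph(net))
  max(comp$csize) / net$N
}

#' Global clustering coefficient (transitivity)
#'
#' \eqn{C = 3 \times} triangles / connected triples: the probability that two
#' neighbours of a node are themselves connected. Returns 0 when the graph
#' has no connected triple.
#'
#' @param net a \code{\link{thresholded_network}}.
#' @return real in [0, 1].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  C <- igraph::transitivity(adjacency_graph(net), type = "global")
  if (is.nan(C)) 0 else C
}

#' Consecutive differences of a clustering-coefficient series
#'
#' For a series C recorded along an ascending threshold grid,
#' \eqn{\Delta C(i) = C(i) - C(i+1)} with i counted from the lower-threshold
#' side; a stable (small-|Delta C|) stretch marks the plateau that precedes
#' the topological break-up.
#'
#' @param C_values numeric vector of clustering coefficients (length >= 2).
#' @param thresholds optional matching vector of threshold multipliers; must
#'   be strictly ascending if supplied.
#' @return numeric vector of length \code{length(C_values) - 1}.
#' @export
clustering_differences <- function(C_values, thresholds = NULL) {
  if (length(C_values) < 2L)
    stop("need at least two clustering values", call. = FALSE)
  if (!is.null(thresholds)) {
    if (length(thresholds) != length(C_values))
      stop("`thresholds` and `C_values` lengths differ", call. = FALSE)
    if (any(diff(thresholds) <= 0))
      stop("`thresholds` must be strictly ascending", call. = FALSE)
  }
  -diff(C_values)
}

#' Absolute node strengths of a thresholded network
#'
#' \eqn{ns_i = \sum_{j \ne i} |\tilde w_{ij}|} over the retained weights. The
#' strengths change with the threshold, tracing how the weighted core of the
#' network erodes as connections are removed.
#'
#' @param net a \code{\link{thresholded_network}}.
#' @return numeric vector of length N.
#' @export
node_strengths <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  rowSums(abs(net$weights))
}

#' Two-sided Kolmogorov-Smirnov distance from a model CDF
#'
#' \eqn{D = \max_k \max(|F(x_{(k)}) - k/n|, |F(x_{(k)}) - (k-1)/n|)}: the
#' largest gap between the empirical step function and the model CDF,
#' evaluated on both sides of every step.
#'
#' @param sorted_sample numeric vector sorted ascending.
#' @param model_cdf monotone function mapping the support to [0, 1].
#' @return KS distance in [0, 1].
#' @export
ks_distance <- function(sorted_sample, model_cdf) {
  n <- length(sorted_sample)
  if (n < 1L) stop("empty sample", call. = FALSE)
  if (is.unsorted(sorted_sample))
    stop("`sorted_sample` must be sorted ascending", call. = FALSE)
  Fx <- model_cdf(sorted_sample)
  k <- seq_len(n)
  max(pmax(abs(Fx - k / n), abs(Fx - (k - 1) / n)))
}

#' Fit the upper-truncated power-law strength model
#'
#' Fits \eqn{p(ns) \propto (ns_{max} - ns)^\gamma} on
#' \eqn{[ns_{min}, ns_{max}]} to a strength sample, with
#' \eqn{ns_{min} = \min(ns)}. For each candidate \eqn{ns_{max}} on a
#' \code{grid_size}-point grid spanning \eqn{(\max(ns)(1 + 10^{-6}),\,
#' \max(ns) + 2\,\mathrm{range}(ns)]}, the exponent has the closed-form
#' conditional maximum-likelihood solution
#' \deqn{\hat\gamma = 1 / \mathrm{mean}\,\ln\frac{ns_{max} - ns_{min}}
#'       {ns_{max} - ns_i} - 1,}
#' and the candidate minimizing the KS distance between the model CDF
#' \eqn{F(x) = 1 - ((ns_{max} - x)/(ns_{max} - ns_{min}))^{\hat\gamma + 1}}
#' and the empirical CDF is selected. A Gaussian fit (sample mean/sd) to the
#' same data provides the comparison KS distance.
#'
#' @param ns numeric strength sample, length >= 10, not all equal.
#' @param grid_size number of \eqn{ns_{max}} candidates (default 50).
#' @return an object of class \code{strength_fit} with fields \code{gamma},
#'   \code{ns_max}, \code{ns_min}, \code{ks_D}, \code{ks_D_normal}, and
#'   \code{model_cdf} (the fitted CDF function).
#' @export
fit_strength_model <- function(ns, grid_size = 50) {
  ns <- as.numeric(ns)
  if (length(ns) < 10L)
    stop("need at least 10 strength values to fit", call. = FALSE)
  rng <- range(ns)
  if (diff(rng) <= 0)
    stop("degenerate sample: all strengths equal", call. = FALSE)
  ns_min <- rng[1L]
  mx <- rng[2L]
  span <- diff(rng)
  sorted <- sort(ns)
  candidates <- seq(mx * (1 + 1e-6) + span * 1e-9, mx + 2 * span,
                    length.out = grid_size)
  best <- NULL
  for (cand in candidates) {
    mean_log <- mean(log((cand - ns_min) / (cand - ns)))
    if (!is.finite(mean_log) || mean_log <= 0) next
    gamma_hat <- 1 / mean_log - 1
    cdf <- local({
      nm <- cand; lo <- ns_min; ex <- gamma_hat + 1
      function(x) {
        f <- 1 - ((nm - pmin(x, nm)) / (nm - lo))^ex
        pmin(pmax(f, 0), 1)
      }
    })
    D <- ks_distance(sorted, cdf)
    if (is.null(best) || D < best$ks_D)
      best <- list(gamma = gamma_hat, ns_max = cand, ks_D = D, model_cdf = cdf)
  }
  if (is.null(best))
    stop("strength-model fit failed on this sample", call. = FALSE)
  mu <- mean(ns)
  sdv <- stats::sd(ns)
  ks_norm <- ks_distance(sorted, function(x) stats::pnorm(x, mu, sdv))
  structure(
    list(gamma = best$gamma, ns_max = best$ns_max, ns_min = ns_min,
         ks_D = best$ks_D, ks_D_normal = ks_norm, model_cdf = best$model_cdf,
         n = length(ns)),
    class = "strength_fit")
}

#' @export
print.strength_fit <- function(x, ...) {
  cat(sprintf("<strength_fit> gamma = %.3f, ns_max = %.4g on [%.4g, ns_max], n = %d\n",
              x$gamma, x$ns_max, x$ns_min, x$n))
  cat(sprintf("  KS distance: model %.4f vs normal %.4f\n",
              x$ks_D, x$ks_D_normal))
  invisible(x)
}
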