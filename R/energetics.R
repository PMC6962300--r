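#' Wiring cost of a thresholded network
#'
#' \eqn{E_W = \sum_{i,j} a_{ij}} over all ordered pairs (the adjacency is
#' symmetric, so each undirected edge counts twice; the diagonal is zero).
#'
#' @param net a \code{\link{thresholded_network}}.
#' @return non-negative integer ordered-pair edge count.
#' @export
wiring_cost <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  as.integer(sum(net$adjacency))
}

#' Hopfield energy of a ternary activation state
#'
#' Bias-free Hopfield energy over the retained signed weights,
#' \eqn{E_H = -\sum_{i \ne j} r_i \tilde w_{ij} r_j} (ordered pairs, so each
#' symmetric term is counted twice). Negative values mark low-energy
#' (mutually consistent) activation states.
#'
#' @param net a \code{\link{thresholded_network}}.
#' @param r ternary state vector of length N.
#' @return Hopfield energy (real).
#' @export
hopfield_energy <- function(net, r) {
  stopifnot(inherits(net, "thresholded_network"))
  if (length(r) != net$N) stop("state length does not match N", call. = FALSE)
  -as.numeric(t(r) %*% net$weights %*% r)
}

#' Activity cost of a ternary activation state
#'
#' \eqn{E_A = \sum_{i \ne j} |r_i \tilde w_{ij} r_j|}: the unsigned total
#' interaction magnitude, which avoids the sign cancellation of the Hopfield
#' energy. Always \eqn{E_A \ge |E_H|}.
#'
#' @inheritParams hopfield_energy
#' @return non-negative real.
#' @export
activity_cost <- function(net, r) {
  stopifnot(inherits(net, "thresholded_network"))
  if (length(r) != net$N) stop("state length does not match N", call. = FALSE)
  a <- abs(r)
  as.numeric(t(a) %*% abs(net$weights) %*% a)
}

#' Batch energy report with normalized quantities
#'
#' Averages the Hopfield energy and the activity cost over the K responses of
#' a batch and forms the two normalized quantities: \eqn{E_H/E_W} (activity
#' energy per retained connection) and \eqn{E_W/E_A} (wiring cost per unit of
#' activity). Zero denominators yield \code{NA} with the matching
#' \code{*_defined} flag set to \code{FALSE}, never an error.
#'
#' @param net a \code{\link{thresholded_network}}.
#' @param responses a \code{\link{simulate_transfer}} batch on \code{net}.
#' @return an object of class \code{energy_report} with fields \code{E_W},
#'   \code{E_H}, \code{E_A} (batch means), \code{EH_over_EW},
#'   \code{EW_over_EA}, \code{EH_over_EW_defined}, \code{EW_over_EA_defined},
#'   and the per-response vectors \code{E_H_each}, \code{E_A_each}.
#' @export
energy_report <- function(net, responses) {
  stopifnot(inherits(net, "thresholded_network"),
            inherits(responses, "response_batch"))
  R <- responses$states
  if (ncol(R) != net$N) stop("batch does not match network size", call. = FALSE)
  W <- net$weights
  e_h <- -rowSums((R %*% W) * R)
  Ra <- abs(R)
  e_a <- rowSums((Ra %*% abs(W)) * Ra)
  E_W <- wiring_cost(net)
  E_H <- mean(e_h)
  E_A <- mean(e_a)
  eh_ew_ok <- E_W > 0
  ew_ea_ok <- E_A > 0
  structure(
    list(E_W = E_W, E_H = E_H, E_A = E_A,
         EH_over_EW = if (eh_ew_ok) E_H / E_W else NA_real_,
         EW_over_EA = if (ew_ea_ok) E_W / E_A else NA_real_,
         EH_over_EW_defined = eh_ew_ok,
         EW_over_EA_defined = ew_ea_ok,
         E_H_each = e_h, E_A_each = e_a, K = nrow(R)),
    class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> E_W = %d, E_H = %.5g, E_A = %.5g over K = %d responses\n",
              x$E_W, x$E_H, x$E_A, x$K))
  cat(sprintf("  E_H/E_W = %s, E_W/E_A = %s\n",
              if (x$EH_over_EW_defined) sprintf("%.5g", x$EH_over_EW) else "undefined",
              if (x$EW_over_EA_defined) sprintf("%.5g", x$EW_over_EA) else "undefined"))
  invisible(x)
}
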