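#' Construct a connectivity matrix object
#'
#' Wraps an N x N symmetric weight matrix (e.g. a Pearson correlation matrix
#' between regional fMRI time series) together with subject metadata. The
#' diagonal is zeroed on construction: self-correlations are artifacts and are
#' excluded from all downstream statistics (threshold moments, energies, the
#' response sum).
#'
#' @param weights numeric N x N matrix, N >= 2.
#' @param subject_id character scalar identifying the subject.
#' @param node_labels optional character vector of length N.
#' @param symmetrize_tol asymmetry beyond this (max |w - t(w)|) triggers a
#'   warning before symmetrization by averaging; it is never an error.
#' @return an object of class \code{connectivity_matrix} with fields
#'   \code{subject_id}, \code{N}, \code{weights}, \code{node_labels}.
#' @export
connectivity_matrix <- function(weights, subject_id = "subject",
                                node_labels = NULL, symmetrize_tol = 1e-6) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop(sprintf("`weights` must be square, got %d x %d",
                 nrow(weights), ncol(weights)), call. = FALSE)
  n <- nrow(weights)
  if (n < 2L)
    stop("connectivity matrix needs N >= 2 nodes", call. = FALSE)
  if (anyNA(weights))
    stop("`weights` contains missing values", call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetrize_tol)
    warning(sprintf(
      "matrix '%s' asymmetric beyond %.1e (max deviation %.3e); symmetrizing by averaging",
      subject_id, symmetrize_tol, asym), call. = FALSE)
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != n)
      stop("`node_labels` must have one entry per node", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), N = n, weights = w,
         node_labels = node_labels),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject '%s', N = %d nodes\n",
              x$subject_id, x$N))
  offd <- offdiag_values(x$weights)
  cat(sprintf("  off-diagonal |w|: mean %.4g, sd %.4g, max %.4g\n",
              mean(abs(offd)), stats::sd(abs(offd)), max(abs(offd))))
  invisible(x)
}

# off-diagonal entries of a square matrix as a vector (both triangles)
offdiag_values <- function(w) w[row(w) != col(w)]

#' Read a connectivity matrix from a delimited text file
#'
#' Reads the plain-text N x N numeric grid format used for connectivity-matrix
#' dumps (one row per line). The subject id is taken from the file stem. The
#' matrix is symmetrized by averaging (with a warning when the asymmetry
#' exceeds \code{1e-6}) and the diagonal is zeroed.
#'
#' @param path path to the matrix file.
#' @param delimiter one of \code{"whitespace"} (default), \code{"comma"},
#'   \code{"tab"}.
#' @param node_labels_path optional path to a one-label-per-line sidecar file.
#' @return a \code{\link{connectivity_matrix}}.
#' @export
read_connectivity_matrix <- function(path,
                                     delimiter = c("whitespace", "comma", "tab"),
                                     node_labels_path = NULL) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path))
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop(sprintf("matrix file is empty: %s", path), call. = FALSE)
  splitter <- switch(delimiter,
    whitespace = "[[:space:]]+",
    comma      = "[[:space:]]*,[[:space:]]*",
    tab        = "\t")
  cells <- strsplit(lines, splitter)
  ncols <- lengths(cells)
  nr <- length(cells)
  if (any(ncols != nr))
    stop(sprintf(
      "non-square grid in %s: %d rows but row %d has %d columns",
      path, nr, which(ncols != nr)[1L], ncols[ncols != nr][1L]), call. = FALSE)
  vals <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_len(nr)) {
    bad <- which(is.na(vals[[i]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                   cells[[i]][bad[1L]], i, bad[1L], path), call. = FALSE)
  }
  w <- do.call(rbind, vals)
  labels <- NULL
  if (!is.null(node_labels_path)) {
    labels <- trimws(readLines(node_labels_path))
    labels <- labels[nzchar(labels)]
  }
  connectivity_matrix(w,
                      subject_id = tools::file_path_sans_ext(basename(path)),
                      node_labels = labels)
}

#' Write a connectivity matrix as whitespace-delimited text
#'
#' @param M a \code{\link{connectivity_matrix}}.
#' @param path output file path.
#' @param digits significant digits to write (default 9).
#' @return \code{path}, invisibly.
#' @export
write_connectivity_matrix <- function(M, path, digits = 9) {
  stopifnot(inherits(M, "connectivity_matrix"))
  fmt <- sprintf("%%.%dg", as.integer(digits))
  rows <- apply(M$weights, 1L, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' Compute the subject-specific connectivity threshold
#'
#' The cut-off is defined from the moments of the absolute off-diagonal
#' weights: \eqn{w_t = \langle|w|\rangle + n\,\sigma_{|w|}}. Both triangles of
#' the (symmetric) matrix enter the moments; the diagonal never does. The
#' standard deviation is the sample sd (denominator \eqn{m - 1} over the
#' \eqn{m = N(N-1)} off-diagonal entries).
#'
#' @param M a \code{\link{connectivity_matrix}}.
#' @param n real threshold multiplier (may be negative).
#' @return an object of class \code{threshold_spec} with fields \code{n},
#'   \code{mean_abs_w}, \code{sd_abs_w}, \code{w_t}.
#' @export
compute_threshold <- function(M, n) {
  stopifnot(inherits(M, "connectivity_matrix"))
  if (M$N < 2L) stop("degenerate matrix: N < 2", call. = FALSE)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n))
  aw <- abs(offdiag_values(M$weights))
  mu <- mean(aw)
  sdv <- stats::sd(aw)
  structure(
    list(n = n, mean_abs_w = mu, sd_abs_w = sdv, w_t = mu + n * sdv),
    class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> n = %g: w_t = %.6g (<|w|> = %.6g, sd = %.6g)\n",
              x$n, x$w_t, x$mean_abs_w, x$sd_abs_w))
  invisible(x)
}

#' Low-level constructor for a thresholded network
#'
#' Normally produced by \code{\link{apply_threshold}}; exposed so that small
#' networks with hand-picked retained weights can be built directly (e.g. in
#' worked examples). \code{weights} are the retained signed weights (zero where
#' the connection was removed); the adjacency and the effective response
#' threshold \eqn{t^* = \max(w_t, 0)} are derived.
#'
#' @param weights N x N signed retained-weight matrix (zero diagonal).
#' @param spec a \code{threshold_spec} (only \code{w_t} is required; use
#'   \code{list(w_t = ...)} for ad-hoc networks).
#' @return an object of class \code{thresholded_network} with fields
#'   \code{spec}, \code{weights}, \code{adjacency}, \code{t_star}, \code{N}.
#' @export
thresholded_network <- function(weights, spec) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (is.null(spec$w_t) || !is.finite(spec$w_t))
    stop("`spec` must carry a finite w_t", call. = FALSE)
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  adj <- (w != 0) * 1L
  structure(
    list(spec = spec, weights = w, adjacency = adj,
         t_star = max(spec$w_t, 0), N = nrow(w)),
    class = "thresholded_network")
}

#' Apply a connectivity threshold to a matrix
#'
#' Retains connections with \eqn{|w_{ij}| > w_t} (strict; ties at exactly
#' \eqn{w_t} are dropped). Retained weights keep their sign. The effective
#' response threshold is \eqn{t^* = \max(w_t, 0)}: a negative cut-off retains
#' every connection and classifies responses by plain sign.
#'
#' @param M a \code{\link{connectivity_matrix}}.
#' @param spec a \code{threshold_spec} from \code{\link{compute_threshold}}.
#' @return a \code{\link{thresholded_network}}.
#' @export
apply_threshold <- function(M, spec) {
  stopifnot(inherits(M, "connectivity_matrix"))
  w <- M$weights
  w[abs(w) <= spec$w_t] <- 0
  diag(w) <- 0
  thresholded_network(w, spec)
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf(
    "<thresholded_network> N = %d, w_t = %.6g (t* = %.6g), %d undirected edges\n",
    x$N, x$spec$w_t, x$t_star, sum(x$adjacency) / 2))
  invisible(x)
}

#' Principal submatrix on a random node subset
#'
#' Robustness check: re-run the analysis on a matrix restricted to \code{k}
#' uniformly sampled nodes (e.g. 100 of the 177 regions).
#'
#' @param M a \code{\link{connectivity_matrix}}.
#' @param k number of nodes to keep, \code{2 <= k <= N}.
#' @param seed integer seed; the same seed always selects the same subset.
#' @return a \code{\link{connectivity_matrix}} on the sampled nodes (indices
#'   kept in ascending order; attribute \code{"nodes"} records them).
#' @export
subsample_nodes <- function(M, k, seed) {
  stopifnot(inherits(M, "connectivity_matrix"))
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2L || k > M$N)
    stop(sprintf("`k` must be an integer in [2, %d]", M$N), call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sort(sample.int(M$N, k))
  out <- connectivity_matrix(
    M$weights[idx, idx, drop = FALSE],
    subject_id = sprintf("%s_sub%d", M$subject_id, k),
    node_labels = if (!is.null(M$node_labels)) M$node_labels[idx])
  attr(out, "nodes") <- idx
  out
}
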