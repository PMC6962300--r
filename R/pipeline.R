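#' Threshold / activation-probability sweep over a matrix collection
#'
#' For every (subject, threshold multiplier n, activation probability p):
#' compute the subject-specific cut-off, threshold the matrix, simulate K
#' random ternary stimuli and their one-step responses, and record the full
#' metric row -- network mutual information, the three energies and the two
#' normalized energies, mean pattern overlap, largest-component fraction,
#' transitivity, and the strength-distribution fit (KS distance and exponent).
#' Topology and the strength fit depend only on (subject, n) and are computed
#' once per threshold. Stimulus seeds are derived deterministically from
#' (\code{root_seed}, subject index, n index, p index) via
#' \code{\link{derive_seed}}, so identical calls give bit-identical tables.
#'
#' A failing subject is skipped with a warning, never fatally. Conditions
#' where the strength fit is degenerate (e.g. the over-thresholded regime
#' with all-zero strengths) carry \code{NA} in \code{ks_D} and \code{gamma}.
#'
#' @param matrices list of \code{\link{connectivity_matrix}} objects (or a
#'   single one).
#' @param n_grid ascending vector of threshold multipliers
#'   (default \code{seq(-2, 2, by = 0.2)}).
#' @param p_values activation probabilities in [0, 0.5]
#'   (default \code{c(0.1, 0.05, 0.01)}).
#' @param K stimuli per condition (default 100, >= 2).
#' @param root_seed integer root seed.
#' @param subject_limit optional cap on the number of subjects used.
#' @param verbose print one progress line per subject.
#' @return a \code{data.frame} with one row per (subject, n, p) and columns
#'   \code{subject_id, n, p, mi, E_W, E_H, E_A, EH_over_EW, EW_over_EA,
#'   overlap, lcc_fraction, C, ks_D, gamma}.
#' @export
run_sweep <- function(matrices, n_grid = seq(-2, 2, by = 0.2),
                      p_values = c(0.1, 0.05, 0.01), K = 100,
                      root_seed = 1, subject_limit = NULL, verbose = FALSE) {
  if (inherits(matrices, "connectivity_matrix")) matrices <- list(matrices)
  if (length(matrices) == 0L)
    stop("empty matrix source", call. = FALSE)
  if (is.unsorted(n_grid, strictly = TRUE))
    stop("`n_grid` must be strictly ascending", call. = FALSE)
  if (any(p_values < 0 | p_values > 0.5))
    stop("all `p_values` must lie in [0, 0.5]", call. = FALSE)
  if (K < 2L) stop("need K >= 2 stimuli per condition", call. = FALSE)
  if (!is.null(subject_limit))
    matrices <- matrices[seq_len(min(subject_limit, length(matrices)))]

  rows <- vector("list", length(matrices))
  for (si in seq_along(matrices)) {
    M <- matrices[[si]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      sweep_one_subject(M, si, n_grid, p_values, K, root_seed),
      error = function(e) {
        warning(sprintf("subject '%s' skipped: %s",
                        M$subject_id, conditionMessage(e)), call. = FALSE)
        NULL
      })
    rows[[si]] <- res
    if (verbose)
      message(sprintf("[sweep] %s: %d conditions in %.2fs",
                      M$subject_id,
                      if (is.null(res)) 0L else nrow(res),
                      proc.time()[["elapsed"]] - t0))
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("every subject failed; no sweep records produced", call. = FALSE)
  rownames(out) <- NULL
  out
}

sweep_one_subject <- function(M, si, n_grid, p_values, K, root_seed) {
  recs <- vector("list", length(n_grid) * length(p_values))
  k <- 0L
  for (ni in seq_along(n_grid)) {
    spec <- compute_threshold(M, n_grid[ni])
    net <- apply_threshold(M, spec)
    lcc <- largest_component_fraction(net)
    C <- clustering_coefficient(net)
    fit <- tryCatch(fit_strength_model(node_strengths(net)),
                    error = function(e) NULL)
    for (pi in seq_along(p_values)) {
      p <- p_values[pi]
      stim <- sample_stimuli(M$N, p, K,
                             seed = derive_seed(root_seed, si, ni, pi))
      resp <- simulate_transfer(net, stim)
      mi <- network_mi(stim, resp)
      en <- energy_report(net, resp)
      ov <- mean_overlap(resp)
      k <- k + 1L
      recs[[k]] <- data.frame(
        subject_id = M$subject_id, n = n_grid[ni], p = p,
        mi = mi$network_mi,
        E_W = en$E_W, E_H = en$E_H, E_A = en$E_A,
        EH_over_EW = en$EH_over_EW, EW_over_EA = en$EW_over_EA,
        overlap = ov$mean_overlap,
        lcc_fraction = lcc, C = C,
        ks_D = if (is.null(fit)) NA_real_ else fit$ks_D,
        gamma = if (is.null(fit)) NA_real_ else fit$gamma,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Aggregate a sweep table across subjects
#'
#' Per (n, p) condition: mean and sample standard deviation of every metric
#' column across subjects. With a single subject the sd columns are \code{NA}.
#'
#' @param sweep_table a \code{\link{run_sweep}} result.
#' @return a \code{data.frame} keyed by (n, p) with \code{<metric>_mean} and
#'   \code{<metric>_sd} columns plus \code{n_subjects}.
#' @export
aggregate_sweep <- function(sweep_table) {
  if (is.null(sweep_table) || nrow(sweep_table) == 0L)
    stop("empty sweep table", call. = FALSE)
  metric_cols <- setdiff(names(sweep_table), c("subject_id", "n", "p"))
  key <- interaction(sweep_table$n, sweep_table$p, drop = TRUE)
  groups <- split(sweep_table, key)
  rows <- lapply(groups, function(g) {
    out <- data.frame(n = g$n[1L], p = g$p[1L], n_subjects = nrow(g))
    for (col in metric_cols) {
      v <- g[[col]]
      out[[paste0(col, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(col, "_sd")]] <- if (nrow(g) > 1L)
        stats::sd(v, na.rm = TRUE) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-quantity correlation along the threshold axis
#'
#' Emits the (x, y) series indexed by threshold (the scatter behind the
#' figure-style correlation panels) together with its Pearson coefficient,
#' and locates the thresholds at which each quantity peaks and bottoms out.
#' Mean columns from \code{\link{aggregate_sweep}} may be addressed by their
#' base metric name (\code{"mi"} resolves to \code{"mi_mean"}).
#'
#' @param aggregated an \code{\link{aggregate_sweep}} table (or a raw
#'   single-subject sweep table).
#' @param x,y column names to correlate.
#' @param p optional: restrict to one activation probability first.
#' @return an object of class \code{sweep_correlation}: \code{series}
#'   (data.frame n, x, y), \code{pearson} (\code{NA} + \code{defined = FALSE}
#'   when either column has zero variance), \code{x_argmax_n},
#'   \code{x_argmin_n}, \code{y_argmax_n}, \code{y_argmin_n}.
#' @export
correlate_sweep <- function(aggregated, x, y, p = NULL) {
  tbl <- aggregated
  if (!is.null(p)) tbl <- tbl[tbl$p == p, , drop = FALSE]
  resolve <- function(col) {
    if (col %in% names(tbl)) return(col)
    alt <- paste0(col, "_mean")
    if (alt %in% names(tbl)) return(alt)
    stop(sprintf("column '%s' not found in table", col), call. = FALSE)
  }
  xc <- resolve(x); yc <- resolve(y)
  tbl <- tbl[order(tbl$n), , drop = FALSE]
  ok <- is.finite(tbl[[xc]]) & is.finite(tbl[[yc]])
  series <- data.frame(n = tbl$n[ok], x = tbl[[xc]][ok], y = tbl[[yc]][ok])
  names(series)[2:3] <- c(x, y)
  if (nrow(series) < 3L)
    stop("need at least 3 conditions to correlate", call. = FALSE)
  sx <- stats::sd(series[[x]]); sy <- stats::sd(series[[y]])
  defined <- sx > 0 && sy > 0
  structure(
    list(series = series,
         pearson = if (defined) stats::cor(series[[x]], series[[y]]) else NA_real_,
         defined = defined,
         x_argmax_n = series$n[which.max(series[[x]])],
         x_argmin_n = series$n[which.min(series[[x]])],
         y_argmax_n = series$n[which.max(series[[y]])],
         y_argmin_n = series$n[which.min(series[[y]])]),
    class = "sweep_correlation")
}

#' @export
print.sweep_correlation <- function(x, ...) {
  nm <- names(x$series)
  cat(sprintf("<sweep_correlation> %s vs %s over %d thresholds: Pearson r = %s\n",
              nm[2], nm[3], nrow(x$series),
              if (x$defined) sprintf("%.4f", x$pearson) else "undefined (zero variance)"))
  cat(sprintf("  %s peaks at n = %g; %s peaks at n = %g\n",
              nm[2], x$x_argmax_n, nm[3], x$y_argmax_n))
  invisible(x)
}

#' Write a sweep or aggregate table as tab-separated text
#'
#' @param tbl a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a tab-separated sweep table
#'
#' @param path file written by \code{\link{write_sweep_table}}.
#' @return a data.frame.
#' @export
read_sweep_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
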