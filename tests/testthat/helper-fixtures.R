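# Small fixture builders used across test files.

# connectivity matrix from an upper-triangle edge list: edges is a data.frame
# (i, j, w); remaining entries are zero
cm_from_edges <- function(N, edges, subject_id = "fixture") {
  w <- matrix(0, N, N)
  for (k in seq_len(nrow(edges))) {
    w[edges$i[k], edges$j[k]] <- edges$w[k]
    w[edges$j[k], edges$i[k]] <- edges$w[k]
  }
  connectivity_matrix(w, subject_id = subject_id)
}

# thresholded network with hand-picked retained weights and cut-off
net_from_edges <- function(N, edges, w_t) {
  w <- matrix(0, N, N)
  for (k in seq_len(nrow(edges))) {
    w[edges$i[k], edges$j[k]] <- edges$w[k]
    w[edges$j[k], edges$i[k]] <- edges$w[k]
  }
  thresholded_network(w, list(w_t = w_t))
}

# the 3-node example network used in several worked cases:
# w12 = 0.6, w13 = -0.5, w23 = 0.3
net3 <- function(w_t) {
  net_from_edges(3, data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                               w = c(0.6, -0.5, 0.3)), w_t)
}

# symmetric random weight matrix as a connectivity_matrix
random_cm <- function(N, seed, lim = 1) {
  set.seed(seed)
  w <- matrix(stats::runif(N * N, -lim, lim), N, N)
  connectivity_matrix((w + t(w)) / 2, subject_id = sprintf("rand_%d", seed),
                      symmetrize_tol = Inf)
}

# adjacency-only network: unit weights on listed undirected edges
unit_net <- function(N, ij) {
  edges <- data.frame(i = ij[, 1], j = ij[, 2], w = 1)
  net_from_edges(N, edges, w_t = 0.5)
}
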