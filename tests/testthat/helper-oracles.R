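# Independent brute-force oracles. These deliberately use plain double loops
# and textbook formulas, never the package's vectorized code paths.

oracle_respond <- function(W, w_t, s) {
  N <- nrow(W)
  t_star <- max(w_t, 0)
  r <- integer(N)
  for (j in seq_len(N)) {
    acc <- 0
    for (i in seq_len(N)) if (i != j) acc <- acc + W[i, j] * s[i]
    r[j] <- if (acc > t_star) 1L else if (acc < -t_star) -1L else 0L
  }
  r
}

oracle_hopfield <- function(W, r) {
  N <- nrow(W)
  acc <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    if (i != j) acc <- acc + r[i] * W[i, j] * r[j]
  -acc
}

oracle_activity <- function(W, r) {
  N <- nrow(W)
  acc <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    if (i != j) acc <- acc + abs(r[i] * W[i, j] * r[j])
  acc
}

# direct-sum MI: sum p(s,r) log2 p(s,r) / (p(s) p(r))
oracle_mi <- function(joint) {
  total <- sum(joint)
  ps <- rowSums(joint) / total
  pr <- colSums(joint) / total
  acc <- 0
  for (a in 1:3) for (b in 1:3) {
    p <- joint[a, b] / total
    if (p > 0) acc <- acc + p * log2(p / (ps[a] * pr[b]))
  }
  acc
}

oracle_overlap <- function(ra, rb) {
  hits <- 0
  for (i in seq_along(ra)) if (ra[i] == rb[i]) hits <- hits + 1
  hits / length(ra)
}

# global transitivity by triple enumeration
oracle_transitivity <- function(adj) {
  N <- nrow(adj)
  triangles <- 0
  triples <- 0
  for (v in seq_len(N)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    triples <- triples + ncol(pairs)
    for (k in seq_len(ncol(pairs)))
      if (adj[pairs[1, k], pairs[2, k]] == 1) triangles <- triangles + 1
  }
  if (triples == 0) 0 else triangles / triples  # = 3*tri/conn.triples
}

# connected components by breadth-first search
oracle_largest_component <- function(adj) {
  N <- nrow(adj)
  seen <- rep(FALSE, N)
  best <- 0L
  for (start in seq_len(N)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; size <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1L
      nb <- which(adj[v, ] == 1 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best / N
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# all ternary states of length N as a 3^N x N matrix
all_ternary_states <- function(N) {
  m <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), N)))
  dimnames(m) <- NULL
  m
}
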