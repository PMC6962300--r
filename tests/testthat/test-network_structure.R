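test_that("largest-component fraction handles complete, empty and split graphs", {
  M <- random_cm(5, seed = 2)
  expect_equal(largest_component_fraction(apply_threshold(M, list(w_t = -1))), 1.0)
  expect_equal(largest_component_fraction(apply_threshold(M, list(w_t = 10))), 0.2)

  # two disjoint triangles on 6 nodes
  tri2 <- unit_net(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                            c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(largest_component_fraction(tri2), 0.5)
})

test_that("component sizes agree with a breadth-first-search oracle on random graphs", {
  for (seed in 1:8) {
    set.seed(seed)
    N <- 12
    adj <- matrix(0L, N, N)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, 0.12)
    adj <- adj + t(adj)
    net <- thresholded_network(adj * 0.9, list(w_t = 0.5))
    expect_equal(largest_component_fraction(net), oracle_largest_component(net$adjacency))
  }
})

test_that("transitivity matches closed forms and the triple-enumeration oracle", {
  expect_equal(clustering_coefficient(unit_net(3, rbind(c(1, 2), c(2, 3), c(1, 3)))), 1.0)
  star <- unit_net(5, cbind(1, 2:5))
  expect_equal(clustering_coefficient(star), 0.0)
  # triangle plus one pendant edge: 3 triangles-as-triples out of 5 triples
  tri_pendant <- unit_net(4, rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  expect_equal(clustering_coefficient(tri_pendant), 0.6)
  # no connected triples at all
  expect_equal(clustering_coefficient(unit_net(4, rbind(c(1, 2)))), 0)

  # exhaustive: all graphs on 4 nodes
  combos <- expand.grid(rep(list(0:1), 6))
  pairs <- utils::combn(4, 2)
  for (g in seq_len(nrow(combos))) {
    adj <- matrix(0L, 4, 4)
    for (e in 1:6) {
      adj[pairs[1, e], pairs[2, e]] <- combos[g, e]
      adj[pairs[2, e], pairs[1, e]] <- combos[g, e]
    }
    net <- thresholded_network(adj * 1.0, list(w_t = 0.5))
    expect_equal(clustering_coefficient(net), oracle_transitivity(net$adjacency))
  }
  # random graphs up to 7 nodes
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(5:7, 1)
    adj <- matrix(0L, N, N)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, 0.4)
    adj <- adj + t(adj)
    net <- thresholded_network(adj * 1.0, list(w_t = 0.5))
    expect_equal(clustering_coefficient(net), oracle_transitivity(net$adjacency))
  }
})

test_that("clustering differences subtract consecutive values along ascending thresholds", {
  expect_equal(clustering_differences(c(0.4, 0.4, 0.4)), c(0, 0))
  expect_equal(clustering_differences(c(0.5, 0.3, 0.3)), c(0.2, 0))
  expect_length(clustering_differences(runif(9)), 8)
  expect_error(clustering_differences(0.5), "at least two")
  expect_error(clustering_differences(c(0.5, 0.3), thresholds = c(1, 0)),
               "ascending")
  expect_error(clustering_differences(c(0.5, 0.3), thresholds = c(1, 2, 3)),
               "lengths differ")
})

test_that("node strengths are absolute retained-weight row sums", {
  M <- random_cm(6, seed = 3)
  empty <- apply_threshold(M, list(w_t = 10))
  expect_equal(node_strengths(empty), rep(0, 6))

  matching <- net_from_edges(4, data.frame(i = c(1, 3), j = c(2, 4),
                                           w = c(1, -1)), w_t = 0.5)
  expect_equal(node_strengths(matching), rep(1, 4))

  expect_equal(node_strengths(net3(w_t = 0)), c(1.1, 0.9, 0.8))
})

test_that("KS distance evaluates the two-sided empirical gap", {
  cdf <- function(x) pmin(pmax(x, 0), 1)  # Uniform(0, 1)
  # sample at the 0.25 / 0.75 quantiles: hand-evaluated step gap is 0.25
  expect_equal(ks_distance(c(0.25, 0.75), cdf), 0.25)

  # midpoint quantiles achieve the best-case bound 1/(2n)
  n <- 40
  expect_lte(ks_distance((seq_len(n) - 0.5) / n, cdf), 1 / (2 * n) + 1e-12)

  # sample entirely below the model support
  far <- function(x) ifelse(x < 100, 0, 1)
  expect_equal(ks_distance(sort(runif(50)), far), 1)

  expect_error(ks_distance(c(0.5, 0.2), cdf), "sorted")

  # agrees with stats::ks.test statistic on a random sample
  set.seed(6)
  x <- sort(rnorm(200))
  D_pkg <- ks_distance(x, function(q) pnorm(q))
  D_ref <- suppressWarnings(stats::ks.test(x, "pnorm")$statistic)
  expect_equal(unname(D_pkg), unname(D_ref))
})

test_that("the truncated power-law fit recovers generating parameters", {
  # uniform special case gamma = 0
  x0 <- sample_strengths(1e4, gamma = 0, ns_max = 5, ns_min = 1, seed = 2)
  f0 <- fit_strength_model(x0)
  expect_lt(abs(f0$gamma), 0.1)
  expect_lt(f0$ks_D, 0.02)

  x2 <- sample_strengths(1e4, gamma = 2, ns_max = 5, ns_min = 1, seed = 3)
  f2 <- fit_strength_model(x2)
  expect_gt(f2$gamma, 1.8)
  expect_lt(f2$gamma, 2.2)
  expect_gt(f2$ns_max, max(x2))

  # truncated power law beats the normal fit for gamma >= 1
  expect_lt(f2$ks_D, f2$ks_D_normal)

  expect_error(fit_strength_model(rep(1, 20)), "all strengths equal")
  expect_error(fit_strength_model(1:5), "at least 10")
})

test_that("fitted model CDF is self-consistent at its own quantiles", {
  x <- sample_strengths(2000, gamma = 1.5, ns_max = 4, ns_min = 0.5, seed = 8)
  fit <- fit_strength_model(x)
  # exact quantile sample of the fitted CDF: KS distance <= 1/n
  n <- 100
  probs <- (seq_len(n) - 0.5) / n
  ex <- fit$gamma + 1
  quantiles <- fit$ns_max - (fit$ns_max - fit$ns_min) * (1 - probs)^(1 / ex)
  expect_lte(ks_distance(sort(quantiles), fit$model_cdf), 1 / n)
})
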