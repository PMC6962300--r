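test_that("matrix files are ingested with diagonal zeroing and symmetrization", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 .5 .2", ".5 0 .1", ".2 .1 0"), path)
  M <- read_connectivity_matrix(path)
  expect_s3_class(M, "connectivity_matrix")
  expect_identical(M$N, 3L)
  expect_equal(M$weights[1, 2], 0.5)
  expect_equal(M$weights[2, 3], 0.1)
  expect_identical(M$subject_id, tools::file_path_sans_ext(basename(path)))

  # self-correlation diagonal is forced to zero
  writeLines(c("1 .5 .2", ".5 1 .1", ".2 .1 1"), path)
  expect_equal(diag(read_connectivity_matrix(path)$weights), rep(0, 3))

  # comma and tab dialects read the same grid
  writeLines(c("0, .5, .2", ".5, 0, .1", ".2, .1, 0"), path)
  expect_equal(read_connectivity_matrix(path, delimiter = "comma")$weights[1, 2], 0.5)
  writeLines(c("0\t.5\t.2", ".5\t0\t.1", ".2\t.1\t0"), path)
  expect_equal(read_connectivity_matrix(path, delimiter = "tab")$weights[1, 3], 0.2)
})

test_that("malformed grids are rejected with located errors; asymmetry only warns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 .5 .2 .9", ".5 0 .1 .9", ".2 .1 0 .9"), path)
  expect_error(read_connectivity_matrix(path), "non-square")

  writeLines(c("0 .5 .2", ".5 0 oops", ".2 .1 0"), path)
  expect_error(read_connectivity_matrix(path), "row 2, column 3")

  writeLines(c("0 .5 .2", ".9 0 .1", ".2 .1 0"), path)
  expect_warning(M <- read_connectivity_matrix(path), "asymmetric")
  expect_equal(M$weights[1, 2], 0.7)  # symmetrized by averaging
  expect_equal(M$weights, t(M$weights))
})

test_that("threshold follows w_t = <|w|> + n * sd(|w|) over off-diagonal entries", {
  # zero-variance case: every off-diagonal |w| = 0.5
  w <- matrix(0.5, 4, 4)
  M <- connectivity_matrix(w)
  spec <- compute_threshold(M, n = 2)
  expect_equal(spec$sd_abs_w, 0)
  expect_equal(spec$w_t, 0.5)

  # n = 0 returns the mean exactly, for any matrix
  M2 <- random_cm(12, seed = 4)
  spec0 <- compute_threshold(M2, n = 0)
  expect_identical(spec0$w_t, spec0$mean_abs_w)

  # direct arithmetic oracle on a crafted 3-node matrix
  M3 <- cm_from_edges(3, data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                    w = c(0.1, -0.2, 0.3)))
  av <- c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3)  # both triangles
  spec1 <- compute_threshold(M3, n = 1)
  expect_equal(spec1$mean_abs_w, mean(av))
  expect_equal(spec1$sd_abs_w, sd(av))
  expect_equal(spec1$w_t, mean(av) + sd(av))
})

test_that("thresholding retains strictly super-threshold signed weights", {
  M <- cm_from_edges(4, data.frame(i = c(1, 1, 1, 2, 2, 3),
                                   j = c(2, 3, 4, 3, 4, 4),
                                   w = c(0.9, -0.7, 0.4, 0.2, -0.1, 0.05)))
  # cut between 2nd and 3rd largest |w|: exactly 2 undirected edges survive
  net <- apply_threshold(M, list(w_t = 0.55, n = NA))
  expect_identical(sum(net$adjacency) / 2, 2)
  expect_equal(net$weights[1, 2], 0.9)
  expect_equal(net$weights[1, 3], -0.7)  # sign preserved
  expect_equal(net$weights[1, 4], 0)

  # ties at exactly w_t are dropped (strict inequality)
  net_tie <- apply_threshold(M, list(w_t = 0.4))
  expect_equal(net_tie$weights[1, 4], 0)

  # over-threshold: empty network
  net_hi <- apply_threshold(M, list(w_t = 10))
  expect_true(all(net_hi$adjacency == 0))
  expect_true(all(net_hi$weights == 0))

  # negative threshold retains everything non-zero, t* clamps to 0
  net_lo <- apply_threshold(M, list(w_t = -0.2))
  expect_identical(sum(net_lo$adjacency) / 2, 6)
  expect_identical(net_lo$t_star, 0)
})

test_that("edge sets shrink monotonically as the threshold rises", {
  for (seed in 1:5) {
    M <- random_cm(15, seed = seed)
    prev <- NULL
    for (n in seq(-1.5, 1.5, by = 0.25)) {
      net <- apply_threshold(M, compute_threshold(M, n))
      edges <- which(net$adjacency == 1)
      if (!is.null(prev)) expect_true(all(edges %in% prev))
      prev <- edges
    }
  }
})

test_that("write/read round-trips reproduce the weights", {
  M <- random_cm(9, seed = 21)
  path <- withr::local_tempfile(fileext = ".txt")
  write_connectivity_matrix(M, path, digits = 17)
  back <- read_connectivity_matrix(path)
  expect_lt(max(abs(back$weights - M$weights)), 1e-12)

  write_connectivity_matrix(M, path)  # default 9 significant digits
  back9 <- read_connectivity_matrix(path)
  expect_lt(max(abs(back9$weights - M$weights)), 1e-8)
})

test_that("node subsampling returns consistent, seed-deterministic submatrices", {
  M <- random_cm(20, seed = 9)
  full <- subsample_nodes(M, k = 20, seed = 1)
  expect_equal(full$weights, M$weights)

  sub <- subsample_nodes(M, k = 8, seed = 5)
  idx <- attr(sub, "nodes")
  expect_length(idx, 8)
  expect_equal(sub$weights, M$weights[idx, idx])
  expect_equal(sub$weights, t(sub$weights))

  sub2 <- subsample_nodes(M, k = 8, seed = 5)
  expect_identical(attr(sub2, "nodes"), idx)
  expect_equal(sub2$weights, sub$weights)

  expect_error(subsample_nodes(M, k = 1, seed = 1), "must be an integer")
  expect_error(subsample_nodes(M, k = 21, seed = 1), "must be an integer")
})
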