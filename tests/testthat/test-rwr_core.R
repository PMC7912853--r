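toy_n1 <- function() {
  # one sample, two layers: every block is the 1x1 matrix [1]
  layers <- list(matrix(1, 1, 1, dimnames = list("a", "a")),
                 matrix(1, 1, 1, dimnames = list("a", "a")))
  assemble_multiplex(layers, "RWRF")
}

test_that("transition matrix reproduces hand-computed blocks and is row-stochastic", {
  # n = 1, L = 2, lambda = (1/2, 1/2): W = [[1/2, 1/2], [1/2, 1/2]]
  w <- transition_matrix(toy_n1())
  expect_equal(unclass_attr(w), matrix(0.5, 2, 2), ignore_attr = TRUE)

  # RWRF inter block is lambda_2 * I
  layers <- random_layers(5, 2, seed = 1)
  mx <- assemble_multiplex(layers, "RWRF")
  w2 <- transition_matrix(mx, lambdas = c(0.5, 0.5))
  expect_equal(w2[1:5, 6:10], 0.5 * diag(5))
  # intra block is lambda_1 * row-normalized similarity
  expect_equal(w2[1:5, 1:5],
               0.5 * unclass_attr(layers[[1]]) / rowSums(layers[[1]]),
               ignore_attr = TRUE)

  # rows sum to one for random 8-node, 3-layer multiplexes, both variants
  for (variant in c("RWRF", "RWRNF")) {
    mx3 <- assemble_multiplex(random_layers(8, 3, seed = 2), variant,
                              m = 3, beta = 0.8)
    w3 <- transition_matrix(mx3)
    expect_lt(max(abs(rowSums(w3) - 1)), 1e-12)
    expect_true(all(w3 >= 0))
  }
})

test_that("initial distributions place the documented restart mass", {
  layers <- random_layers(6, 2, seed = 3)
  mx <- assemble_multiplex(layers, "RWRF")
  p0 <- initial_distribution(mx, 1, "s01")
  expect_equal(sum(p0), 1)
  expect_equal(p0[1], 0.5)       # seed node
  expect_equal(p0[7], 0.5)       # mirror node
  expect_equal(sum(p0 != 0), 2L)

  mxn <- assemble_multiplex(layers, "RWRNF", m = 2, beta = 0.5)
  p0n <- initial_distribution(mxn, 1, 1, alpha = 0.5)
  expect_equal(sum(p0n), 1)
  expect_equal(p0n[1], 0.5)
  # layer-2 block = 0.5 * coupling row: 0.25 on the mirror, 0.125 on each
  # of the two neighbor mirrors
  blk2 <- p0n[7:12]
  expect_equal(blk2[1], 0.25)
  expect_setequal(round(blk2[blk2 > 0], 10), c(0.25, 0.125))
  expect_equal(sum(blk2), 0.5)
})

test_that("gamma = 1 returns the restart vector as the fixed point", {
  mx <- assemble_multiplex(random_layers(5, 2, seed = 4), "RWRF")
  w <- transition_matrix(mx)
  p0 <- initial_distribution(mx, 1, 2)
  out <- rwr(w, p0, gamma = 1)
  expect_identical(out$p_stable, p0)
  expect_identical(rwr_direct(w, p0, gamma = 1), p0)
})

test_that("the doubly stochastic one-sample toy keeps the uniform fixed point", {
  w <- transition_matrix(toy_n1())
  for (g in c(0.3, 0.7, 0.9)) {
    out <- rwr(w, c(0.5, 0.5), gamma = g)
    expect_equal(out$p_stable, c(0.5, 0.5), tolerance = 1e-12)
  }
})

test_that("iterative RWR agrees with the direct linear solve", {
  for (i in 1:10) {
    n <- sample(4:10, 1)
    L <- sample(2:3, 1)
    variant <- sample(c("RWRF", "RWRNF"), 1)
    mx <- assemble_multiplex(random_layers(n, L, seed = 100 + i), variant,
                             m = min(3, n - 1), beta = 0.8)
    w <- transition_matrix(mx)
    p0 <- initial_distribution(mx, 1, 1)
    for (g in c(0.3, 0.7)) {
      it <- rwr(w, p0, gamma = g)
      direct <- rwr_direct(w, p0, gamma = g)
      expect_lt(max(abs(it$p_stable - direct)), 1e-8)
      expect_equal(sum(it$p_stable), 1, tolerance = 1e-12)
    }
  }
})

test_that("non-convergence raises an error carrying the residual", {
  mx <- assemble_multiplex(random_layers(6, 2, seed = 5), "RWRF")
  w <- transition_matrix(mx)
  p0 <- initial_distribution(mx, 1, 1)
  expect_error(rwr(w, p0, gamma = 0.1, max_iter = 2), "converge")
})

test_that("the one-sample toy fuses to exactly 0.5", {
  fz <- fuse_networks(toy_n1())
  expect_equal(unclass_attr(fz$s_fusion), matrix(0.5, 1, 1),
               ignore_attr = TRUE)
})

test_that("all-seed fusion equals looping rwr() seed by seed", {
  mx <- assemble_multiplex(random_layers(6, 2, seed = 6), "RWRNF",
                           m = 2, beta = 0.7)
  fz <- fuse_networks(mx)
  w <- transition_matrix(mx)
  for (seed_ix in c(1L, 4L, 9L)) {  # seeds in both layers
    j <- (seed_ix - 1L) %/% 6L + 1L
    x <- (seed_ix - 1L) %% 6L + 1L
    p0 <- initial_distribution(mx, j, x)
    ref <- rwr(w, p0)
    expect_identical(fz$iterations[seed_ix], ref$iterations)
    # row x of S'_j is the layer-j block of that seed's stationary vector
    # (matrix iteration vs per-seed matvec differ only in BLAS rounding)
    expect_equal(unname(fz$s_prime[[j]][x, ]),
                 ref$p_stable[(j - 1L) * 6L + 1:6], tolerance = 1e-13)
  }
})

test_that("fusion output satisfies its structural invariants", {
  mx <- assemble_multiplex(random_layers(7, 3, seed = 7), "RWRF")
  fz <- fuse_networks(mx)
  s <- fz$s_fusion
  expect_lt(max(abs(s - t(s))), 1e-12)
  expect_true(all(s >= 0))
  # each row of the assembled stationary profile sums to 1: the L blocks
  # of seed (j, x) live in row x of S'_j and of each cross block
  for (j in 1:3) {
    tot <- rowSums(fz$s_prime[[j]])
    for (l in setdiff(1:3, j)) tot <- tot + rowSums(fz$cross[[j]][[l]])
    expect_equal(unname(tot), rep(1, 7), tolerance = 1e-9)
  }
})

test_that("identical layers with equal weights give identical per-layer profiles", {
  s <- random_layers(6, 1, seed = 9)[[1]]
  mx <- assemble_multiplex(list(s, s), "RWRF")
  fz <- fuse_networks(mx)
  expect_lt(max(abs(fz$s_prime[[1]] - fz$s_prime[[2]])), 1e-10)
})

test_that("permuting layer order permutes profiles and preserves the fusion", {
  layers <- random_layers(5, 3, seed = 10)
  fz <- fuse_networks(assemble_multiplex(layers, "RWRF"))
  fz_p <- fuse_networks(assemble_multiplex(layers[c(2, 3, 1)], "RWRF"))
  expect_equal(fz_p$s_fusion, fz$s_fusion, tolerance = 1e-10)
  expect_equal(fz_p$s_prime[[1]], fz$s_prime[[2]], tolerance = 1e-10)
})

test_that("RWRNF with beta = 1 and matching seed weights reduces to RWRF", {
  layers <- random_layers(6, 2, seed = 11)
  f_rwrf <- fuse_networks(assemble_multiplex(layers, "RWRF"))
  f_red <- fuse_networks(assemble_multiplex(layers, "RWRNF", beta = 1),
                         alpha = 0.5)
  expect_lt(max(abs(f_rwrf$s_fusion - f_red$s_fusion)), 1e-10)
})
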