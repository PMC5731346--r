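test_that("mixing matrices are row-stochastic and degenerate cleanly", {
  pp <- population_params(20, theta0 = 0, s0 = 0, D = 0)
  W <- build_mixing_matrix(pp, c(0, 5, 10, 15), 4)
  expect_equal(unname(W), diag(4))        # releases hit distinct bins
  expect_equal(build_mixing_matrix(pp, 3, 1), matrix(1, 1, 1),
               ignore_attr = TRUE)
  pp2 <- population_params(22, 0.4, 0.07, 1e-3)
  W2 <- build_mixing_matrix(pp2, seq(0, 21, 3), 6)
  expect_equal(rowSums(W2), rep(1, 8), ignore_attr = TRUE)
  expect_true(all(W2 >= 0))
})

test_that("pool deconvolution solves identifiable systems exactly", {
  p <- deconvolve_pools(c(2, 4), sd = 1, W = diag(2), lambda = 0)
  expect_equal(p$pools, c(2, 4), tolerance = 1e-10)

  W <- matrix(c(0.5, 0.5, 0.25, 0.75), 2, byrow = TRUE)
  # exact linear-solve oracle: W %*% P = meas
  truth <- solve(W, c(3, 3.5))
  p2 <- deconvolve_pools(c(3, 3.5), sd = 0.1, W = W, lambda = 0)
  expect_equal(p2$pools, truth, tolerance = 1e-8)
  expect_equal(truth, c(2, 4))

  # constant measurements with any row-stochastic W admit constant pools
  W3 <- build_mixing_matrix(population_params(22, 0.4, 0.07, 1e-3),
                            seq(0, 21, 3), 6)
  p3 <- deconvolve_pools(rep(2.5, 8), sd = 0.1, W = W3, lambda = 0)
  expect_lt(p3$residual_norm, 1e-6)
})

test_that("unidentifiable bins error at lambda 0 and are flagged otherwise", {
  W <- cbind(matrix(runif(8), 4), 0)   # dead 3rd bin
  W <- W / rowSums(W)
  expect_error(deconvolve_pools(rep(1, 4), 0.1, W, lambda = 0),
               "unidentifiable")
  p <- deconvolve_pools(rep(1, 4), 0.1, W, lambda = 1)
  expect_identical(p$flagged, 3L)
  expect_true(is.finite(p$pools[3]))
})

test_that("MID deconvolution recovers bin signals in easy regimes", {
  # B = 1: output equals input
  arr <- array(0, dim = c(3, 2, 3))
  arr[, 1, ] <- matrix(rep(c(0.5, 0.3, 0.2), each = 3), 3)
  arr[, 2, ] <- matrix(rep(c(0.2, 0.3, 0.5), each = 3), 3)
  out <- deconvolve_mids(arr, matrix(1, 3, 1), pools = 2, sd = 0.01,
                         lambda = 0)
  expect_equal(out$mids[1, 1, ], c(0.5, 0.3, 0.2), tolerance = 1e-8)

  # identical MIDs in every bin: any W returns that MID
  W <- build_mixing_matrix(population_params(22, 0.4, 0.07, 1e-3),
                           seq(0, 21, 3), 4)
  arr2 <- array(rep(c(0.6, 0.3, 0.1), each = 8 * 2), dim = c(8, 2, 3))
  out2 <- deconvolve_mids(arr2, W, pools = rep(1, 4), sd = 0.01, lambda = 0)
  for (b in 1:4) {
    expect_equal(out2$mids[b, 1, ], c(0.6, 0.3, 0.1), tolerance = 1e-6)
  }

  # near-identity mixing with distinct bin MIDs: exact recovery
  Wn <- diag(2) * 0.96 + 0.02
  truthM <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.2, 0.7))
  arr3 <- array(NA_real_, dim = c(2, 1, 3))
  arr3[, 1, ] <- Wn %*% truthM
  out3 <- deconvolve_mids(arr3, Wn, pools = c(1, 1), sd = 0.01, lambda = 0)
  expect_equal(out3$mids[, 1, ], truthM, tolerance = 1e-6)
})

test_that("deconvolved MIDs are valid and converge to a common signal as
          lambda grows", {
  set.seed(5)
  W <- build_mixing_matrix(population_params(22, 0.4, 0.07, 1e-3),
                           seq(0, 21, 3), 4)
  truthM <- t(apply(matrix(runif(12), 4), 1, function(x) x / sum(x)))
  arr <- array(NA_real_, dim = c(8, 1, 3))
  arr[, 1, ] <- W %*% truthM
  out <- deconvolve_mids(arr, W, pools = rep(1, 4), sd = 0.01, lambda = 1e7)
  expect_equal(rowSums(out$mids[, 1, ]), rep(1, 4), tolerance = 1e-9)
  spread <- max(apply(out$mids[, 1, ], 2, function(x) diff(range(x))))
  expect_lt(spread, 1e-3)
  expect_true(all(out$mids >= 0))
})

test_that("forward model of a deconvolution reproduces noise-free data", {
  set.seed(11)
  W <- build_mixing_matrix(population_params(22, 0.4, 0.05, 8e-4),
                           seq(0, 21, 3), 6)
  pools <- runif(6, 1, 2)
  truthM <- t(apply(matrix(runif(18) + 0.2, 6), 1, function(x) x / sum(x)))
  wp <- W * rep(pools, each = 8)
  Aeff <- wp / rowSums(wp)
  arr <- array(NA_real_, dim = c(8, 1, 3))
  arr[, 1, ] <- Aeff %*% truthM
  out <- deconvolve_mids(arr, W, pools, sd = 0.01, lambda = 0)
  resid <- Aeff %*% out$mids[, 1, ] - arr[, 1, ]
  expect_lt(sqrt(sum(resid^2)), 1e-6)
})
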