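test_that("pure advection moves a point mass by t/T", {
  pp <- population_params(20, theta0 = 0, s0 = 0, D = 0)
  d <- evolve_density(pp, 5, 20)
  expect_equal(d$mass[6], 1)         # bin [0.25, 0.30)
  expect_equal(sum(d$mass), 1)
  d0 <- evolve_density(population_params(20, theta0 = 0.37), 0, 100)
  expect_equal(d0$mass[38], 1)       # point mass at theta0
})

test_that("long-time limits: uniform unweighted, 2^(1-theta) weighted", {
  pp <- population_params(20, theta0 = 0.3, s0 = 0.05, D = 0.002,
                          division_weighting = FALSE)
  d <- evolve_density(pp, 5000, 50)
  expect_lt(max(abs(d$mass - 1 / 50)), 1e-6)

  ppw <- population_params(20, theta0 = 0.3, s0 = 0.05, D = 0.002,
                           division_weighting = TRUE)
  dw <- evolve_density(ppw, 5000, 50)
  # division weighting gives the classical exponential-growth age structure
  # rho(theta) = 2^(1-theta) * ln 2
  edges <- seq(0, 1, length.out = 51)
  expected <- 2^(1 - edges[-51]) - 2^(1 - edges[-1])
  expected <- expected / sum(expected)
  expect_lt(max(abs(dw$mass - expected)), 1e-6)
})

test_that("phase fractions follow interval masses and stay normalized", {
  ph <- phase_definition()
  u <- evolve_density(population_params(20, 0, 0.3, 0.01,
                                        division_weighting = FALSE),
                      1e5, 200)
  expect_equal(unname(phase_fractions(u, ph)), c(0.4, 0.35, 0.25),
               tolerance = 1e-5)
  pt <- evolve_density(population_params(20, theta0 = 0.5), 0, 200)
  expect_equal(unname(phase_fractions(pt, ph)), c(0, 1, 0))
  r <- evolve_density(population_params(22, 0.1, 0.08, 0.001), 7, 48)
  expect_equal(sum(phase_fractions(r, ph)), 1, tolerance = 1e-9)
})

test_that("phase fractions are linear in the density", {
  ph <- phase_definition()
  d1 <- evolve_density(population_params(22, 0.2, 0.05, 0.001), 3, 60)
  d2 <- evolve_density(population_params(22, 0.6, 0.08, 0.002), 9, 60)
  mix <- d1
  mix$mass <- 0.3 * d1$mass + 0.7 * d2$mass
  expect_equal(phase_fractions(mix, ph),
               0.3 * phase_fractions(d1, ph) + 0.7 * phase_fractions(d2, ph),
               tolerance = 1e-12)
})

test_that("the circular mean advances by dt/T under pure advection", {
  pp <- population_params(25, theta0 = 0.1, s0 = 0.06, D = 0,
                          division_weighting = FALSE)
  mean_angle <- function(d) {
    Arg(sum(d$mass * exp(2i * pi * d$theta))) / (2 * pi)
  }
  m1 <- mean_angle(evolve_density(pp, 2, 300))
  m2 <- mean_angle(evolve_density(pp, 7, 300))
  expect_equal((m2 - m1) %% 1, 5 / 25, tolerance = 1e-6)
})

test_that("desynchronization parameters are recovered from phase fractions", {
  truth <- population_params(22, theta0 = 0.4, s0 = 0.05, D = 8e-4)
  ph <- phase_definition()
  tr <- seq(0, 21, by = 3)
  fr <- t(vapply(tr, function(t) {
    phase_fractions(evolve_density(truth, t, 240), ph)
  }, numeric(3)))
  obs <- cbind(data.frame(t_release_h = tr), as.data.frame(fr))
  fit <- fit_population_params(obs, ph, T_cycle = 22, n_starts = 10)
  expect_equal(fit$params$theta0, truth$theta0, tolerance = 1e-3)
  expect_equal(fit$params$s0, truth$s0, tolerance = 1e-3)
  expect_equal(fit$params$D, truth$D, tolerance = 1e-3 * truth$D + 1e-5)
  expect_lt(fit$ssr, 1e-10)

  expect_error(fit_population_params(obs[1:2, ], ph, T_cycle = 22),
               "at least 4")
})

test_that("cycle length is recovered within 10% from noisy fractions", {
  truth <- population_params(22, theta0 = 0.4, s0 = 0.05, D = 8e-4)
  ph <- phase_definition()
  tr <- seq(0, 21, by = 3)
  hits <- 0L
  for (s in 1:3) {
    set.seed(1000 + s)
    fr <- t(vapply(tr, function(t) {
      f <- phase_fractions(evolve_density(truth, t, 240), ph) +
        rnorm(3, 0, 0.02)
      pmax(f, 0) / sum(pmax(f, 0))
    }, numeric(3)))
    obs <- cbind(data.frame(t_release_h = tr), as.data.frame(fr))
    fit <- fit_population_params(obs, ph, T_cycle = NULL, n_starts = 12,
                                 seed = s)
    if (abs(fit$params$T_cycle - 22) / 22 < 0.10) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
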