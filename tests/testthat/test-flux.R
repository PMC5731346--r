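make_toy_obs <- function(net, fm, tracer, tau = c(0, 0.25, 0.5, 1, 2, 4),
                         targets = NULL, sd = 0.01, noise_sd = 0,
                         seed = NULL) {
  sim <- simulate_labeling(net, fm, tracer, tau, targets = targets)
  mids <- sim$mids
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mids <- lapply(mids, function(mm) {
      t(apply(mm + matrix(rnorm(length(mm), 0, noise_sd), nrow(mm)), 1,
              normalize_mid))
    })
  }
  flux_observation(tracer, tau, mids, sd = sd)
}

test_that("free-flux parameterization spans steady state structurally", {
  net <- read_network(default_network_path())
  fp <- flux_parameterization(net)
  expect_length(fp$free_ids, 7L)
  set.seed(9)
  for (i in 1:5) {
    vf <- runif(7, 0, 2)
    fm <- fp$to_fluxmap(vf)
    expect_identical(nrow(validate_steady_state(fm, net)), 0L)
  }
  truth <- default_tca_fluxmap()
  fm2 <- fp$to_fluxmap(truth$net[fp$free_ids])
  expect_equal(fm2$net[names(truth$net)], truth$net, tolerance = 1e-12)
})

test_that("a single-pool decay observation identifies the flux exactly", {
  net <- two_pool_chain(pool_b = 2)
  tr <- uniform_tracer("S", 2)
  # unlabeled fraction exp(-(v/C) tau) with v/C = 0.5
  obs <- make_toy_obs(net, flux_map(c(R1 = 1, R2 = 1)), tr,
                      targets = "B")
  fit <- fit_fluxes(net, obs, config = fit_config(n_starts = 4, seed = 1,
                                                  flux_ub = 5))
  expect_equal(unname(fit$fluxmap$net["R1"]), 1.0, tolerance = 1e-4)
  expect_lt(fit$ssr, 1e-10)
})

test_that("noise-free refitting recovers random admissible flux maps", {
  net <- branched_toy()
  tr <- uniform_tracer("S", 2)
  fp <- flux_parameterization(net)
  set.seed(31)
  for (i in 1:3) {
    vf <- runif(length(fp$free_ids), 0.2, 1.5)
    fm <- fp$to_fluxmap(vf)
    if (any(fm$net < 0)) next
    obs <- make_toy_obs(net, fm, tr, targets = c("A", "B"))
    fit <- fit_fluxes(net, obs, config = fit_config(n_starts = 4, seed = i,
                                                    flux_ub = 5))
    expect_lt(fit$ssr, 1e-8)
    expect_equal(fit$fluxmap$net[names(fm$net)], fm$net, tolerance = 1e-3)
  }
})

test_that("doubling sigma on duplicated observations halves the SSR", {
  net <- two_pool_chain()
  tr <- uniform_tracer("S", 2)
  fm <- flux_map(c(R1 = 1.3, R2 = 1.3))
  ob1 <- make_toy_obs(net, fm, tr, targets = "B", noise_sd = 0.01,
                      seed = 4, sd = 0.01)
  ob2 <- ob1
  ob2$sd <- 0.02
  cfg <- fit_config(n_starts = 3, seed = 2, flux_ub = 5)
  fit1 <- fit_fluxes(net, list(ob1), config = cfg)
  # duplicating every point while doubling sigma: same minimizer,
  # SSR scaled by 2 * (1/2)^2 = 1/2
  fit2 <- fit_fluxes(net, list(ob2, ob2), config = cfg)
  expect_equal(unname(fit2$fluxmap$net["R1"]),
               unname(fit1$fluxmap$net["R1"]), tolerance = 1e-5)
  expect_equal(fit2$ssr, 0.5 * fit1$ssr, tolerance = 1e-3)
})

test_that("an unmodeled observed metabolite raises an error", {
  net <- two_pool_chain()
  tr <- uniform_tracer("S", 2)
  obs <- flux_observation(tr, c(0, 1), list(Q = matrix(c(1, 0, 0), 2, 3,
                                                       byrow = TRUE)))
  expect_error(fit_fluxes(net, obs), "not in the network")
})

test_that("profile likelihood brackets the truth on noise-free data", {
  net <- branched_toy()
  tr <- uniform_tracer("S", 2)
  fm <- branched_toy_fluxmap()
  obs <- make_toy_obs(net, fm, tr, targets = c("A", "B"))
  fit <- fit_fluxes(net, obs, config = fit_config(n_starts = 3, seed = 5,
                                                  flux_ub = 5))
  for (fl in fit$free_ids) {
    ci <- profile_likelihood_ci(fit, fl)
    expect_lte(ci$lo, fm$net[fl] + 1e-6)
    expect_gte(ci$hi, fm$net[fl] - 1e-6)
    expect_true(ci$reliable)
  }
})

test_that("an unobservable branch flux has an open profile interval", {
  net <- branched_toy(extra_branch = TRUE)
  tr <- uniform_tracer("S", 2)
  fm <- branched_toy_fluxmap(extra_branch = TRUE)
  obs <- make_toy_obs(net, fm, tr, targets = c("A", "B"))
  fit <- fit_fluxes(net, obs, config = fit_config(n_starts = 3, seed = 6,
                                                  flux_ub = 5))
  ci <- profile_likelihood_ci(fit, "R6")
  expect_true(ci$open_hi)
  expect_equal(ci$lo, 0, tolerance = 1e-6)
})

test_that("raising the confidence level never shrinks the interval", {
  net <- branched_toy()
  tr <- uniform_tracer("S", 2)
  fm <- branched_toy_fluxmap()
  obs <- make_toy_obs(net, fm, tr, targets = c("A", "B"), noise_sd = 0.01,
                      seed = 8)
  fit <- fit_fluxes(net, obs, config = fit_config(n_starts = 3, seed = 7,
                                                  flux_ub = 5))
  ci90 <- profile_likelihood_ci(fit, "R2", level = 0.90)
  ci99 <- profile_likelihood_ci(fit, "R2", level = 0.99)
  expect_lte(ci99$lo, ci90$lo + 1e-9)
  expect_gte(ci99$hi, ci90$hi - 1e-9)
})

test_that("redox accounting is exactly linear with the documented yields", {
  acct <- data.frame(reaction = c("PDH", "IDH", "AKGDH", "MDH", "SDH"),
                     nadh = c(1, 1, 1, 1, 0),
                     fadh2 = c(0, 0, 0, 0, 1),
                     nadph = 0)
  v1 <- flux_map(c(PDH = 1, IDH = 1, AKGDH = 1, MDH = 1, SDH = 1))
  r1 <- compute_redox_oxphos(v1, acct)
  expect_equal(r1$nadh, 4)
  expect_equal(r1$fadh2, 1)
  expect_equal(r1$o2, 2.5)

  v0 <- flux_map(setNames(rep(0, 5), acct$reaction))
  r0 <- compute_redox_oxphos(v0, acct)
  expect_equal(unlist(r0[c("nadh", "fadh2", "o2")]), c(0, 0, 0),
               ignore_attr = TRUE)

  v2 <- v1; v2$net <- 2 * v2$net
  r2 <- compute_redox_oxphos(v2, acct)
  expect_equal(r2$nadh, 2 * r1$nadh)
  expect_equal(r2$o2, 2 * r1$o2)

  # additivity
  va <- v1; va$net <- c(PDH = 0.3, IDH = 0.1, AKGDH = 0.5, MDH = 0.2,
                        SDH = 0.4)
  vs <- v1; vs$net <- v1$net + va$net
  ra <- compute_redox_oxphos(va, acct)
  rs <- compute_redox_oxphos(vs, acct)
  expect_equal(rs$nadh, r1$nadh + ra$nadh, tolerance = 1e-12)

  expect_error(compute_redox_oxphos(flux_map(c(PDH = 1)), acct), "absent")
  neg <- data.frame(reaction = "PDH", nadh = -1, fadh2 = 0, nadph = 0)
  expect_error(compute_redox_oxphos(flux_map(c(PDH = 1)), neg), "negative")
})

test_that("oscillation summaries report amplitude and earliest-peak ties", {
  flat <- oscillation_summary(c(G1 = 1, S = 1, G2M = 1))
  expect_equal(flat$amplitude, 0)
  expect_identical(flat$peak, "G1")

  two <- oscillation_summary(c(G1 = 2, S = 4))
  expect_equal(two$amplitude, 2 / 3)
  expect_identical(two$peak, "S")

  a <- c(G1 = 1, S = 3, G2M = 2)
  perm <- a[c(2, 3, 1)]
  expect_equal(oscillation_summary(perm)$amplitude,
               oscillation_summary(a)$amplitude)
  expect_identical(oscillation_summary(perm)$peak, "S")

  expect_error(oscillation_summary(c(G1 = -2, S = 1)), "not positive")
})
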