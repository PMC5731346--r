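test_that("single-pool turnover follows the closed-form exponential", {
  net <- two_pool_chain(pool_b = 1)
  fm <- flux_map(c(R1 = 1, R2 = 1))
  tr <- uniform_tracer("S", 2)
  sim <- simulate_labeling(net, fm, tr, times = c(0, 1))
  expect_equal(unname(sim$mids$B[1, ]), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(unname(sim$mids$B[2, ]),
               c(exp(-1), 0, 1 - exp(-1)), tolerance = 1e-7)

  net2 <- two_pool_chain(pool_b = 2)
  sim2 <- simulate_labeling(net2, fm, tr, times = 2)
  expect_equal(unname(sim2$mids$B[1, 1]), exp(-1), tolerance = 1e-7)
})

test_that("EMU and brute-force engines agree on the default TCA network", {
  net <- read_network(default_network_path())
  fm <- default_tca_fluxmap()
  tt <- c(0, 0.25, 1, 4)
  for (src in c("Pyr.ext", "Gln")) {
    tr <- uniform_tracer(src, net$metabolites[[src]]$n_carbons)
    emu <- simulate_labeling(net, fm, tr, tt, rtol = 1e-10, atol = 1e-12)
    bf <- simulate_labeling_bruteforce(net, fm, tr, tt)
    expect_lt(max_mid_dev(emu, bf), 1e-8)
  }
})

test_that("engines agree on random toy networks with symmetry and dilution", {
  for (seed in c(101, 202)) {
    toy <- random_toy_network(seed)
    tt <- c(0, 0.5, 2)
    emu <- simulate_labeling(toy$net, toy$fluxmap, toy$tracer, tt,
                             rtol = 1e-10, atol = 1e-12)
    bf <- simulate_labeling_bruteforce(toy$net, toy$fluxmap, toy$tracer, tt)
    expect_lt(max_mid_dev(emu, bf), 1e-8)
  }
})

test_that("the compiled RK45 path matches the lsoda reference path", {
  net <- read_network(default_network_path())
  fm <- default_tca_fluxmap()
  tr <- uniform_tracer("Pyr.ext", 3)
  tt <- c(0, 0.5, 2)
  a <- simulate_labeling(net, fm, tr, tt, engine = "rk45")
  b <- simulate_labeling(net, fm, tr, tt, engine = "lsoda")
  expect_lt(max_mid_dev(a, b), 1e-7)
})

test_that("symmetric intermediates scramble positional fates", {
  net <- symmetric_fumarate_toy()
  fm <- flux_map(c(R1 = 1, R2 = 1, R3 = 1))
  # a 2-labeled source; downstream M sees both orientations through the
  # symmetric pool, so its two 2-carbon halves carry identical label
  tr <- tracer_spec(list(S = c(0, 0, 1, 0, 0)))
  ss_lo <- steady_state_mids(net, fm, tr,
                             emu = emu_decompose(net, list(
                               list(metabolite = "M", indices = 1:2))))
  ss_hi <- steady_state_mids(net, fm, tr,
                             emu = emu_decompose(net, list(
                               list(metabolite = "M", indices = 3:4))))
  expect_equal(ss_lo$M, ss_hi$M, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("steady state matches long integration and handles dilution", {
  net <- read_network(default_network_path())
  fm <- default_tca_fluxmap()
  tr <- uniform_tracer("Pyr.ext", 3)
  obs <- tca_observed()
  ss <- steady_state_mids(net, fm, tr, targets = obs)
  sim <- simulate_labeling(net, fm, tr, c(0, 200), targets = obs,
                           rtol = 1e-10, atol = 1e-12)
  for (m in obs) {
    expect_equal(unname(ss[[m]]), unname(sim$mids[[m]][2, ]),
                 tolerance = 1e-6)
  }

  dil <- parse_network(c(
    "met: S, 2, 1.0, source, 0.0",
    "met: B, 2, 1.0, balanced, 0.5",
    "met: B.snk, 2, 1.0, source, 0.0",
    "R1: S (ab) -> B (ab)",
    "R2: B (ab) -> B.snk (ab)"))
  ssd <- steady_state_mids(dil, flux_map(c(R1 = 1, R2 = 1)),
                           uniform_tracer("S", 2))
  expect_equal(unname(ssd$B[3]), 0.5, tolerance = 1e-9)

  dead <- parse_network(c(
    "met: S, 2, 1.0, source, 0.0",
    "met: B, 2, 1.0, balanced, 0.0",
    "met: B.snk, 2, 1.0, source, 0.0",
    "R1: S (ab) -> B (ab)",
    "R2: B (ab) -> B.snk (ab)"))
  expect_error(steady_state_mids(dead, flux_map(c(R1 = 0, R2 = 0)),
                                 uniform_tracer("S", 2)),
               "zero-turnover")
})

test_that("natural-abundance correction inverts the binomial convolution", {
  expect_equal(correct_natural_abundance(c(0.9893, 0.0107), 1),
               c(1, 0), tolerance = 1e-9)
  raw2 <- c(0.97871, 0.02117, 0.00011)
  raw2 <- raw2 / sum(raw2)
  expect_equal(correct_natural_abundance(raw2, 2), c(1, 0, 0),
               tolerance = 1e-4)
  mid <- c(0.2, 0.5, 0.3)
  expect_equal(correct_natural_abundance(mid, 2, p13 = 0), mid)
  # forward-convolution o correction = identity
  M <- natural_abundance_matrix(6, 0.0107)
  mid6 <- normalize_mid(runif(7))
  expect_equal(correct_natural_abundance(drop(M %*% mid6), 6), mid6,
               tolerance = 1e-10)
  expect_error(correct_natural_abundance(c(1, 0), 1, p13 = 0.2), "p13")
  expect_error(correct_natural_abundance(rep(1 / 22, 22), 21),
               "ill-conditioned")
})

test_that("returned MIDs are normalized and enrichment grows monotonically", {
  net <- linear_chain3()
  fm <- flux_map(c(R1 = 1, R2 = 1, R3 = 1, R4 = 1))
  tr <- uniform_tracer("S", 2)
  tt <- seq(0, 6, by = 0.5)
  sim <- simulate_labeling(net, fm, tr, tt)
  for (m in names(sim$mids)) {
    expect_equal(rowSums(sim$mids[[m]]), rep(1, length(tt)),
                 tolerance = 1e-6)
    enr <- apply(sim$mids[[m]], 1, mid_enrichment)
    expect_true(all(diff(enr) > -1e-9))
  }
})

test_that("trajectories are invariant under joint flux/pool scaling", {
  toy <- random_toy_network(77)
  tt <- c(0, 0.5, 2)
  base <- simulate_labeling(toy$net, toy$fluxmap, toy$tracer, tt)
  c_scale <- 3.7
  net2 <- toy$net
  for (m in names(net2$metabolites)) {
    net2$metabolites[[m]]$pool_size <- net2$metabolites[[m]]$pool_size *
      c_scale
  }
  fm2 <- toy$fluxmap
  fm2$net <- fm2$net * c_scale
  both <- simulate_labeling(net2, fm2, toy$tracer, tt)
  expect_lt(max_mid_dev(base, both), 1e-7)
  # scaling fluxes alone compresses time by the same factor
  fast <- simulate_labeling(toy$net, fm2, toy$tracer, tt / c_scale)
  expect_lt(max_mid_dev(base, fast), 1e-6)
})

test_that("brute force enforces its positional state-count cap", {
  m17 <- paste(letters[1:17], collapse = "")
  net <- parse_network(c(
    "met: S, 17, 1.0, source, 0.0",
    "met: Big, 17, 1.0, balanced, 0.0",
    "met: B.snk, 17, 1.0, source, 0.0",
    sprintf("R1: S (%s) -> Big (%s)", m17, m17),
    sprintf("R2: Big (%s) -> B.snk (%s)", m17, m17)))
  expect_error(simulate_labeling_bruteforce(net, flux_map(c(R1 = 1, R2 = 1)),
                                            uniform_tracer("S", 17),
                                            c(0, 1)),
               "exceeds the 1e5 cap")
})
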