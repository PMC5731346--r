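test_that("scenarios are constructed as designed", {
  expect_error(make_scenario("warburg"), "constant, oscillating")

  const <- make_scenario("constant")
  for (b in 2:const$B) {
    expect_equal(const$fluxmaps[[b]]$net, const$fluxmaps[[1]]$net)
  }

  osc <- make_scenario("oscillating")
  bp <- bin_phases(osc$B, osc$phases)
  expect_true(bp[which.max(osc$free_fluxes$PDH)] == "G1")
  expect_true(bp[which.max(osc$free_fluxes$GDH)] == "S")
  expect_true(bp[which.max(osc$free_fluxes$RC)] == "S")

  # total NAD(P)H production is identical across bins by construction
  acct <- read_redox_accounting()
  nadh <- vapply(osc$fluxmaps, function(f) {
    compute_redox_oxphos(f, acct)$nadh
  }, numeric(1))
  expect_lt(diff(range(nadh)), 1e-9)

  # every bin flux map is admissible
  net <- read_network(osc$network_path)
  for (fm in osc$fluxmaps) {
    expect_true(all(fm$net >= 0))
    expect_identical(nrow(validate_steady_state(fm, net)), 0L)
  }
})

test_that("generation is deterministic for a fixed seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  run_simulate("oscillating", d1, seed = 42)
  run_simulate("oscillating", d2, seed = 42)
  for (f in c("pools.csv", "mids.csv", "phase_fractions.csv",
              "truth_free_fluxes.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- file.path(tempdir(), "det3")
  run_simulate("oscillating", d3, seed = 43)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "mids.csv"))),
                         unname(tools::md5sum(file.path(d3, "mids.csv")))))
})

test_that("noise-free measurements of the constant scenario are
          release-invariant", {
  sc <- make_scenario("constant")
  sc$release_times <- c(0, 6, 12)
  ex <- generate_experiment(sc, noise = FALSE)
  m <- ex$measurements$mids
  for (tau in unique(m$tau_h)) {
    rows <- m[m$metabolite == "Cit" & m$tracer == "glc" & m$tau_h == tau, ]
    for (k in paste0("M", 0:6)) {
      expect_lt(diff(range(rows[[k]])), 1e-9)
    }
  }
})

test_that("noise-free measurements lie in the mixing model's row space", {
  sc <- make_scenario("oscillating")
  sc$release_times <- seq(0, 21, 7)
  ex <- generate_experiment(sc, noise = FALSE)
  W <- ex$truth$mixing_matrix
  for (m in c("Cit", "Glu")) {
    truthM <- ex$truth$mids$gln[[m]]      # B x tau x K
    Pb <- sc$pools[, m]
    wp <- W * rep(Pb, each = nrow(W))
    Aeff <- wp / rowSums(wp)
    meas <- tempoflux:::.read_mid_array(ex$measurements$mids, m, "gln")
    for (ri in seq_len(nrow(W))) {
      pred <- apply(truthM, c(2, 3), function(v) sum(Aeff[ri, ] * v))
      expect_lt(max(abs(pred - meas$arr[ri, , ])), 1e-10)
    }
  }
})

test_that("recovery scoring reports RMSE, coverage and peak agreement", {
  sc <- make_scenario("oscillating")
  ex <- generate_experiment(sc, noise = FALSE)
  truth <- ex$truth

  perfect <- evaluate_recovery(truth, list(
    pools = truth$pools,
    mids = truth$mids,
    peaks = list(PDH = "G1", RC = "S")),
    true_peaks = c(PDH = "G1", RC = "S"))
  expect_equal(perfect$pool_rmse_rel, 0)
  expect_equal(perfect$mid_rmse, 0)
  expect_true(all(perfect$peak_agreement))

  shifted <- truth$pools * 1.05
  r2 <- evaluate_recovery(truth, list(pools = shifted))
  expect_equal(r2$pool_rmse_rel, 0.05, tolerance = 1e-9)

  bad <- evaluate_recovery(truth, list(peaks = list(PDH = "S")),
                           true_peaks = c(PDH = "G1"))
  expect_false(bad$peak_agreement[["PDH"]])

  bp <- bin_phases(sc$B, sc$phases)
  ci <- data.frame(phase = c("G1", "S"), flux = c("PDH", "GDH"),
                   lo = c(0, 0), hi = c(10, 0.1))
  r3 <- evaluate_recovery(truth, list(flux_cis = ci))
  expect_equal(r3$ci_coverage, 0.5)

  expect_error(evaluate_recovery(truth, list(pools = truth$pools[1:2, ])),
               "shape mismatch")
})

test_that("mean deconvolution error does not decrease with noise", {
  sc <- make_scenario("oscillating")
  levels <- c(0.005, 0.02, 0.08)
  mean_err <- numeric(length(levels))
  for (li in seq_along(levels)) {
    errs <- c()
    for (s in 1:3) {
      sc$noise$mid_sd <- levels[li]
      sc$seed <- 100 + s
      ex <- generate_experiment(sc, noise = TRUE)
      W <- ex$truth$mixing_matrix
      ma <- tempoflux:::.read_mid_array(ex$measurements$mids, "Cit", "gln")
      dm <- deconvolve_mids(ma$arr, W, sc$pools[, "Cit"], sd = levels[li])
      errs <- c(errs, sqrt(mean((dm$mids - ex$truth$mids$gln$Cit)^2)))
    }
    mean_err[li] <- mean(errs)
  }
  expect_true(all(diff(mean_err) > 0))
})
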