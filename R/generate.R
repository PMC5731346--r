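#' Generate a complete synthetic pulse-chase experiment
#'
#' Simulates every position bin's labeling time course under its own flux
#' map and pools, mixes bins into population-averaged measurements through
#' the division-weighted population density at each release time (frozen
#' over the short chase), adds measurement noise, and returns the
#' measurements together with the ground truth.
#'
#' @param config A `scenario_config` from [make_scenario()].
#' @param noise Apply the config's noise model (default `TRUE`); `FALSE`
#'   yields noise-free measurements.
#' @return An `experiment` list:
#' \describe{
#'   \item{measurements}{`pools`: data frame `t_release_h, metabolite,
#'     pool_size, pool_sd`; `mids`: data frame `tracer, t_release_h, tau_h,
#'     metabolite, M0..Mn, sd`; `phase_fractions`: data frame
#'     `t_release_h, frac_<phase>`.}
#'   \item{truth}{bin flux maps, free-flux table, bin pools, bin MID arrays
#'     per tracer/metabolite (`B x tau x channels`), mixing matrix,
#'     densities, phase labels per bin.}
#'   \item{config}{the input config.}
#' }
#' @export
generate_experiment <- function(config, noise = TRUE) {
  set.seed(config$seed)
  net <- read_network(config$network_path)
  B <- config$B
  obs <- config$observed
  tau <- config$chase_times
  rel <- config$release_times
  nc <- vapply(obs, function(m) net$metabolites[[m]]$n_carbons, integer(1))

  emu <- emu_decompose(net, obs)

  # per-bin labeling truth: truth_mids[[tracer]][[met]] = B x tau x (n+1)
  truth_mids <- list()
  for (trn in names(config$tracers)) {
    arrs <- lapply(obs, function(m) {
      array(NA_real_, dim = c(B, length(tau), nc[[m]] + 1L))
    })
    names(arrs) <- obs
    for (b in seq_len(B)) {
      netb <- net
      for (m in colnames(config$pools)) {
        netb$metabolites[[m]]$pool_size <- config$pools[b, m]
      }
      if (nrow(validate_steady_state(config$fluxmaps[[b]], netb)) > 0) {
        stop("bin ", b, " flux map violates steady state")
      }
      sim <- simulate_labeling(netb, config$fluxmaps[[b]],
                               config$tracers[[trn]], tau, emu = emu)
      for (m in obs) arrs[[m]][b, , ] <- sim$mids[[m]]
    }
    truth_mids[[trn]] <- arrs
  }

  W <- build_mixing_matrix(config$population, rel, B)
  densities <- lapply(rel, function(t) {
    evolve_density(config$population, t, B)
  })

  # population-averaged pools: every chase sample of every release window
  # yields an independent pool measurement (the pool is constant over the
  # short chase; each LC-MS run measures it again)
  pool_rows <- list()
  for (m in obs) {
    Pb <- config$pools[, m]
    true_pool <- drop(W %*% Pb)
    for (ri in seq_along(rel)) {
      meas <- rep(true_pool[ri], length(tau))
      sd_m <- config$noise$pool_rel_sd * meas
      if (noise && config$noise$pool_rel_sd > 0) {
        meas <- meas * rlnorm(length(meas),
                              -config$noise$pool_rel_sd^2 / 2,
                              config$noise$pool_rel_sd)
      }
      pool_rows[[length(pool_rows) + 1L]] <- data.frame(
        t_release_h = rel[ri], tau_h = tau, metabolite = m,
        pool_size = meas, pool_sd = sd_m, stringsAsFactors = FALSE)
    }
  }
  pools_df <- do.call(rbind, unname(pool_rows))

  # population-averaged MIDs (channels padded to the widest metabolite)
  kmax <- max(nc)
  mid_rows <- list()
  for (trn in names(config$tracers)) {
    for (m in obs) {
      Pb <- config$pools[, m]
      wp <- W * rep(Pb, each = nrow(W))
      Aeff <- wp / rowSums(wp)
      for (ri in seq_along(rel)) {
        mix <- t(Aeff[ri, , drop = FALSE] %*%
                   matrix(truth_mids[[trn]][[m]], nrow = B))
        mix <- matrix(mix, nrow = length(tau))
        if (noise && config$noise$mid_sd > 0) {
          mix <- mix + matrix(rnorm(length(mix), 0, config$noise$mid_sd),
                              nrow = nrow(mix))
          mix <- t(apply(mix, 1, normalize_mid))
        }
        pad <- matrix(NA_real_, length(tau), kmax - nc[[m]])
        mix <- cbind(mix, pad)
        df <- data.frame(tracer = trn, t_release_h = rel[ri], tau_h = tau,
                         metabolite = m, stringsAsFactors = FALSE)
        colnames(mix) <- paste0("M", 0:kmax)
        mid_rows[[length(mid_rows) + 1L]] <- cbind(
          df, as.data.frame(mix), sd = config$noise$mid_sd)
      }
    }
  }
  mids_df <- do.call(rbind, unname(mid_rows))

  # observed phase fractions, evaluated on a fine position grid (the
  # flow-cytometry readout resolves phases, not the analysis bins)
  fr <- t(vapply(rel, function(t) {
    phase_fractions(evolve_density(config$population, t, 240L),
                    config$phases)
  }, numeric(nrow(config$phases))))
  if (noise && config$noise$frac_sd > 0) {
    fr <- fr + matrix(rnorm(length(fr), 0, config$noise$frac_sd), nrow(fr))
    fr <- t(apply(fr, 1, function(x) pmax(x, 0) / sum(pmax(x, 0))))
  }
  frac_df <- data.frame(t_release_h = rel)
  for (i in seq_len(nrow(config$phases))) {
    frac_df[[paste0("frac_", config$phases$phase[i])]] <- fr[, i]
  }

  structure(list(
    measurements = list(pools = pools_df, mids = mids_df,
                        phase_fractions = frac_df),
    truth = list(fluxmaps = config$fluxmaps,
                 free_fluxes = config$free_fluxes,
                 pools = config$pools, mids = truth_mids,
                 mixing_matrix = W, densities = densities,
                 bin_phase = bin_phases(B, config$phases)),
    config = config), class = "experiment")
}

#' Score pipeline outputs against the generating ground truth
#'
#' @param truth The `truth` element of [generate_experiment()] output.
#' @param outputs List with any of: `pools` (matrix/data frame of per-bin
#'   pools, metabolite columns), `mids` (per-tracer, per-metabolite arrays
#'   matching the truth layout), `flux_cis` (data frame `phase, flux, lo,
#'   hi` of confidence intervals on free fluxes), `peaks` (named list of
#'   peak phases per summarized flux).
#' @param true_peaks Named character vector of expected peak phases (only
#'   used when `outputs$peaks` is given).
#' @return A `recovery_report` list with `pool_rmse_rel`, `mid_rmse`,
#'   `ci_coverage`, and `peak_agreement` (those computable from `outputs`).
#' @export
evaluate_recovery <- function(truth, outputs, true_peaks = NULL) {
  rep <- list()
  if (!is.null(outputs$pools)) {
    est <- as.matrix(outputs$pools)
    tru <- truth$pools[, colnames(est), drop = FALSE]
    if (!all(dim(est) == dim(tru))) stop("pool estimate shape mismatch")
    rep$pool_rmse_rel <- sqrt(mean(((est - tru) / tru)^2))
  }
  if (!is.null(outputs$mids)) {
    devs <- c()
    for (trn in names(outputs$mids)) {
      for (m in names(outputs$mids[[trn]])) {
        est <- outputs$mids[[trn]][[m]]
        tru <- truth$mids[[trn]][[m]]
        if (!all(dim(est) == dim(tru))) stop("MID estimate shape mismatch")
        devs <- c(devs, as.numeric(est - tru))
      }
    }
    rep$mid_rmse <- sqrt(mean(devs^2))
  }
  if (!is.null(outputs$flux_cis)) {
    ci <- outputs$flux_cis
    covered <- logical(nrow(ci))
    for (i in seq_len(nrow(ci))) {
      b <- which(truth$bin_phase == ci$phase[i])
      tv <- mean(truth$free_fluxes[[ci$flux[i]]][b])
      covered[i] <- ci$lo[i] <= tv && tv <= ci$hi[i]
    }
    rep$ci_coverage <- mean(covered)
  }
  if (!is.null(outputs$peaks)) {
    if (is.null(true_peaks)) stop("true_peaks required to score peaks")
    rep$peak_agreement <- vapply(names(outputs$peaks), function(f) {
      identical(outputs$peaks[[f]], unname(true_peaks[[f]]))
    }, logical(1))
  }
  structure(rep, class = "recovery_report")
}
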