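#!/usr/bin/env Rscript
# Score the analysis output against the generator's ground truth and render
# the human-readable reports.
#
# Usage: Rscript analysis/03_recovery_report.R [scenario ...]

library(tempoflux)

args <- commandArgs(trailingOnly = TRUE)
scenarios <- if (length(args)) args else c("constant", "oscillating")

for (scenario in scenarios) {
  rd <- file.path("results", "analysis", scenario)
  if (!file.exists(file.path(rd, "results.json"))) {
    stop("missing ", rd, "; run analysis/02_deconvolve_and_fit.R first")
  }
  cat("==", scenario, "==\n")

  # rebuild truth (deterministic from the dataset's manifest seed)
  mani <- yaml::read_yaml(file.path("results", "datasets", scenario,
                                    "manifest.yaml"))
  sc <- make_scenario(scenario, seed = mani$seed)
  ex <- generate_experiment(sc, noise = mani$noise)
  res <- jsonlite::read_json(file.path(rd, "results.json"),
                             simplifyVector = TRUE)

  bin_pools <- read.csv(file.path(rd, "bin_pools.csv"))
  est <- as.matrix(bin_pools[, colnames(sc$pools)[colnames(sc$pools) %in%
                                                    names(bin_pools)]])
  rec <- evaluate_recovery(ex$truth, list(pools = est))
  cat(sprintf("  per-bin pool relative RMSE: %.3f\n", rec$pool_rmse_rel))

  if (!is.null(res$flux_cis) && length(res$flux_cis)) {
    ci <- as.data.frame(res$flux_cis)
    rec_ci <- evaluate_recovery(ex$truth, list(flux_cis = ci))
    cat(sprintf("  CI coverage over %d profiled fluxes: %.2f\n",
                nrow(ci), rec_ci$ci_coverage))
  }

  peaks <- lapply(res$oscillations, `[[`, "peak")
  if (scenario == "oscillating") {
    rec_pk <- evaluate_recovery(ex$truth,
                                list(peaks = peaks[c("PDH", "GDH", "RC")]),
                                true_peaks = c(PDH = "G1", GDH = "S",
                                               RC = "S"))
    cat("  peak-phase agreement:",
        paste(names(rec_pk$peak_agreement), rec_pk$peak_agreement,
              collapse = ", "), "\n")
  }

  run_report(rd)
  cat("  report:", file.path(rd, "report.md"), "\n")
}
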