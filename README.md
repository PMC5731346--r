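# tempoflux

Cell-cycle-resolved metabolic flux analysis from pulse-chase 13C isotope
tracing in synchronized cell populations.

## The problem

Metabolic demands change through the division cycle, but every LC-MS
measurement on a cell population averages over cell-cycle positions — and a
synchronized culture desynchronizes within one cycle, so sampling at
successive release times sweeps a *moving, broadening mixture* of
cell-cycle states past the instrument. `tempoflux` turns such measurements
into phase-specific fluxes:

1. **Population model.** The distribution of cells over cycle position
   `theta` on the unit circle is a wrapped Gaussian that advects by `t/T`
   and broadens as `s0^2 + 2 D t`, with division weighting (lineages past
   division count twice). Its parameters are fitted to flow-cytometry
   phase fractions.
2. **Deconvolution.** Population-averaged pool sizes and mass-isotopomer
   distributions (MIDs) are unmixed into position-bin-specific values by
   non-negative least squares through the mixing matrix
   `meas_r = sum_b W_rb P_b M_b / sum_b W_rb P_b`, with a circular
   smoothness penalty whose weight is chosen by Stein's unbiased risk
   estimate.
3. **Isotopically non-stationary MFA.** Phase-specific TCA fluxes are
   fitted to the labeling kinetics
   `d(C X)/dt = sum_in v_in X_in - (sum_out v_out) X`, simulated on the
   elementary-metabolite-unit (EMU) decomposition of an atom-mapped
   network, with free fluxes parameterized on the stoichiometric null
   space, simultaneous fitting of [U-13C]glucose-like and
   [U-13C]glutamine-like tracers, and profile-likelihood 95% confidence
   intervals (`SSR_min + 3.841` threshold).
4. **Derived rates.** Linear accounting of NAD(P)H and FADH2 production
   and the oxygen-equivalent OxPhos rate `(NADH + FADH2)/2`, plus
   oscillation summaries (relative amplitude `(max - min)/mean`, peak
   phase) per flux.

A synthetic-data generator (`make_scenario()`, `generate_experiment()`)
produces complete pulse-chase experiments with known ground truth — bin
fluxes, pools, MIDs, mixing matrix — so the whole chain is testable without
instrument data. A brute-force positional-isotopomer simulator serves as an
independent oracle for the EMU engine.

## Worked example

Simulate the shipped "oscillating" scenario — glucose oxidation peaking in
G1, glutamine-derived oxidative and reductive flux peaking in S, total
NAD(P)H production constant across bins by construction — and analyze it:

```r
library(tempoflux)
run_simulate("oscillating", "results/datasets/oscillating", seed = 1)
res <- run_analyze("results/datasets/oscillating",
                   "results/analysis/oscillating",
                   fit = fit_config(n_starts = 4, seed = 1), seed = 1)
for (q in c("PDH", "GDH", "RC", "NADH")) {
  cat(q, round(res$oscillations[[q]]$amplitude, 3),
      res$oscillations[[q]]$peak, "\n")
}
```

```
PDH 0.418 G1
GDH 0.488 S
RC 0.859 S
NADH 0.056 S
```

Reading: the fitted glucose-oxidation flux (PDH) oscillates with relative
amplitude 0.42 and peaks in G1; glutamine oxidation (GDH) and reductive
carboxylation (RC) peak in S; and the total NAD(P)H production rate is
nearly flat (amplitude 0.056) even though the fluxes feeding it swing by
40–90% — the complementary oscillation the scenario was built to show. The
per-phase flux maps behind these summaries are in
`res$phase_fluxmaps` (e.g. PDH 1.30 / 0.91 / 0.87 across G1 / S / G2M for
this seed), per-bin pools and MIDs in `res$bin_pools` / `res$bin_mids`,
and `run_report()` renders a markdown summary with the
profile-likelihood confidence intervals.

The numbered drivers under `analysis/` run the same workflow for all three
scenarios and score the recovery against the generator's ground truth:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_deconvolve_and_fit.R 1
Rscript analysis/03_recovery_report.R
```

## Layout

- `R/`, `src/` — package code (network parser, EMU decomposition, labeling
  simulators, population model, deconvolution, flux fitting, scenarios,
  pipeline).
- `inst/extdata/` — default atom-mapped TCA network and redox accounting
  table (both plain text, both user-replaceable).
- `analysis/` — numbered workflow drivers.
- `vignettes/temporal-fluxomics-methods.Rmd` — the methods notes: model
  assumptions, numerical choices, what the generator does and does not
  emulate, and known limitations.
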