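---
title: "Methods: cell-cycle-resolved metabolic flux analysis from pulse-chase tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle-resolved metabolic flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Metabolic fluxes change as cells traverse the division cycle, but any
measurement on a cell population averages over cell-cycle positions. Even a
chemically synchronized culture desynchronizes within one cycle, so a
time series of LC-MS measurements taken after release is a *moving,
broadening mixture* of cell-cycle states, not a clean sweep through them.
`tempoflux` implements the computational half of a temporal-fluxomics
experiment on such populations:

1. model the population's distribution over cell-cycle position as it
   advects and broadens after release;
2. deconvolve population-averaged metabolite pool sizes and mass-isotopomer
   distributions (MIDs) from pulse-chase 13C-tracing measurements into
   position-bin-specific values;
3. estimate phase-specific TCA-cycle fluxes from the labeling kinetics by
   isotopically non-stationary metabolic flux analysis (MFA), with
   profile-likelihood confidence intervals;
4. derive NAD(P)H/FADH2 production and oxygen-equivalent oxidative
   phosphorylation rates, and summarize how each flux oscillates over the
   cycle.

A synthetic-data generator with complete ground truth stands in for the
LC-MS instrument, so every stage is testable end to end.

# Labeling kinetics

## Model

Metabolism is assumed to be at *metabolic* steady state within each
analysis window (fluxes `v` and pool sizes `C` constant while a tracer is
chased), while the *isotopic* state is transient. For each metabolite pool
the mass-isotopomer fractions `X` obey

```
d(C * X)/dt = sum_in v_in * X_in  -  (sum_out v_out) * X
```

where the influx MID `X_in` is determined by the producing reaction's atom
map — a convolution of substrate-fragment MIDs for condensation reactions
such as citrate synthase. A per-metabolite `dilution_fraction` mixes
unlabeled material into the influx (exchange with an unlabeled sink).

The simulator works on the elementary-metabolite-unit (EMU) decomposition
of the atom-mapped network: backward-tracing the atom maps from the
observed fragments yields the minimal set of carbon subsets whose mass
distributions close under the dynamics, typically orders of magnitude
smaller than the full positional-isotopomer space. A brute-force simulator
that integrates the complete `2^n` positional-isotopomer system directly
from the atom maps ships alongside as an independent oracle; the test suite
requires the two engines to agree to `1e-8` on the default TCA network
(both tracers) and on randomized toy networks with scrambling symmetry and
dilution.

Two conventions matter for reproducing results:

* **Symmetric metabolites.** Succinate and fumarate are two-fold
  rotationally symmetric; the parser expands every reaction *consuming* a
  `symmetric`-flagged metabolite into two half-weighted variants with the
  carbon map reversed, which scrambles downstream positional fates exactly.
* **Source labeling.** Externally fixed sources (tracers) are treated as
  positionally exchangeable given their MID. This is exact for the
  uniformly labeled (`[U-13C]`) tracers used here and for unlabeled
  material; both engines share the convention.

## Numerics

The production integrator is an adaptive Dormand-Prince RK45 in compiled
code with relative tolerance `1e-8` and absolute tolerance `1e-10`. An
implicit stiff scheme is unnecessary here: rate constants `v/C` in the
default network span roughly two orders of magnitude, well within an
explicit method's comfort zone, and a stiff-capable `deSolve::lsoda` path
(`engine = "lsoda"`) integrates the identical right-hand side as a
cross-check (the suite holds the two to `1e-7`). The brute-force oracle
always uses `lsoda` at `1e-10`/`1e-12`, keeping the two code paths
independent down to the integrator.

Isotopic steady state is solved algebraically, size class by size class:
convolution inputs always involve strictly smaller EMUs, so each class is a
linear system. A zero-turnover pool makes the system singular and is
reported as an error naming the metabolite.

Natural-abundance correction inverts the binomial convolution
`observed_shift = tracer_shift + Binomial(n - shift, p13)` with
`p13 = 0.0107` by default; it is applied to measurements only — simulations
live in corrected space.

# The default TCA network

The shipped network (`default_network_path()`) is a single-compartment TCA
cycle: a glycolytic pyruvate source, PDH, pyruvate carboxylase, citrate
synthase, oxidative citrate → alpha-ketoglutarate → succinate flow with CO2
release, reductive carboxylation (alpha-KG + CO2 → citrate, the reverse IDH
mapping), glutamine → glutamate → alpha-KG anaplerosis, the symmetric
succinate → fumarate → malate → OAA arm, ATP-citrate-lyase-style citrate
cleavage, and efflux reactions to biosynthetic sinks. CO2 is an explicit
1-carbon source/sink, never balanced and unlabeled unless a tracer says
otherwise. Pool sizes are per-cell amounts in arbitrary units; only ratios
`v/C` enter the kinetics. Compartmentation (cytosolic vs mitochondrial
pools) is deliberately out of scope — the network file format accepts any
refinement.

# Population model and deconvolution

## Desynchronization

Cell-cycle position `theta` lives on the unit circle. A synchronized
population released at mean position `theta0` with spread `s0` evolves as a
wrapped Gaussian with mean `theta0 + t/T` and variance `s0^2 + 2 D t`
(advection-diffusion). With division weighting on (the default), lineage
mass doubles at each wrap past division — population measurements weight
cells, and a divided lineage is two cells. Two consequences the tests pin
down: without weighting the long-time limit is uniform; with weighting it
is the classical exponential-growth age structure `2^(1-theta) ln 2`.

The model's parameters are fitted to flow-cytometry-style phase-fraction
time courses by bounded multistart least squares (`fit_population_params`);
the cycle length can be fixed (default 22 h in the analyses here) or
co-fitted.

## Mixing and deconvolution

Row `r` of the mixing matrix `W` holds the population mass per position bin
at release time `t_r` (frozen over the short chase; chase times are at most
4 h against a 22 h cycle). Population measurements then obey

* pools: `meas_r = sum_b W_rb P_b`
* MIDs: `meas_r = sum_b W_rb P_b M_b / sum_b W_rb P_b` (abundance
  weighting),

and deconvolution inverts these as non-negative least squares with a
circular Tikhonov penalty across neighboring bins (adjacent cell-cycle
positions have similar metabolic states; position is a circle, so the
penalty wraps). MIDs additionally carry a per-bin unit-sum constraint and
are projected exactly onto the simplex afterwards.

The smoothing weight is explicit and configurable. When not given, it is
chosen by minimizing Stein's unbiased risk estimate (`resid^2 + 2 edof`,
valid because the measurement sds are known). We found the classical
L-curve corner (still available as `method = "lcurve"`) unstable on these
small systems, and the Morozov discrepancy target degenerate when the
parameter count is a sizable fraction of the data count; both observations
drove the SURE default. Pool deconvolution uses every chase sample of every
release window as an independent pool measurement — the pool is constant
over the chase, each LC-MS run re-measures it.

Linear error propagation through the regularized solve yields per-bin,
per-channel sds of the deconvolved MIDs; the flux fits weight by these
(floored at the raw measurement sd, since the propagation cannot see
smoothing bias). Bins with no mixing support are flagged and filled by
neighbor interpolation rather than silently extrapolated.

# Flux estimation

## Parameterization and fitting

Free fluxes are a QR-pivoted basis of the balanced stoichiometric matrix's
null space: any free-flux assignment determines all dependent net fluxes,
so every candidate satisfies steady state structurally; negative dependent
fluxes are penalized rather than projected. Reversible reactions are
parameterized as net + exchange with the exchange flux log-scaled and
bounded by 100x the flux upper bound. Fitting minimizes
`SSR = sum(((sim - meas)/sd)^2)` by bounded Levenberg-Marquardt
(`minpack.lm`) from multiple seeded starts (default 20; the analyses here
use 4, which the noise-free refit shows is ample for this network),
simultaneously across tracers, with all randomness flowing from one root
seed.

The pipeline estimates phase fluxes in two stages. Stage one fits one flux
map per phase to the deconvolved bin MIDs of that phase's bins jointly
(each bin keeps its own pools). Stage two — the default final estimator —
re-fits *per-bin* flux maps directly against the raw population-averaged
MIDs by forward simulation through the mixing model, warm-started from
stage one, with a circular smoothness penalty tying neighboring bins'
free fluxes together. The refinement exists because deconvolved MIDs carry
errors that are strongly correlated across chase times and bins (the same
mixing-matrix row error touches every sample of a release window); fitting
them as if independent biases weakly identified fluxes, which we observed
most acutely for reductive carboxylation. The population MIDs, by
contrast, carry independent measurement noise, so the forward-model fit is
correctly specified. Phase values are reported as abundance-weighted means
over the phase's bins.

## Confidence intervals

Profile-likelihood intervals walk a named net flux away from its optimum,
re-optimizing all other parameters at each value (the profiled flux is held
by a stiff linear constraint penalty, so dependent fluxes can be profiled
too), until the re-optimized SSR crosses `SSR_min + 3.841` (the 95%
chi-square threshold with one degree of freedom), then refine the crossing
by bisection to `1e-3 * |fitted|`. A direction that never crosses before
its bound is reported open; a failed re-optimization marks the interval
unreliable instead of silently widening it. Coverage is checked by
simulation: 50 noisy replicates on a compact branched network, requiring
the true flux inside the 95% interval at least 42 times.

## Redox and oscillation summaries

Reducing-equivalent production is linear accounting over the fitted net
fluxes with an editable YAML yield table (default: PDH, AKGDH, MDH → 1
NADH; IDH → 1 NADPH; SDH → 1 FADH2; reductive carboxylation → −1 NADPH).
NADPH is merged into the NADH total by default (`merge_nadph = FALSE`
separates it and excludes it from oxidative phosphorylation). The
oxygen-equivalent OxPhos rate is `(NADH + FADH2)/2`. Oscillation summaries
report the relative amplitude `(max − min)/mean` over phases and the peak
phase, ties resolving to the earliest phase in cycle order.

# The synthetic-data generator

`make_scenario()` fixes the full experimental design: the default TCA
network; 8 release times over one 22 h cycle; chase times 0, 0.25, 0.5, 1,
2, 4 h; B = 6 position bins; `[U-13C]`glucose-like (pyruvate M+3) and
`[U-13C]`glutamine-like (M+5) tracers; additive Gaussian MID noise
(sd 0.01 per channel, renormalized), multiplicative lognormal pool noise
(10%), and Gaussian phase-fraction noise (sd 0.01). The population is
released at `theta0 = 0.4` — the G1/S boundary, where standard
double-thymidine synchronization of HeLa cells arrests — with initial
spread `s0 = 0.05` and dispersion `D = 8e-4` per hour, which desynchronizes
the population substantially within one cycle. Releasing at G1/S means the
S and G2/M bins are sampled early, while the population is still sharp;
the G1 bins are sampled late and are correspondingly harder to resolve.

Free fluxes vary over the cycle as smooth periodic (cosine) profiles
evaluated at bin centers. In the `"oscillating"` scenario glucose oxidation
(PDH) peaks mid-G1 (position 0.2, amplitude 0.3 around base 1.0) and the
glutamine-derived oxidative (GDH, 0.25 around 0.6) and reductive (RC, 0.15
around 0.18) fluxes peak at position 0.5, centered on the S bins. The
citrate efflux is then *solved per bin* from the linear constraint
`4 PDH + 2 GDH − 3 CITout = const`, which under the default accounting
makes total NAD(P)H production identical in every bin — the scenario's
complementarity is exact by construction, and all bin flux maps remain
non-negative and balanced. Effect sizes were chosen so that the designed
phase contrasts sit a few estimated standard errors apart; a designed
effect below the design's own detection limit would make end-to-end checks
uninformative. Per-bin pools vary as a smooth periodic profile
(`1 + 0.15 cos(2 pi (theta − 0.55))`), consistent with the deconvolution's
circular smoothness prior.

What the generator does **not** emulate: per-cell amounts actually halve
discontinuously at division (a sawtooth on the circle that fights any
circular smoothness prior); chromatographic artifacts, batch effects and
peak-picking errors; compartment-specific pools; tracer switch dynamics
(the media swap is instantaneous at chase time 0). Passing tests therefore
demonstrate correctness of the inference chain under its stated model, not
robustness to real LC-MS pathology.

# Problem sizes and runtime choices

The test suite and acceptance script run everything at the scales above:
the default network's EMU system has ~73 nodes across size classes 1-6;
oracle-equivalence checks use 6 chase times and 7 networks; the coverage
study uses 50 replicates of a 4-metabolite branched network; the end-to-end
run uses one full scenario (8 releases x 6 chase times x 8 metabolites x 2
tracers) with 4 optimizer starts per fit and a 30-iteration cap on the
mixing-model refinement. These sizes were chosen so a complete run stays
comfortable on a single CPU while leaving every statistical check
well-powered.

# Known limitations

* Single-pool (no compartment) metabolite model; mitochondrial/cytosolic
  mixing is absorbed into effective pools and dilution fractions.
* The wrapped-Gaussian desynchronization model is a two-parameter stand-in;
  any richer model can be swapped behind `evolve_density()` /
  `build_mixing_matrix()`.
* Per-phase fluxes assume piecewise-smooth variation over position; sharp
  intra-phase switches are attenuated by both the bin discretization and
  the smoothing priors.
* Exchange fluxes are fit on a log scale and are often weakly identified;
  their profile intervals are frequently open, which is reported rather
  than hidden.
* Profile-likelihood intervals are calibrated for fits to directly observed
  MIDs (the coverage simulation runs there). When computed inside the
  pipeline on deconvolved MIDs they inherit that stage's correlated errors
  and the phase-constant approximation of heterogeneous bins, and can
  under-cover the phase-mean truth; treat pipeline-level CIs as optimistic.
* The NNLS solver's active-set iteration can cycle on exactly collinear
  designs; a tiny escalating ridge (far below measurement precision)
  breaks such degeneracies.
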