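# nucshuttle

Quantitative analysis of **mechanoselective protein import across the
nuclear pore complex (NPC)**, for single-molecule biophysicists and
cell biologists quantifying nucleocytoplasmic transport with optogenetic
shuttling probes and force spectroscopy.

The NPC imports NLS-tagged cargos faster when a mechanically soft or
unstructured region leads the way through the pore. Testing that
quantitatively requires several pieces of machinery, all provided here:

* **Compartmental transport kinetics** — the recovery of the
  nucleus-to-cytoplasm ratio after light-driven export follows
  `[N]/[C](t) = Ke (1 − e^(−kI t)) / (1 + v Ke e^(−kI t))`, with
  accumulation `Ke`, import rate constant `kI` (ks⁻¹) and
  nucleus-to-cytoplasm volume ratio `v`. Bounded nonlinear least squares
  per cell (`fit_recovery()`, `fit_export()`), an initial-condition
  correction (`correct_initial_conditions()`), and the coupled
  import/export variant with exact aggregate inversion
  (`nc_ratio_model_coupled()`, `rates_from_coupled_fit()`).
* **Three-step cell filtering** — iterative extreme-studentized-deviate
  outlier removal (`gesd_filter()`, tolerance 2 SD), activation-phase QC
  against the 1.4 ks⁻¹ export-rate threshold (`activation_qc()`), and
  manual rejection lists; population summaries and rank-sum comparisons.
* **Polyprotein unfolding under force clamp** — stochastic
  (`r_N = rU / H_N`, the max-of-N-exponentials law) versus sequential
  (`r_N = rU / N`) scaling, a Monte-Carlo staircase simulator, step
  detection, trajectory selection rules (≥2 steps, detachment ≥ 3 t_N),
  ensemble rates `1/⟨t_N⟩` and one-parameter scaling fits with model
  discrimination (`fit_scaling()`).
* **Polymer elasticity** — freely-jointed-chain step-to-contour-length
  conversion (Kuhn length 1.1 nm) and the worm-like-chain interpolation
  force law.
* **Mechanoselectivity statistics** — the ~1/N mass law and anchored
  mass-threshold detection, relative accelerations, soft-vs-stiff-leading
  directionality ratios, and the transport free-energy surface
  `ΔG(M, F_U) = −kT ln(kI / kI_ref)`.
* **Synthetic data with ground truth** — generators for single-cell
  traces (import, export, coupled two-channel) and force-clamp
  ensembles, deterministic in (parameters, seed), plus the packaged
  table of reported per-construct rate constants (`construct_table()`).

## Worked example

Simulate a 120-cell wild-type-like population, fit every cell, run the
full filtering protocol, and summarize:

```r
library(nucshuttle)

cfg  <- synthetic_config(seed = 7, n_cells = 120, construct = "WT")
pop  <- generate_population(cfg)
fits <- lapply(pop$traces, fit_recovery)
fits <- flag_unphysical(fits)
fits <- flag_outliers(fits)            # GESD on kI and Ke, tolerance 2 SD
fits <- flag_poor_activation(fits, pop$traces)
summarize_population(fits, pop$traces, construct = "WT")
#> <population_summary> WT: n = 100, kI = 1.669 +/- 0.038 ks^-1, Ke = 2.031 +/- 0.049
```

The generating rate was the fixture value 1.62 ks⁻¹ (median of the
inter-cell lognormal); the filtered population mean lands within ~1.3
SEM of it, and 20 of 120 cells were flagged (the literal 2-SD iterative
sweep is aggressive by construction — see the methods vignette).

Force-clamp scaling analysis against the two unfolding models:

```r
tab <- do.call(rbind, lapply(1:8, function(N) {
  ens <- generate_trajectory_ensemble(2000, N = N, rU = 1.15,
                                      mode = "stochastic", seed = 100 + N)
  ensemble_rates(ens$trajectories)
}))
fit_scaling(tab, model = "stochastic")
#> <scaling_fit> stochastic model: rU = 1.1560 s^-1 (rss = 14; competing model rss = 4.68e+03)
```

The per-domain rate is recovered within 0.6% and the stochastic model is
preferred over the sequential one by a ~300x residual ratio.

Caption-style cross-construct statistics from the packaged rate table:

```r
acc <- relative_acceleration(1.97, 1.64)   # (GI)4-tagged vs untagged cargo
sprintf("relative acceleration: %+d%% (raw %.2f%%)", acc$percent, acc$raw)
#> "relative acceleration: +20% (raw 20.12%)"
```

## Layout

* `R/` — implementation (transport model and fits, QC, unfolding,
  polymer elasticity, mechanoselectivity, synthetic generators, CLI).
* `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (one test per acceptance criterion).
* `vignettes/transport-kinetics-methods.Rmd` — models, assumptions,
  parameter defaults, numerical choices and known limitations.
* `scripts/acceptance.R` — the acceptance report described above.
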