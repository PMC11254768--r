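---
title: "Models and methods: nucleocytoplasmic transport kinetics and polyprotein unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshuttle)
```

## The scientific problem

The nuclear pore complex (NPC) imports protein cargos bearing a nuclear
localization signal (NLS). Beyond mass and surface chemistry, the *local
mechanical stability* of the protein region adjacent to the NLS modulates
the import rate: cargos that lead with a mechanically soft or unstructured
region enter faster. This package provides the quantitative machinery for
such studies: compartmental kinetics fitted to single-cell optogenetic
recovery curves, the cell-level quality-control protocol, force-clamp
polyprotein unfolding models and simulation, polymer-elasticity
conversions, and cross-construct statistics (mass law, directionality,
free-energy surface). Because the raw live-cell recordings behind such
studies are typically not deposited, a synthetic-data module generates
every input with known ground truth.

## The compartmental transport model

During dark recovery an optogenetic (LEXY-type) construct is re-imported
into the nucleus by its NLS while its NES is docked and invisible, so the
kinetics are first order with no active export. With $K_e$ the
steady-state nucleus-to-cytoplasm accumulation, $k_I$ the import rate
constant and $v$ the nucleus-to-cytoplasm volume ratio, the
nucleus-to-cytoplasm concentration ratio evolves as

$$\frac{[N]}{[C]}(t) \;=\; \frac{K_e\!\left(1 - e^{-k_I t}\right)}
  {1 + v\,K_e\,e^{-k_I t}},$$

which starts at 0, rises monotonically and saturates at $K_e$
(`nc_ratio_model()`). $K_e$ and $k_I$ are independent free parameters:
$k_I$ sets the kinetics, $K_e$ the transport efficiency. For cargos with
non-negligible active export (e.g. serum-stimulated MRTFA) the same
functional form holds with the aggregates $K_e = k_I/k_E$ and relaxation
rate $k = k_E + v\,k_I$ (`nc_ratio_model_coupled()`); after fitting the
aggregates, `rates_from_coupled_fit()` inverts the $2\times 2$ system
exactly.

Rates are reported in $\mathrm{ks}^{-1}$ (events per 1000 s), the
convention of live-cell import kinetics; all time vectors are seconds.

### Forming the ratio from measured signals

Only the nuclear and whole-cell signals are measured; the cytoplasmic
signal is formed as whole-cell minus nuclear, so the analysis ratio is
$\mathrm{nuc}/(\mathrm{cell}-\mathrm{nuc})$. This conserves total signal
by construction. Whether the underlying proxy is concentration-like (mean
intensity) or amount-like (integrated intensity) is ambiguous in this
kind of data; the two differ by a factor $v$ absorbed into $K_e$ unless
the segmented areas change. The package fixes the *ratio contract* —
`nuc/(cell - nuc)` follows the model above with the nominal parameters —
and the synthetic generator emits signals consistent with it (under which
the stored signals behave like concentration proxies unless $v = 1$).
This is a declared convention, not an inference about any particular
instrument.

### Initial-condition correction

Activation rarely empties the nucleus completely. The residual is removed
by fitting the raw recovery nuclear signal to the shared-rate
bi-exponential $n_0 e^{-kt} + n_e(1 - e^{-kt})$ and subtracting
$n_0 e^{-kt}$ pointwise (`correct_initial_conditions()`), so the
corrected series starts at $\approx 0$. Two numerical points deserve
emphasis:

* The decay and rise share one rate $k$; the model is a shifted
  exponential, and when the data really follow it the fit is exact.
* The generator produces recovery nuclear signals of exactly this form
  (residual decaying at the recovery rate). Under that stated world the
  corrected ratio is *exactly* the compartmental model for any residual
  amplitude, which is what makes the $10^{-6}$ round-trip tests
  meaningful. With a residual of a different shape the correction is an
  approximation; the Monte-Carlo recovery tests quantify the resulting
  bias (below 1% at the default settings).

### Fitting

`fit_recovery()` uses bounded trust-region nonlinear least squares
(`nls(algorithm = "port")`), with $k_I \in (0, 50]$ ks$^{-1}$,
$K_e \in (0, 100]$, starting values $K_{e,0}$ = last ratio value and
$k_{I,0} = 1$ ks$^{-1}$. The volume ratio $v$ is *fixed* per cell
(segmentation-derived when available, default 0.25): $v$ and $K_e$ are
strongly correlated in the fit, and freeing both destroys
identifiability. A fit whose parameter lands on a bound is reported as
non-converged (a trace already at steady state drives the rate to its
ceiling); this surfaces as the `unphysical` QC flag rather than an error.
Export experiments are fitted by `fit_export()` as the exact mirror:
cytoplasm-to-nucleus ratio, volume ratio inverted, rate reported as
$k_E$.

## The three-step filtering protocol

1. **Unphysical fits and outliers.** `flag_unphysical()` removes
   non-converged and bound-pinned fits. `flag_outliers()` then runs an
   iterative extreme-studentized-deviate sweep (`gesd_filter()`)
   independently on the $k_I$ and $K_e$ distributions; a cell rejected by
   either is excluded. The "tolerance of two standard deviations" is
   implemented literally: remove the most extreme value while
   $|x-\bar x|/s > 2$, recomputing $\bar x, s$ each round, with at most
   20% of the sample removed.

   A known mathematical property of this literal rule: iterated
   $2\sigma$ trimming has a fixed point that rejects $\approx 13.6\%$ of
   *perfectly Gaussian* data (the trimmed-normal SD satisfies
   $c = 2 s(c)$ at $c \approx 1.49$). A "clean populations lose
   $\lesssim 10\%$" expectation is therefore unattainable under this
   definition — the filter rejects its cap on realistic unimodal data.
   The implementation keeps the literal rule (it reproduces the
   documented worked example, is idempotent at natural termination, and
   captures injected $10\times$ outliers at $>90\%$); users wanting a
   gentler filter can raise `tolerance_sd`.
2. **Activation QC.** `activation_qc()` fits a single exponential decay
   (amplitude, offset, rate) to the activation-phase nuclear signal and
   fails the cell if the rate is below 1.4 ks$^{-1}$ — the model's
   $[N]_0 \to 0$ assumption requires fast activation export. A fit whose
   decay explains little variance (flat traces) fails too. Note the
   identifiability limit: in a 10-minute activation window a weak decay's
   rate is poorly determined under noise, so exact threshold
   classification is only guaranteed for noise-free constructed traces;
   at 5% noise, cells near the threshold can land on either side.
3. **Manual rejection.** Human inspection is represented by an explicit
   identifier list (`apply_manual_rejections()`); the flag is retained as
   an audit trail, never silently dropped.

`summarize_population()` averages retained cells only (mean ± SEM and the
point-by-point mean recovery curve); `compare_groups()` wraps the
two-sided Mann–Whitney rank-sum test, appropriate for the right-skewed
rate distributions.

## Stochastic versus sequential polyprotein unfolding

A polyprotein of $N$ identical domains held at constant force unfolds
*stochastically*: every domain sees the force, each unfolds independently
at rate $r_U$, and the time to unfold all $N$ is the maximum of $N$
exponentials, so the total rate is

$$r_N = \frac{r_U}{H_N}, \qquad H_N = \sum_{n=1}^N \frac1n .$$

A pore that processes one domain at a time is *sequential*: the total
time is a sum of $N$ exponentials and $r_N = r_U/N$. The two laws differ
strongly in shape ($r_1/r_8$ is $H_8 \approx 2.72$ versus 8), which is
what the scaling fit discriminates.

`simulate_trajectory()` draws the event times accordingly, builds a
staircase of 25-nm steps with additive Gaussian noise at 1 kHz sampling
(noise applied post-staircase; cantilever dynamics are out of scope) and
detaches the molecule at `detachment_factor` times the last unfolding
time (default 5, comfortably beyond the 3x selection rule so that
default ensembles are not truncated). The rate estimator is
$r_N = 1/\langle t_N\rangle$: the alternative $\langle 1/t_N\rangle$ is
not used because the reciprocal of an exponential-like time has no finite
expectation, and $1/\langle t_N\rangle$ is the quantity the closed forms
above predict.

Step detection (`detect_steps()`) is deliberately simple and auditable:
the jump across each sample boundary is estimated as the difference of
3-ms window means of the extension, contiguous above-threshold regions
collapse to their strongest boundary, jumps below half the expected step
are rejected, and a jump close to a multiple of the expected step is
counted as coincident events. On the default noise model this matches
$\ge 95\%$ of true steps within $\pm 5$ ms; events closer than the window
merge, which is the resolution limit of any windowed detector.
`select_trajectories()` applies the fingerprint rules ($\ge 2$ steps,
detachment $\ge 3 t_N$).

## Polymer elasticity conversions

An unfolding step observed at force $F$ under-reports the released
contour length because the new chain is only fractionally extended. The
freely jointed chain gives the fraction as the Langevin function
$x/L_c = \coth(Fb/kT) - kT/(Fb)$ with Kuhn length $b = 1.1$ nm
(`fjc_extension_fraction()`, `contour_increment_from_step()`); the
worm-like chain interpolation form
$F = (kT/p)\,[\tfrac14(1-x/L_c)^{-2} - \tfrac14 + x/L_c]$ serves
force-extension fitting (`wlc_force()`). $kT$ defaults to 4.114 pN nm
(298 K). One known discrepancy is recorded rather than patched: published
magnetic-tweezers worked numbers (a ~21 nm step at ~25–30 pN quoted as a
~35 nm contour increment) are not reproduced by the plain FJC formula
with $b = 1.1$ nm, which gives ~26 nm; the exact conversion convention
behind such numbers (effective force, folded-length correction) is not
stated in the source material, so this package implements the plain
formula and documents the gap.

## Cross-construct statistics

* **Mass law** (`fit_mass_law()`): one-parameter weighted fit
  $k_I(N) = A/N$, regressing on domain count $N$ (the form the law is
  stated in), with mass carried for reporting.
* **Mass threshold** (`mass_threshold()`): deviations from the law emerge
  at low mass, so the law is anchored on the largest-$N$ records and
  grown downward while records stay within `deviation_sd` SEMs; low-mass
  records below the anchored law by more than that are flagged and the
  threshold is the largest flagged mass. A global fit would let the
  deviant points drag the amplitude toward themselves and mask the
  threshold (verified numerically during development). The 2-SEM rule is
  this package's operationalization of a qualitative concept and is
  configurable.
* **Relative acceleration** (`relative_acceleration()`):
  $100(k_I^{var}/k_I^{ref}-1)$, rounded half-away-from-zero to integer
  percent for caption parity, raw value retained.
* **Directionality ratio** (`directionality_ratio()`): soft-leading over
  stiff-leading import rate with SEM propagated in quadrature.
* **Free-energy surface** (`free_energy_surface()`):
  $\Delta G = -\ln(k_I/k_I^{ref})$ in $kT$ units per construct, placed at
  its (mass, unfolding force) coordinates, with optional inverse-distance
  interpolation onto a grid for visualization only. The packaged
  unfolding-force coordinates are representative AFM values from the
  single-molecule literature (documented as such); they are plotting
  coordinates and never enter a fitted quantity.

## The synthetic-data generator: what it emulates, what it does not

`generate_population()` emulates per-construct single-cell ensembles:
10-min activation (one frame/min), 45-min recovery, per-cell $(k_I, K_e)$
lognormal around the construct's fixture rate (median-parameterized,
log-SD 0.3 — rates are positive and right-skewed), $v$ truncated normal
(0.25 ± 0.05), residual amplitude $n_0$ truncated normal (0.05 ± 0.02),
activation rate 6 ± 1.5 ks$^{-1}$ for well-activated cells, and 5%
multiplicative Gaussian noise per frame and compartment (shot-noise-like,
independent across frames). A configurable fraction of cells is generated
with activation rates in (0.5, 1.1) ks$^{-1}$ to exercise the QC exactly.
Defaults were chosen once as realistic for confocal live-cell data and
are not tuned to any test outcome; where the original acquisition
parameters are stated (frame interval, phase durations) those are the
defaults.

The generator does **not** emulate: photobleaching, focus drift,
segmentation error, spatial heterogeneity within compartments, or
non-stationary noise. A green recovery test therefore establishes that
the estimator chain is correct and well-conditioned under the stated
noise model — not that any particular biological dataset meets that
model. The population rate constants themselves (e.g. 1.62 ks$^{-1}$ for
the wild-type monomer construct) derive from unreleased recordings and
enter only as fixture values and generation targets.

Every generator is a deterministic function of (parameters, seed); seeds
are mandatory.

## Numerical choices and degenerate inputs

* Bounded `port` fits everywhere; non-convergence is always a flagged
  result, never an exception, except where the input violates a
  precondition (too few frames, wrong direction).
* Constant (steady-state) traces converge to a bound and are flagged
  `unphysical`.
* SEM of a single-cell summary is 0 by convention; a single-trajectory
  rate group reports `NA` SEM.
* GESD ties are broken by first index; with continuous data ties have
  probability zero.
* Percent rounding is half-away-from-zero (so $-11.59 \to -12$), not
  banker's rounding.

## Known limitations

* The activation-QC rate is weakly identified for slow decays in a
  10-minute window; exact classification holds for constructed noise-free
  traces only.
* The step detector merges events closer than its 3-ms window.
* The mass-threshold rule and the GESD tolerance are operationalizations
  of qualitatively described procedures; both are configurable and their
  defaults are documented above.
* The free-energy surface interpolation is for display; no uncertainty is
  propagated onto the grid.
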