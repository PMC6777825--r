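---
title: "Thermal-shift (DSF) binding analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-shift (DSF) binding analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfshift)
```

## The assay and the analysis problem

Differential scanning fluorimetry (DSF) follows the unfolding of a protein
as a temperature ramp exposes hydrophobic surface to an
environment-sensitive dye.  For a receptor ligand-binding domain (LBD),
a ligand that binds the folded state raises the apparent melting
temperature $T_m$; the size of the shift carries quantitative information
about affinity.  `dsfshift` implements the full analysis chain for such a
screen against a heterodimeric class C GPCR LBD (the package's motivating
system is a fish taste-receptor T1r2a/T1r3 LBD screened against amino
acids): $T_m$ calling from raw melt curves, apparent dissociation
constants ($K_{d\text{-app}}$) from thermal shifts, single-concentration
receptor-response potencies (EC$_{50}$), and the association between the
two, including a classical QSAR regression on side-chain descriptors.

## Tm calling

$T_m$ is defined as the temperature of the maximum of
$dF/dT$ — the derivative-maximum definition used by plate-instrument
software.  `differentiate()` computes a Savitzky–Golay (local quadratic)
smoothed derivative over a `smooth_window_C` (default 1.0 °C, i.e. five
points on the default 0.2 °C grid); the vendor algorithm is undisclosed,
so the smoother is an explicit, configurable choice.  A linear ramp
differentiates to its exact slope, and on noiseless simulated curves the
derivative argmax sits at the simulated midpoint to within one grid step.

`call_tm()` retains derivative peaks by two rules:

* **relative prominence** — a peak's topographic prominence must be at
  least `prominence_frac` (default 0.10) of the most prominent peak's;
* **absolute noise floor** — it must also exceed `snr_min` (default 10)
  times the noise level of the derivative trace, estimated from first
  differences so that smooth curve structure (baseline, quench tail) does
  not inflate it.  Pure-noise traces therefore return a "no transition"
  state rather than a spurious call.  At the default simulation noise a
  genuine transition sits near 50 noise units, so both margins are wide.

Peaks closer than `min_separation_C` (default 2 °C) merge into the more
prominent one.  Curves whose global derivative maximum lies on a grid
boundary are flagged unusable rather than extrapolated.  When two or more
peaks survive, the profile is **biphasic** and the **rightmost peak is
adopted**: in the motivating system the left-side transition (~50 °C)
does not shift with ligand, while the right-side transition carries the
binding signal.  Adopted $T_m$ values are grid-quantised (no sub-grid
interpolation); replicate averaging restores sub-grid precision, and the
0.2 °C default grid keeps the quantisation error below typical replicate
noise.

$T_0$, the no-ligand reference, is the mean adopted $T_m$ of the
buffer-only wells of the same plate (`t0_source = "buffer_wells"`), or a
fixed kelvin value.  Downstream of replicate summaries all temperatures
are kelvin; degrees Celsius appear only at I/O boundaries.

## From shift to affinity: the Schellman model

For a reversibly unfolding protein whose native state binds the ligand,

$$\Delta T_m \;=\; T_m - T_0 \;=\; \frac{T_m T_0 R}{\Delta H^0}
  \ln\!\left(1 + \frac{[L]}{K_{d\text{-app}}}\right),$$

with $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $\Delta H^0$
the van 't Hoff unfolding enthalpy at $T_0$.  Solved for $T_m$ this gives
the closed form used throughout
(`predict_tm()`):
$T_m = T_0 / (1 - T_0 R \ln(1+[L]/K_d)/\Delta H^0)$.  The model assumes
reversible unfolding, a shift-independent $K_d$, and no heat-capacity
term; these are documented caveats, not code.

Two estimators invert it:

* **Dose-series fit** (`fit_dose_series()`): unweighted nonlinear least
  squares of replicate-averaged $T_m$ against concentration with $T_0$
  fixed, estimating $K_{d\text{-app}}$ and $\Delta H^0$.  Positivity is
  enforced by log-parameterisation; a small multistart over initial
  enthalpies (40/70/100 kcal mol$^{-1}$) with the half-maximal-shift
  concentration as the $K_d$ start guards against local minima; trial
  parameters that run past the model's feasibility boundary are penalised
  by clamping rather than erroring.  Standard errors are delta-method
  transforms of the log-scale covariance.  Series flatter than 0.5 K are
  refused, as are series with fewer than four concentrations.
  sem-weighted fitting exists behind `weighted = TRUE` but is off by
  default, matching the reference analysis, which fit plain averages.
* **Single-point inversion** (`estimate_kd_single_point()`): with $T_0$
  and $\Delta H^0$ fixed (defaults 326.1 K and 72.1 kcal mol$^{-1}$, the
  screen-level constants of the motivating study),
  $K_{d\text{-app}} = [L]\,/\,(\exp[\Delta T_m \Delta H^0 /(R\,T_m T_0)] - 1)$.
  The two functions are exact inverses, which the tests verify to
  $10^{-9}$ relative across the feasible range.

Single-point estimates are only trustworthy in an empirical shift window:
6–11 K is **preferred**, 2–11 K **acceptable**, below 1 K is under the
reporting floor, negative shifts mean destabilisation (no affinity is
assigned), and everything else is out of range.  The thresholds are named
configuration constants (`dsf_config()`), since they were derived
empirically, not thermodynamically.  `select_reporting_estimate()`
encodes the concentration-adoption rule used for screening panels: take
the lowest concentration whose shift is preferred, else the highest
acceptable one, else mark the ligand unusable with its reason recorded.
A useful robustness property motivated the window design: inside the
preferred window, a ±18% error in the assumed enthalpy changes the
single-point $K_d$ by less than a factor of two (at exactly ±20% the
fold-error touches 2.0).

## Receptor response and the association analyses

`estimate_ec50()` inverts the fixed-maximum Hill relation (coefficient
fixed at 1 — the response model carries no exponent, and the package does
not make it configurable):
$\mathrm{EC}_{50} = [L](\Delta RFU_{max} - \Delta RFU)/\Delta RFU$ with
$\Delta RFU_{max} = 104.3$ by default.  Non-positive responses are
excluded as states (`negative_excluded`), and responses at or above the
maximum are `saturated` — the ligand defining the maximum cannot itself
yield a finite estimate.  p-scales are molar-basis
($pK = -\log_{10} K[\mathrm{M}]$) throughout; the base unit only adds a
constant, so correlations are unaffected.

`correlate_binding_response()` supports the two comparisons a screen
validation needs: raw $\Delta T_m$ vs raw $\Delta RFU$ at a common
concentration (all co-measured ligands, including destabilised ones), and
$pK_{d\text{-app}}$ vs $pEC_{50}$ (usable binding estimates and `ok`
responses only).  Pearson's $r$ is used since the p-scale relation is
plotted and interpreted linearly; every excluded ligand is recorded with
its reason.

`qsar_search()` regresses $pK_{d\text{-app}}$ on all descriptor subsets
of size 1 and 2 — classical QSAR practice for a ~15-ligand panel — and
reports $r$, the standard error of estimate $s$, the overall $F$ and its
significance at $\alpha = 0.05$.  No multiplicity correction is applied
across the 21 enumerated models, again matching classical practice; the
number of models tried is reported so the reader can discount nominal
significance accordingly.  With six correlated descriptors the
familywise false-positive rate of the uncorrected enumeration is roughly
20–30% on no-signal panels — a model flagged at $\alpha=0.05$ in such a
search is weak evidence at best.  The built-in descriptor table
(`builtin_descriptor_table()`) is a stand-in assembled from standard
published per-residue scales (Fauchère–Pliska π, Hopp–Woods
hydrophilicity, Grantham polarity, Kyte–Doolittle hydropathy, formal
charge at pH ≈ 8, Zamyatnin volume); it is generic literature data, not a
transcription of any particular study's supplement.

## The synthetic-data generator

Every stage is testable without instrument files because the generator
produces inputs with known ground truth:

* **Melt curves** (`simulate_melt_curve()`): linear dye baseline plus one
  two-state van 't Hoff logistic per transition (midpoint `tm_true`,
  sharpness `dh_vh` — a *simulator* enthalpy, deliberately distinct from
  the Schellman $\Delta H^0$), optional white noise, and an exponential
  post-melt quench.  The quench switches on 5 °C above the last midpoint
  (`quench_offset_C`): starting it at the midpoint itself would drag the
  derivative maximum down by ~0.4 K at the default rate, so the offset
  preserves the defining property that with zero noise the derivative
  maximum of each component sits exactly at its `tm_true`.
* **Plates** (`simulate_plate()`): buffer wells carry a single transition
  at 53.0 °C; agonist wells get the Schellman-shifted main transition
  plus a fixed ligand-insensitive 50 °C first transition (biphasic mode);
  destabilisers lower the main transition by a phenomenological
  $-1$ K/decade of concentration (no thermodynamic model is assumed for
  destabilisation); inert ligands change nothing.  The default
  fluorescence noise (0.001 AU on unit-amplitude transitions) was chosen
  to reproduce an instrument-grade per-well $T_m$ repeatability of
  ~0.15 K (s.e.m. ≈ 0.06 K over 7 buffer wells).
* **Dose series** (`simulate_dose_series()`): replicate $T_m$ values from
  `predict_tm()` plus Gaussian $T_m$ noise.  Noise is applied at the
  $T_m$ level here but at the fluorescence level in the plate simulator —
  deliberately two levels, so caller error and fit error are separable in
  tests.
* **Response panels** (`simulate_response_panel()`): Hill responses with
  fixed maximum plus noise; noise may push weak responses negative,
  exercising the exclusion rule.

All randomness flows through an explicit `seed` argument; the global RNG
stream is saved and restored, so seeded runs are bit-reproducible and the
generators never perturb a caller's random state.

What the generator does *not* emulate: dye-binding kinetics,
heat-capacity curvature of the baseline, scan-rate dependence,
irreversible aggregation, and any mechanistic model of destabilisation or
of the ligand-insensitive first transition.  Passing tests therefore
demonstrate correctness of the estimators under the stated two-state
model, not robustness to every pathology of real dye data.

## Worked example

```{r example}
specs <- list(Gln = ligand_spec("Gln", "agonist", kd_true = 30.9),
              Glu = ligand_spec("Glu", "agonist", kd_true = 422),
              Lys = ligand_spec("Lys", "destabilizer"))
map <- plate_map(
  well_id  = c(paste0("B", 1:4), paste0("W", 1:9)),
  ligand_id = c(rep("buffer", 4), rep(c("Gln", "Glu", "Lys"), each = 3)),
  conc_uM  = c(rep(0, 4), rep(c(100, 1000, 10000), times = 3)))
curves <- simulate_plate(map, specs, seed = 42)
report <- run_pipeline(curves)
report
report$selected
```

## Problem sizes and numerical choices

The package's own validation uses deliberately modest problem sizes:
melt curves of ~370 points (25–99 °C at 0.2 °C), plates of tens of wells,
200-repeat parameter-recovery simulations for the dose-series fitter, and
100-repeat Monte-Carlo calibrations of the QSAR false-positive rate.
Convergence of the fitter is declared only when the optimiser converged
*and* the optimum is feasible (the clamped penalty region was left);
ties between derivative peaks are broken toward the more prominent peak,
and exact ties in prominence toward the lower temperature by stable
ordering.  Degenerate inputs — empty transition lists, non-monotone
grids, flat series, all-negative shifts, zero-variance correlation
inputs — are rejected or classified, never silently fitted.

## Known limitations

* Grid-quantised $T_m$ calls: sub-grid interpolation is deliberately
  omitted; on coarse grids the quantisation shows up as a ±half-step
  bias for midpoints between grid points.
* The Schellman inversion assigns no affinity to destabilising ligands;
  they are classified and excluded, as the motivating analysis did.
* Single-point EC$_{50}$ estimates inherit the fixed-maximum assumption;
  a ligand with a different efficacy ceiling is mis-scaled.
* The QSAR module reports uncorrected nominal significance by design;
  treat its `significant` flag as exploratory.
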