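---
title: "Methods: surrogate-nuclide dosimetry and therapy outcomes in ritkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-nuclide dosimetry and therapy outcomes in ritkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ritkit)
```

## Scope and data model

`ritkit` covers the analysis chain of a preclinical radioimmunotherapy
(RIT) experiment in tumor-bearing mice:

1. **Biodistribution**: per-animal %ID/g measurements
   (animal, group, organ, time, %ID/g, body weight) are normalized to a
   20 g reference mouse and collapsed into per-group organ
   time–activity curves (mean, sample SD with the n − 1 denominator,
   n per time point).
2. **Dosimetry**: each group-mean curve, measured with a gamma-emitting
   imaging surrogate, is converted into the absorbed dose a
   beta-emitting therapy conjugate would deliver.
3. **Therapy outcomes**: caliper series become ellipsoid volumes
   (V = length × width²/2), per-animal normalized growth, and
   time-to-endpoint survival with right-censoring at the end of
   observation.
4. **Synthetic cohorts** emulate 1–3 so the pipeline is testable
   without animal data.

## The dosimetry model and its assumptions

The absorbed dose is the MIRD-style self-dose

$$D \;=\; \Delta \,\tilde A, \qquad
\tilde A \;=\; A_0 \cdot 10 \cdot \int_0^\infty f(t)\,e^{-\lambda t}\,dt,$$

where $f(t)$ is the organ's %ID/g curve, $A_0$ the injected activity
(Bq), $\lambda$ the therapy nuclide's decay constant, and
$\Delta$ = 1.495 × 10⁻¹³ Gy·kg·(Bq·s)⁻¹ for ⁹⁰Y. Assumptions, stated
explicitly because each is a genuine modelling choice:

* **Decay correction.** Gamma-counter %ID/g values are assumed
  decay-corrected to injection time (standard practice when counting
  against an injected-dose standard). The *therapy* nuclide's physical
  decay is therefore applied inside the integral, and the surrogate's
  biological kinetics are taken as identical for the therapy conjugate
  (same chelator–antibody construct). `surrogate_substitution_check()`
  quantifies the risk of that substitution: for the ¹¹¹In/⁹⁰Y pair the
  half-life ratio is 67.4/64.1 ≈ 1.051 and the maximal decay-weight
  discrepancy over 168 h is about 9%, below the default 25% warning
  threshold.
* **Self-dose only.** No crossfire between organs and no
  remainder-of-body term: for a pure beta emitter whose range is short
  relative to organ separation this is the customary first
  approximation, and it is what a per-organ dose table can support.
* **Group-level integration.** The default integrates the group-mean
  curve rather than averaging per-animal doses; with five animals and
  30% CV the two differ by sampling noise only. Per-animal dosimetry is
  available by summarizing single-animal subsets.

### Numerical choices

* **Segment integration.** $f$ is piecewise-linear between measured
  times; each segment of $f(t)e^{-\lambda t}$ is integrated in closed
  form. When $\lambda\,\Delta t < 10^{-8}$ the closed form cancels
  catastrophically, so the trapezoid on the product is used there
  (exact to $O((\lambda \Delta t)^2) \le 10^{-16}$ relative). A plain
  trapezoid-on-the-product mode (`method = "trapezoid"`) exists as a
  cross-check.
* **Head of the curve (`t0_mode`).** Nothing is measured before the
  first time point. Default `"auto"`: blood holds its first value back
  to t = 0 (the antibody is intravascular at injection); every other
  organ ramps linearly from (0, 0). Both behaviours are selectable.
* **Tail (`tail_mode`).** Beyond the last measurement, default
  `"physical"` keeps the last %ID/g value under physical decay alone —
  conservative (an upper bound) when biological clearance is slow
  compared with the beta decay, as it is for an IgG.
  `"terminal_slope"` continues the log-linear biological slope of the
  last two points (tail = $f_T e^{-\lambda T}/(\lambda + k_b)$, refusing
  a rising slope whose integral would diverge); `"truncate"` stops at
  the window end. Tails are provably ordered
  truncate ≤ terminal_slope ≤ physical for declining curves, and the
  test suite asserts it.
* **Rounding.** Doses are kept at full precision; the report-layout
  serializer rounds to 0.1 Gy for display only.

### Discretization and the sparse schedule

With the experimental schedule (1, 6, 24, 48, 96, 168 h) the chord
approximation of a smooth double-exponential over-estimates the
integral by roughly 2% (convexity of the uptake phase plus the held
tail). This is a property of sampling six points, not of the
integrator: on a dense grid the same chain agrees with the analytic
double-exponential dose to better than 0.05%. The end-to-end
consistency test therefore runs the default organ kinetics on a dense
schedule; the sparse-schedule bias is accepted as part of the method,
exactly as it is when real six-point data are integrated.

## The synthetic cohorts: what they emulate

`simulate_biodistribution()` states the emulated world:

* solid organs follow
  $f(t) = A\,(e^{-k_c t} - e^{-k_u t})$; tumor parameters
  ($A$ = 49.14 %ID/g, $k_u$ = 0.06 h⁻¹, $k_c$ = 0.004 h⁻¹) are
  calibrated so the noiseless curve peaks at 37.8 %ID/g at ≈48 h, the
  slow antibody accumulation typical of an IgG in a xenograft; normal
  organs use fast uptake and amplitudes giving plausible tissue levels
  (their noiseless 0.925 MBq doses land near the few-Gy scale expected
  for lung/liver/spleen/kidney and tenths of a Gy for muscle).
* blood declines bi-exponentially (f0 = 25 %ID/g, 35% fast phase at
  0.18 h⁻¹, slow phase 0.008 h⁻¹).
* inter-animal variation is a single multiplicative lognormal factor
  per animal (mean 1, CV 0.3) shared across organs — the variance
  structure is unknowable from published mean ± SD, so one shared
  factor was chosen, with optional independent per-time jitter.
* the perfusion enhancer (SQAP) is phenomenological: a tumor-uptake
  multiplier decaying linearly from 1.4 at t = 0 to 1 at 48 h,
  matching a 1.4-fold difference at 1 h and peak parity at 48 h.
  Normal organs are unaffected, as observed. No pharmacodynamics are
  modelled.
* recorded raw %ID/g are de-normalized by each animal's body weight
  (lognormal around 20 g, CV 0.05) so that the pipeline's
  reference-weight normalization exactly recovers the model curve.
* every draw comes from a seed derived per (group, animal, stream), so
  adding organs or animals never perturbs existing values and a master
  seed fixes the cohort bit-for-bit.

The generator is longitudinal (each synthetic animal is observed at all
times) whereas the emulated design was cross-sectional (five animals
killed per time point); group-level means and SDs have the same
structure, but within-animal correlation across times is not something
the real design could exhibit. Other knowingly absent features: no
measurement error separate from biological variation, no tumor-size
dependence of uptake, no hematologic toxicity. A green test on
synthetic data therefore establishes computational correctness of the
chain, not biological validity of the kinetic parameters.

`simulate_therapy()` uses dose-dependent growth delay:
$V(t) = V_0\,e^{g\,\max(0,\,t - \alpha D)}$ with $V_0$ = 256 mm³ (an
8-mm tumor), $g$ = 0.06 d⁻¹ (controls reach the 12-mm endpoint in
about three weeks), $\alpha$ = 0.6 d/Gy so that a 44–48 Gy tumor dose
arrests growth for ≈26–29 days, and a 15% lognormal CV on $g$. Emitted
dimensions satisfy length = width = (2V)^{1/3}, so the volume formula
inverts exactly. Regression during the arrest (rather than stasis) is
not modelled; the delay is the phenomenon of interest.

## Therapy-endpoint conventions

* "Diameter" for the 12-mm humane endpoint is max(length, width) by
  default; the mean of the two dimensions is available, and the two
  readings differ only for elongated tumors.
* The event time is the first measurement day at or beyond the
  endpoint — no interpolation between discrete measurement days;
  animals never reaching it are censored at min(last day, day 56).
* Normalized volumes divide by the animal's own day-0 baseline
  (configurable window for a missing exact day 0); normalizing to the
  group-mean baseline was the open alternative and is reachable by
  summarizing first.
* The survival curve is the product-limit estimator via
  `survival::survfit`, verified in the tests against an exhaustive
  day-by-day counting oracle on every event/censor labelling of up to
  six records.
* Group contrasts are deliberately descriptive; inferential statistics
  (ANOVA and multiple-comparison procedures) are out of scope.

## Degenerate inputs and failure policy

Negative %ID/g, non-positive body weights, unknown organs, missing
columns and non-numeric cells fail ingestion with the row and column
named. In pipeline runs, a per-animal failure (e.g. a missing baseline)
warns and excludes that animal; structural failures abort with a
non-zero exit from the CLI. A nuclide without Δ cannot be used as a
dose emitter. The bi-exponential fitter never throws on
non-convergence; it returns a flagged estimate with diagnostics.

## Limitations

Self-dose only (no photon crossfire for the imaging nuclide, no
S-value phantoms or voxel dosimetry); single-region tumors; the AUC
tail beyond the measurement window is an assumption surfaced in the
run manifest rather than a measurement; kinetic parameters of the
synthetic world are calibration targets, not fitted animal data.
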