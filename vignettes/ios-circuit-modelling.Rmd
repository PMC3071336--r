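---
title: "Equivalent-circuit modelling of impulse oscillometry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-circuit modelling of impulse oscillometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iosmodel)
```

## The measurement and the models

Impulse oscillometry measures the respiratory input impedance
$Z(f) = R(f) + jX(f)$ at a small set of oscillation frequencies,
conventionally $\{3, 5, 10, 15, 20, 25, 35\}$ Hz, with $R$ and $X$ in
kPa·s/L. In healthy adults $R$ is nearly flat in frequency; peripheral
(small-airway) obstruction makes $R$ fall with frequency and drives
low-frequency $X$ negative. `iosmodel` interprets spectra through two
lumped-parameter circuits.

**eRIC.** A central resistance $R_c$ in series with an inertance $I$ and a
peripheral branch $R_p \parallel C_p$:

$$Z(\omega) = R_c + j\omega I + \frac{R_p}{1 + j\omega R_p C_p},
\qquad \omega = 2\pi f,$$

so that

$$\mathrm{Re}\,Z = R_c + \frac{R_p}{1+(\omega R_p C_p)^2}, \qquad
\mathrm{Im}\,Z = \omega I - \frac{\omega R_p^2 C_p}{1+(\omega R_p C_p)^2}.$$

$\mathrm{Re}\,Z$ decreases strictly from $R_c + R_p$ at DC to $R_c$ at high
frequency — the frequency dependence of resistance is carried entirely by
the peripheral branch, which is why $\mathrm{fdR} = R_5 - R_{20}$ and the
fitted $R_p$, $C_p$ track small-airway function. The model reactance
crosses zero at

$$\omega_{res}^2 = \frac{R_p^2 C_p - I}{I\, R_p^2 C_p^2},$$

defined when $R_p^2 C_p > I$ (`model_fres()`); otherwise the model
reactance is positive everywhere and no resonance exists.

**aRIC.** The same branch with an extrathoracic shunt compliance $C_e$
across it, $Z_{a} = Z / (1 + j\omega C_e Z)$. $C_e = 0$ reproduces eRIC
exactly, so the families are nested: an aRIC optimum can never be worse
than the eRIC optimum on the same data, which the tests assert. The
impedance equations themselves are fixed from the circuit topology by
standard series/parallel analysis, and every closed form is checked in the
test suite against naive complex component combination at
$10^{-12}$ relative tolerance.

Units throughout: resistances kPa·s/L, inertance kPa·s²/L, compliances
L/kPa. (Published tables in this literature sometimes carry a garbled
compliance unit string; we read those values as L/kPa.)

## Indices

`compute_indices()` reduces a spectrum to the hallmark indices:

* $R_5$, $R_{20}$, and $\mathrm{fdR} = R_5 - R_{20}$;
* $X_5$;
* $F_{res}$: the first negative-to-non-negative zero crossing of $X$,
  linearly interpolated between bracketing grid points;
* $AX = \int_5^{F_{res}} |X(f)|\,df$, by the trapezoidal rule over the
  grid points between an interpolated 5 Hz endpoint and the crossing
  (the final segment is a triangle).

Numerical conventions, chosen once and tested:

* interpolation is linear in $f$ for both channels — the IOS grid is
  nearly uniform over 3–35 Hz and the triangle picture of $AX$ is
  piecewise linear; no extrapolation outside the grid span, ever;
* $AX = 0$ when $X(5) \ge 0$; $AX$ is **NA** (flagged, never silently 0)
  when $X$ never crosses zero below the top of the grid;
* with noisy multiple sign changes, the first crossing wins;
* 35 Hz supports interpolation but is excluded from circuit fitting,
  which uses 3–25 Hz (configurable in `fit_options()`).

Note one subtlety exercised by the fixtures: $AX$ computed on a
group-*averaged* spectrum need not equal the group mean of per-subject
$AX$ values, because averaging and the nonlinear $F_{res}$/area
construction do not commute. The package therefore treats the two as
consistent within a band, not equal.

## Parameter estimation

`fit_model()` minimises the unweighted stacked least-squares objective

$$\sum_f \left[(R_{mod}(f)-R_{meas}(f))^2 + (X_{mod}(f)-X_{meas}(f))^2\right]$$

over the fit frequencies. $R$ and $X$ share units and magnitude range in
child IOS data, so equal absolute weighting is appropriate; no relative
weighting is applied.

Design of the optimiser:

* **Backend**: Levenberg–Marquardt on the residual vector
  (`minpack.lm::nls.lm`) with box bounds, tolerances $10^{-14}$.
* **Parameter space**: $R_c, I, R_p, C_p$ on the log scale (they are
  positive and span decades); $C_e$ on the linear scale so the no-shunt
  boundary $C_e = 0$ is attainable — fits of aRIC to shunt-free data
  should, and do, drive $C_e$ to the floor.
* **Bounds**: $R_c, R_p \in [10^{-3}, 5]$ kPa·s/L,
  $I \in [10^{-5}, 0.05]$ kPa·s²/L, $C_p \in [10^{-3}, 2]$ L/kPa,
  $C_e \in [0, 0.1]$ L/kPa — wide boxes around physiological child
  values. $R_p = 0$ / $C_p = 0$ are accepted by the evaluators as
  degenerate branch limits but excluded from fitting.
* **Multi-start**: one data-driven heuristic start ($R_c$ from the
  high-frequency resistance, $R_p$ from the low/high resistance drop, $I$
  from the high-frequency reactance, $C_p$ from $X_5$) plus seeded
  uniform draws in optimiser space; default 8 starts. Ties between
  equally good starts break to the lowest start index, and the whole fit
  is bit-deterministic given spectrum and options. The optimiser never
  touches the caller's RNG stream.
* **Safety net**: `grid_search_oracle()` evaluates the objective on an
  exhaustive log-spaced lattice inside the bounds; the optimiser must
  dominate it, and the tests check this on published and random spectra.

On noiseless eRIC-generated spectra the fit recovers the generating
parameters to better than $10^{-6}$ relative (in practice machine
precision); with additive noise of sd 0.01 kPa·s/L the median relative
error of $C_p$ stays below 10%.

Whether group-level parameter estimates should come from fitting each
subject and averaging, or from fitting the group-averaged spectrum, is
genuinely open in this field's practice; both are supported
(`fit_cohort()` vs `fit_model()` on an averaged spectrum) and the two are
*not* asserted equal anywhere.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a two-year paediatric
bronchodilator study: `n_h = 7` healthy and `n_sai = 19` small-airway-
impaired subjects; a first visit with a pre-bronchodilator measurement
only; a second visit two years later with pre- and post-bronchodilator
measurements (3 records per subject).

Per group, a `group_archetype()` holds mean eRIC parameters, a log-normal
between-subject CV, and multiplicative growth and bronchodilator effects:

* Mean $R_p$/$C_p$ (H: 0.501/0.115; SAI: 0.824/0.045) and the effect
  multipliers (e.g. SAI growth $R_p \times 0.73$, $C_p \times 1.25$; SAI
  bronchodilator $R_p \times 0.79$, $C_p \times 1.35$) are set from
  published group means and percent changes for such cohorts, so the
  degenerate generator (CV 0, noise 0) walks the published group
  trajectory exactly (SAI $C_p$: 0.045 → 0.056 → 0.076).
* $R_c$ (0.35/0.40) and $I$ (0.0020/0.0018) and their mild effect
  multipliers ($R_c$: 0.92 growth, 0.95 bronchodilator; $I$: 1.0) are
  **calibration defaults** — no published means exist for them — chosen
  so synthetic spectra resemble real child data ($R_5 \approx$
  0.5–0.7 kPa·s/L, $F_{res} \approx$ 15–22 Hz for impaired subjects).
  They are overridable in `cohort_config()`.
* Between-subject spread is log-normal with the archetype mean as the
  *arithmetic* mean ($\sigma^2_{\log} = \log(1+\mathrm{CV}^2)$,
  $\mu_{\log} = \log m - \sigma^2_{\log}/2$), because published group
  tables report arithmetic means. Default CV 0.25 and measurement noise
  sd 0.01 kPa·s/L per channel are calibration choices; no dispersion is
  published.
* Noise is additive, Gaussian, homoscedastic and independent across
  frequency and channel (replicate averaging upstream of the spectra
  justifies nothing fancier); resistance vectors with any non-positive
  entry are redrawn, up to 100 attempts, then a degenerate-noise error is
  raised.
* The master seed expands into per-subject, per-record substreams by a
  stable string hash of (subject id, visit, condition), so a subject's
  data do not change when the cohort grows.

What the generator does **not** emulate: aRIC-truth data ($C_e > 0$) as a
default, breath-by-breath signals, heteroscedastic or correlated noise,
coherence-based quality weighting, or demographic covariates. Passing
tests on this generator therefore demonstrate correctness of the
estimation and analysis machinery under the stated measurement model, not
robustness to every artefact of real IOS recordings.

## Cohort statistics

`study_report()` composes the statistical surface:

* cell means per (group, visit, condition), with undefined $AX$ values
  kept as flagged missing, never dropped silently;
* percent changes computed **on cell means** (not means of per-subject
  changes), at full precision internally and rounded half-away-from-zero
  to integer percent for display;
* within-subject contrasts (growth: first vs second visit pre-B;
  bronchodilator: pre vs post) by the classic paired t-test;
  between-group contrasts (impaired vs healthy, 19 vs 7) by the Welch
  two-sample test — a paired test is impossible across unequal
  independent groups, so the paired form is reserved for within-subject
  comparisons;
* pooled correlations across all visit-conditions ($C_p$ vs $AX$,
  $R_p$ vs fdR, between-model parameter agreement) by ordinary least
  squares with Pearson $r$;
* raw p-values with an $\alpha = 0.05$ flag; no multiple-testing
  correction is applied, matching the practice this pipeline mirrors.

Degenerate inputs are handled explicitly: identical paired lists give
$t = 0, p = 1$; zero-variance differences with nonzero mean report the
limiting $p = 0$ with a `zero_variance` flag; a constant predictor makes
`linear_fit()` error rather than return nonsense.

## Problem sizes and verification scope

The shipped test suite runs the whole surface in well under a minute:
oracle equivalence of the closed forms on 100–150 random draws,
resonant-frequency closed form vs numeric zero crossing (0.1% relative),
noiseless recovery on 20+100 random spectra, noisy $C_p$ recovery over
30–100 replicates, grid-search domination on 21 spectra at a 5-point
lattice, and a full default cohort (26 subjects, 78 records) through
`study_report()`. The percent-change stage is verified cell-by-cell
against a published change table rebuilt from published group means;
four compliance cells there are checked as a ±2-point band rather than
exactly, because the published percentages were computed from unrounded
per-subject data while only 3-decimal means are in print.

## Known limitations

* The circuit models are minimal: no tissue viscoelasticity
  (constant-phase behaviour), no separate chest-wall compartment; they
  are interpretation devices for 3–25 Hz input impedance, not anatomical
  truth.
* $AX$ on averaged spectra vs averaged per-subject $AX$ differ by
  construction (above); compare like with like.
* Fitted parameters come without standard errors or confidence
  intervals; the multi-start least-squares machinery reports objective
  and convergence diagnostics only.
* The generator's dispersion and $R_c$/$I$ defaults are calibration
  choices; conclusions about statistical power at other noise levels
  require re-running with your own `cohort_config()`.
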