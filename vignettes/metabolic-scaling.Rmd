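---
title: "Methods: allometric scaling and cardiac thermal tolerance in allometherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric scaling and cardiac thermal tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allometherm)
```

## The scientific problem

Within a fish species, whole-animal physiological rates follow power laws of
body mass, `rate = a * BM^b`, which become linear after log transformation:
`ln(rate) = ln(a) + b * ln(BM)`. The exponent `b` (typically 0.8--0.9 for
fish metabolic rates) determines whether large individuals keep
proportionally less aerobic capacity than small ones, and whether acute
warming changes that balance. allometherm implements the full analysis chain
used to ask this question with intermittent-flow respirometry and maximum
heart-rate (fHmax) thermal ramps:

1. **respirometry** — raw dissolved-O2 traces become per-cycle oxygen-uptake
   rates (MO2) and trial summaries: maximum and resting metabolic rate
   (MMR, RMR), absolute and factorial aerobic scope (AAS = MMR − RMR,
   FAS = MMR / RMR);
2. **cardiac thermal tolerance** — per-degree fHmax series become the
   Arrhenius breakpoint temperature (T_AB), the peak (T_PEAK, PEAK_fHmax)
   and the arrhythmia temperature (T_ARR);
3. **allometry** — both feed ln--ln scaling models: linear mixed models with
   per-individual random intercepts for repeated measures, ordinary least
   squares for one-off traits; candidate fixed-effect structures are
   compared by BIC, effects tested with Type II Wald chi-square and
   Tukey-adjusted temperature contrasts;
4. **thermal metrics** — mass-normalized group means at a reference size,
   interval Q10 sensitivities, and the Fick-equation slope decomposition
   `b_MR = b_Vs + b_fH`.

A seeded synthetic-data generator produces studies with known latent truth so
every stage can be tested end to end without animal data.

## Respirometry model and choices

Within a sealed measure phase, dissolved O2 declines linearly; the slope
`m_fish` (mg L⁻¹ min⁻¹), corrected for microbial background respiration and
scaled by the net water volume, gives the oxygen-uptake rate

`MO2 = (|m_fish| − |m_background|) · V_net`  (mg O2 min⁻¹).

Choices a user should know:

* **Trimming and quality.** The first 60 s of each measure phase (mixing) are
  discarded; a usable regression needs ≥ 180 s and R² > 0.96
  (`r2_threshold`). Rejected cycles are retained with a machine-readable
  reason (`too_short`, `degenerate`, `r2_below_threshold`), never silently
  dropped.
* **Net volume.** `V_net = chamber volume − fish mass / (1 kg L⁻¹)`: the fish
  displaces its own volume of water.
* **Background correction.** Background slopes are measured in the empty
  chamber before and after a trial; between those anchors the correction is
  interpolated linearly in time, a minimal model of microbial growth drift.
  A pre/post mean and a per-trial constant are special cases (equal
  anchors).
* **MMR and RMR.** MMR is the maximum MO2 over accepted cycles of ≥ 180 s,
  with every cycle (post-chase and overnight) a candidate, because
  spontaneous overnight activity frequently produces the true maximum. RMR
  is an order statistic: the mean of the 10 lowest accepted values after
  discarding the 5 lowest, robust to both residual activity and occasional
  under-readings. The identities AAS = MMR − RMR and FAS = MMR / RMR are
  exact; a trial with RMR ≥ MMR is reported with a warning flag, not
  clamped. Trials with fewer than 15 accepted cycles yield no summary (the
  pipeline skips them with a notice — incomplete individuals are a normal
  feature of such studies).

## Cardiac breakpoint model and choices

fHmax rises with acute warming, slows at T_AB, peaks at T_PEAK and fails at
T_ARR. On Arrhenius axes (x = 1000/T_K, y = ln fHmax) the rising limbs are
near-linear, so T_AB is the knot of a continuous two-segment regression.

* **Data window.** Only pre-arrhythmia observations enter the transform, and
  the breakpoint regression uses the rising limb (observations up to and
  including T_PEAK): T_AB describes the slowing of the rise, and a
  two-segment model cannot also represent the post-peak decline.
* **Knot search.** The knot is profiled over a dense deterministic grid
  (midpoints between consecutive x values plus 50 uniform candidates per
  interval, at least `min_points_per_segment = 2` points per side) and then
  refined by golden-section search in the bracketing interval. This is
  deliberately exhaustive rather than iterative: at 7--13 points per series
  the grid is cheap, deterministic, and verifiable against a brute-force
  oracle, which the test suite does on every series it generates.
  A 3-points-per-side rule was evaluated and rejected: with ~7--10
  rising-limb points it confines the admissible knot to the middle of the
  ramp and, in about a fifth of simulated series, excludes the true T_AB
  outright, destroying interval coverage.
* **"Statistically identified."** A parametric bootstrap (default
  `n_boot = 100`) of the single-line null: simulate Gaussian data from the
  fitted one-segment model, refit both models, and compare the
  likelihood-ratio-style statistic `n·log(RSS0/RSS1)`; p < 0.05 declares the
  breakpoint identified.
* **Confidence interval.** The 95% CI inverts the RSS profile: all candidate
  knots whose profile RSS stays within a `2·F(0.95; 2, n−4)` acceptance band
  of the minimum, with endpoints converted to °C. The two-parameter band
  reflects the non-regular knot/slope-change pair. We first implemented knot
  percentile bootstraps (plain, reflected, with sigma-chi-square draws, and
  with bootstrap-calibrated thresholds); simulated coverage at per-degree
  sample sizes was 61--81%, against 95% for the profile band, so the profile
  interval is the package's method and the bootstrap is kept for the
  identification test. Fits are excluded when unidentified or when the CI
  half-width exceeds `ci_limit_c = 1.5` °C; tightening that limit can only
  shrink the included set.
* **Tie-break.** T_PEAK is the lowest temperature attaining the maximum
  fHmax (the conservative, earliest-peak reading).

## Scaling models and inference

Repeated-measures responses (MMR, RMR, AAS, FAS, fHmax) use
`ln(response) ~ 0 + temperature + ln(mass) + (1 | fish)` fitted by maximum
likelihood (`lme4`), giving one common exponent and absolute per-temperature
intercepts — the form in which such coefficient tables are published.
ML rather than REML because BIC comparisons span fixed-effect structures.
One-off traits (T_AB, T_PEAK, T_ARR, PEAK_fHmax, ventricle mass) use OLS.

* **Inference.** Wald 95% intervals; Type II Wald chi-square tests
  (`car::Anova`) on a reference-coded refit (cell-means coding is kept for
  reporting but is unsuited to marginality-respecting tests); all-pairs
  temperature contrasts through `emmeans` with asymptotic degrees of freedom
  and Tukey adjustment. Kenward--Roger small-sample degrees of freedom are
  deliberately not used; at these sample sizes (≈ 240 observations, ≈ 80
  groups) the asymptotic and small-sample answers agree to well within
  reporting precision, and the asymptotic route keeps the inference
  estimator-agnostic.
* **Degenerate designs.** Zero random-intercept variance is flagged
  (`singular`), not hidden; a data set without within-individual replication
  falls back to OLS with a warning, which is also the correct limit.
* **Mass normalization.** `value · (ref/mass)^b / ref` rescales a
  whole-animal rate along the fitted exponent to the reference size
  (default 65 g, the cohort's mean) and expresses it per unit reference
  mass. Group means are model-predicted values at the reference mass
  (`exp(ln a_T + b·ln ref)/ref`), the quantity that published group means
  correspond to; raw per-fish normalized means are also derivable but the
  model-predicted value is canonical.
* **Q10.** `(R2/R1)^(10/(T2−T1))`. The source formula for this quantity is
  sometimes typeset with a dropped parenthesis; the standard form above is
  used, and it satisfies the geometric chaining identity across
  sub-intervals, which the tests verify.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions the package is designed
around: 83 fish drawn log-uniformly over 5--700 g (even coverage of the
ln-mass axis that all fits use); repeated respirometry at 12/16/20/22 °C;
whole-animal MMR and RMR following the published coefficient table
(b ≈ 0.81 with temperature-specific intercepts); per-fish normal random
intercepts (SD 0.10) and lognormal trial residuals (SD 0.10) on the ln
scale — the source reports no variance components, so these are stated
assumptions of plausible magnitude, producing interval widths of the same
order as the published standard errors; microbial background at 10% of the
resting rate; chamber volumes targeting a net-volume-to-mass ratio of
40 L kg⁻¹ (within the protocol's 19.2--93.9 band, enlarged automatically so
O2 stays above 70% air saturation, itself computed from the Benson--Krause
solubility model at salinity 33); 62 flush/measure cycles of 10 + 5 min with
an MMR episode in the first post-chase cycle and once overnight; O2 sensor
noise of 0.005 mg L⁻¹, consistent with optical-sensor precision (at
0.01 mg L⁻¹ the largest fish's resting regressions at 12 °C fall below the
R² filter wholesale, contradicting the protocol's own premise of > 60 usable
measurements per trial).

Cardiac series follow a piecewise-linear Arrhenius curve anchored at the
published 16 °C fHmax scaling law, with limb slopes set by the reported
thermal sensitivities (Q10 2.0 below T_AB, 1.35 above), breakpoints
T_AB/T_PEAK/T_ARR as power laws of mass with lognormal individual scatter
(SD 0.02), a post-peak decline of 0.05 ln units per °C anchored at the last
rising ramp step (so the observed series turns over exactly once on the
1 °C observation grid), and observation noise of SD 0.02 on ln fHmax. A
consistency check, not a fitted quantity: the implied 65-g peak
ln(fHmax) ≈ 4.93 against the published mass-independent value 4.916.

Zero-noise settings make every generated quantity equal its closed-form
model value, which is what the exact end-to-end recovery tests exercise.

What passing tests on these data do **not** show about real data: the
generator's residuals are homoscedastic and lognormal with no autocorrelated
sensor drift, no activity cycles beyond the two injected MMR episodes, no
temperature control error, no tank or batch effects, and its MMR/RMR share
exact exponents — so results that depend on real-animal departures from the
shared-exponent law (for example an aerobic-scope exponent exceeding the
MMR exponent, or origin differences in RMR) are structurally outside what
synthetic recovery can confirm. The suite demonstrates estimator
correctness, not biological generality.

## Numerical and reproducibility choices

* One root seed drives everything; each stage (cohort, traces, cardiac,
  ventricles, bootstrap, scaling) derives its own sub-stream, and each
  simulated response its own offset, so adding a stage never perturbs
  another's draws. Reruns are byte-identical.
* BIC ties break by candidate order; ΔBIC is reported to one decimal.
* Degenerate regressions (zero O2 variance) are rejected cycles, not errors;
  too-short cycles likewise.
* Problem sizes in the shipped tests are the package's choices for a
  thorough-but-quick suite: parameter-recovery runs use 100 seeds at the
  study's sample sizes (83 fish / 238 observations mixed-model fits; 30-fish
  simple fits), interval-coverage runs use 200 generated cardiac series, and
  end-to-end runs use 5--6 fish cohorts, which already exercise every code
  path.

## Known limitations

* T_ARR is resolved to the 1 °C ramp grid, as in the underlying protocol;
  the latent arrhythmia temperature is continuous.
* The breakpoint CI is a profile interval on a bounded candidate range; for
  series whose true knot lies within two points of the ramp ends it cannot
  be recovered.
* Between-individual correlation of MMR and RMR intercepts is not modelled
  (independent draws); FAS variance in synthetic data is therefore somewhat
  larger than if the two were positively correlated.
* The per-degree fHmax mixed model treats each °C as a categorical level;
  with breakpoints shifting by mass, the common mass exponent is a
  descriptive summary, not a structural parameter of the piecewise curve.
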