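---
title: "Restitution dispersion from the ECG: models, estimators and the in-silico experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restitution dispersion from the ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restdisp)
```

This vignette is the package's own account of the science it implements:
the models, the estimators, the numerical choices, and what the validation
on synthetic data does and does not establish.

## 1. The quantities

Dispersion of APD restitution is the spatial heterogeneity in how action
potential duration responds to a change in pacing rate.  On the body-surface
ECG its accessible surrogate is the T-peak-to-T-end interval, Tpe: the T
apex reflects the earliest-repolarizing transmural layer (epicardium), the
T end the latest (midmyocardial M cells), so the *rate sensitivity* of Tpe
tracks the spread of local restitution slopes.  The index is

$$\mathrm{DRest} = \frac{\Delta T_{pe}}{\Delta RR}$$

between stationary rate states.  Alongside it the package computes
Fridericia- (and Bazett-) corrected QT and Tpe, and the rate-adaptation
times $t_{90}^{QT}$ and $t_{90}^{Tpe}$: the time for the interval to
complete 90% of its adjustment after an abrupt heart-rate change.

## 2. The rate-memory model

Repolarization intervals depend on the *history* of RR (hysteresis), so a
beat's Tpe cannot be paired with its instantaneous RR.  We model

$$y_k = g\!\left(z_k\right) + \varepsilon_k, \qquad
  z_k = \sum_{i=0}^{L-1} w_i\, rr_{k-i}, \quad w_i \ge 0, \ \sum_i w_i = 1,$$

with $g(z) = a z + b$ linear and the weights spanning a 300 s history
window (`window_s`, the default; shorter windows truncate slow adaptation,
longer ones waste data).  Two weight families are fitted:

* **Free FIR profile.**  Weights live on a graded lag basis — single-beat
  resolution for the first 10 lags, then bins widening geometrically
  (factor 1.25, about 25 parameters over a 370-lag window).  Estimation is
  alternating least squares: ordinary least squares for $(a, b)$ given the
  weights, then a nonnegativity- and sum-to-one-constrained least-squares
  step for the weights (FISTA with projection onto the weighted simplex,
  150 inner iterations), iterated until the residual RMSE changes by less
  than `1e-4` relative (at most 50 outer iterations).  A second-difference
  roughness penalty (`lambda = 1e-3`, scale-matched to the normal
  equations) stabilizes the profile; it is switchable.
* **Exponential profile.**  A single-time-constant kernel, with $\tau$
  found by 1-D minimization of the profiled residual RMSE (the inner
  $(a,b)$ fit is closed-form).  This is the same family the synthetic
  generator uses.

With `profile = "auto"` both are fitted and the lower-AIC model is kept.
The exponential member wins when the data carry no evidence of a more
complex profile — and being truncation-free it gives unbiased $t_{90}$ for
slow adapters — while the free FIR wins decisively for, e.g., a memoryless
target (its fitted profile collapses to a delta at lag 0).  We consider the
pair a single model family with two parameterizations rather than two
competing methods.

$t_{90}$ is the 90% point of the filter's step response: the lag at which
the cumulative weight first reaches 0.90 (linearly interpolated), converted
to seconds with the record's mean RR; for the exponential profile the
closed form $\tau \ln 10$ is used.  A record is **degenerate** when the
1-minute-smoothed RR spans less than 10 ms (no rate information; $t_{90}$
is reported missing) and **low-confidence** below 50 ms — the practical
reading of the requirement that 10–15 minutes with real heart-rate changes
are needed.

## 3. DRest as a regression slope

The two-state ratio generalizes, under the linear stationary curve, to the
slope of Tpe on the surrogate $z$; the package reports the Theil–Sen
estimate (median of pairwise slopes — robust to residual delineation
outliers) with a seeded 1000-resample bootstrap CI over beats, and OLS as a
cross-check.  For records longer than 650 beats the pairwise median uses
200,000 random pairs.  DRest is reported as one subject-level scalar over
the subject's observed RR range; no attempt is made to resolve DRest(RR)
pointwise within a single recording.  Estimates are flagged when fewer than
100 joint-valid beats or less than 50 ms of surrogate-RR range are
available.

Per-beat corrected intervals (QTc, Tpec) use the beat's own RR; the
subject-level value is the mean over valid beats (median switchable) —
the mean was chosen as the conventional default since nothing in the
study design argues otherwise.

## 4. Delineation

QRS detection: 5–25 Hz zero-phase band-pass, squared derivative integrated
over 120 ms, peaks above 20% of a rolling upper quantile, 200 ms refractory
period, anchors refined to sub-sample precision by a quadratic fit at the
band-passed R apex.  Delineation runs on cubic-spline 1 kHz upsamplings of
stage-filtered traces (40 Hz low-pass for the QRS-onset search, 15 Hz for
the T wave; both zero-phase so landmark positions are unbiased):

* **QRS onset** — earliest sustained (≥5 ms) crossing of 2% of the local
  maximal slope, searched 60 ms back from R, floored at 4x the PR-segment
  slope noise.
* **T apex** — extremum of the smoothed T window, which spans 80 ms after
  R to `min(600 ms, 0.7 RR)` (the cap avoids the next beat's P wave at
  fast rates), refined by a least-squares parabola over ±10 ms of the
  wide-band trace.
* **T end** — tangent method: the steepest post-apex tangent intersected
  with the isoelectric baseline (median of the PR segment 75–45 ms before
  R).  The tangent method is the dominant convention for Tpe work, which
  is why it is also applied, identically, to the simulated pseudo-ECG.

Beats failing any search, with T amplitude below 0.05 mV on the wide-band
trace, or with windows clipped at the record edge are invalid with missing
measurements.  `clean_series()` additionally rejects RR outside
300–2500 ms, QT/Tpe more than 5 MAD from a 60-beat running median (the MAD
is floored at 1 ms so that noise-free series are not mass-flagged), and
ectopic-compensatory RR pairs (>30% change followed by >30% reversal).

Lead selection ranks candidates (default V2–V4) by an SNR defined as the
ratio of median-beat-template power to residual power in dB, with
correlation alignment within ±5 samples; the definition is one of several
monotone-equivalent choices and is fixed here for reproducibility.  Lead
choice is per subject.

## 5. The synthetic-data generator

The generator *defines the study conditions* for validation:

* RR: piecewise-constant levels (default schedule: steps every ~6 min,
  levels within ±15% of the subject mean — sustained changes long enough
  for memory transients to complete) plus AR(1) variability (lag-1
  correlation 0.8, s.d. 15 ms) and an optional 0.25 Hz respiratory
  component; floored at 310 ms.
* Intervals: an exponential memory filter with time constant
  $t_{90}/\ln 10$ produces $z$; then
  $T_{pe} = tpe_0 + \mathrm{DRest}_{true}\,(z - 1000)$ and
  $QT = QTc_{true}\,(z/1000)^{1/3}$, plus Gaussian measurement noise
  (default 2 ms).  The 1000 ms reference makes $tpe_0$ directly
  interpretable.
* Waveforms: compact-support Gaussian lobes for P/Q/R/S and an asymmetric
  T whose fall-side width is chosen so that the *tangent-method* T end
  lands exactly at the requested interval (the truncated-Gaussian tangent
  factor is $2 - e^{1/2 - k^2/2}$ for support half-width $k\sigma$,
  $k = 3$); QRS onset coincides with the exact support edge of the Q lobe.
  Landmarks are therefore analytic, and delineation can be graded in
  samples.
* Cohorts: healthy DRest ~ uniform(0.025, 0.058); TdP DRest ~
  uniform(0.18, 0.22); healthy adaptation times uniform(27, 277) s (whose
  20–80 percentiles are exactly 77–227 s) and QT scales from a skewed
  mixture (85% uniform(378, 409), 15% uniform(436, 467)) chosen so the
  20–80 band sits near 384–407 ms while the full range reaches the high
  values seen in whole-range reports; with the default three TdP subjects
  the published individual QTc/RR/adaptation values are assigned directly.

The generator deliberately matches the estimator's exponential-memory
assumption, so recovery tests measure estimation error, not model
mismatch; mismatch robustness is probed separately through the free-FIR
path and the delineation noise tests.  What passing these tests shows is
that the pipeline is *correct and well-calibrated under its own model*;
real ECGs add T-wave morphologies, nonstationary noise, ectopy and
drug-kinetic drift that no synthetic suite certifies.

## 6. The in-silico experiment

Membrane kinetics are the ten Tusscher–Panfilov (2006) human ventricular
model — 19 state variables per cell with endo/M/epi parameter variants —
integrated with forward Euler for potential and concentrations and
Rush–Larsen exponential updates for all gating variables (including the
calcium-release gate, which has closed-form kinetics), `dt = 0.02 ms`
(0.05 ms is the guard limit).  The implementation was verified against an
independent from-scratch implementation of the published equations (scipy
LSODA, rapid-buffering derivative form): steady-state APD90 at CL 1000 ms
agrees within 0.4 ms for all three cell types and under 50% IKr block, and
the resting state drifts less than 0.2 mV over 10 unstimulated seconds.

Tissue is a 1D monodomain cable: 100 nodes at 0.15 mm (15 mm wall),
endo 25% / M 35% / epi 40% (a canonical transmural split; the proportions
are configurable), no-flux ends, stimulation (−52 pA/pF, 1 ms) at the
endocardial end, explicit central-difference diffusion under operator
splitting.  The diffusion default, 0.0006 cm²/ms, is calibrated to a
transmural conduction velocity of ≈47 cm/s at this discretization — within
the 40–70 cm/s range reported for human transmural propagation.  The
pseudo-ECG is the standard far-field integral
$\phi \propto -\int \partial_x V\, \partial_x(1/r)\, dx$ at an axial
electrode 2 cm beyond the epicardial end; its T wave is delineated with the
same tangent method as clinical traces.

The dynamic restitution protocol paces the strand to approximate steady
state at each stationary cycle length in 500–1500 ms, records per-node
APD90 (activation at maximal dV/dt to 90% repolarization, on a 1 ms grid)
and pseudo-ECG Tpe, and differentiates by centered finite differences
(one-sided at the grid ends): `alpha1`/`alpha2` are the extreme per-node
slopes, `drest_spatial` their difference, and `drest_ecg = dTpe/dRR` the
ECG-visible index.  Conduction block at a level flags it rather than
erroring.  Two profiles exist: *full* (50 pre-beats) and *fast* (10
pre-beats, 100 nodes, coarse grid) — the fast profile is what the test
suite and the acceptance script run, and its results should be read as
scaled-down: about 3 minutes per condition on one CPU, with steady-state
residuals of order a few tenths of a millisecond in APD90.

Two numerical honesty notes.  First, the published model's dynamic
restitution *saturates* above RR ≈ 1250 ms: APD90 can decrease by a few
tenths of a millisecond between 1250 and 1500 ms (this persists at 50
pacing beats and in the independent implementation).  Monotonicity of
APD90 in RR is therefore asserted within a 1 ms measurement-resolution
tolerance, not strictly.  Second, with only 10 pre-beats the absolute APD90
level is 1–2 ms from its fully accommodated value; all reported contrasts
(block vs control, short-RR vs long-RR) are computed within the same
profile so this bias largely cancels.

## 7. Cohort statistics

Percentiles are linear-interpolation (type 7) throughout.  The
Mann–Whitney U test is exact whenever feasible: the closed-form exact null
distribution without ties, full enumeration of label assignments (up to
10^6) with ties, and a tie-corrected, continuity-corrected normal
approximation beyond that; the two-sided p is twice the smaller one-sided
p, capped at 1.  Under complete separation at the study's group sizes
(25 vs 3) the exact two-sided p is 2/3276 ≈ 6.1e-4 — a useful floor to
keep in mind when comparing small-sample p-values across methods, since
approximate procedures can report smaller or larger values for the same
data.  Welch's t uses Satterthwaite degrees of freedom, with the
zero-variance degenerate cases defined explicitly (equal constant groups
give p = 1).  Group summaries report 20–80 percentile bounds, or min–max
for groups of at most 7 subjects, matching the convention of reporting
whole ranges for small groups.

## 8. Problem sizes and tolerances used in validation

The test suite fixes: 30-minute records (40 minutes for adaptation-time
recovery) at the generator defaults; slope recovery within 10% median
relative error at 2 ms noise and exact to 4 decimals noise-free;
$t_{90}$ within 15% of $\tau \ln 10$ in at least 80% of 20 seeded
replicates; delineation mean absolute error within one sample at 180 Hz;
cell-model APD90 within 5 ms of the independent reference; and the
control-condition drop of `drest_ecg` between RR 750 and 1100 ms within
0.02 ± 0.01.  These sizes keep the whole suite under about 15 minutes on
one CPU while leaving each estimator enough data to meet its stated
accuracy.

## 9. Known limitations

* The delineator targets monophasic upright T waves; biphasic or notched
  morphologies are out of scope, as are P-wave delineation and U waves.
* The memory model's stationary curve is linear; hyperbolic or parabolic
  families are an extension point behind the same interface.
* DRest from a clinical record is a single slope over the observed RR
  range; rate dependence of DRest itself is only resolved in the
  simulator, where stationary pacing is available.
* The 1D strand stands in for a 2D transmural slice: it reproduces
  transmural dispersion mechanisms but not apico-basal gradients, wall
  curvature, or fiber rotation, and its pseudo-ECG amplitudes are
  arbitrary units.
* Drug effects are reduced to a 50% IKr-conductance scale factor; no
  pharmacokinetics, multichannel effects, or beta-blockade.
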