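# restdisp

Ventricular repolarization biomarkers from ECG beat series, built around the
restitution-dispersion index **DRest**, with a companion in-silico experiment
on a transmural strand of human ventricular myocytes.

## The problem

Class III antiarrhythmic drugs such as sotalol block the rapid delayed
rectifier potassium current (IKr), prolong the action potential, and in a
small fraction of patients trigger Torsades de Pointes (TdP).  The standard
screening biomarker, the rate-corrected QT interval (QTc), is sensitive but
not specific: some patients develop TdP with a near-normal QTc.  Increased
*spatial dispersion of APD restitution* — how differently the action
potential duration at different ventricular depths responds to a change in
rate — is a more mechanistic candidate substrate.  On the surface ECG it can
be quantified as

```
DRest = dTpe / dRR
```

the rate of change of the T-peak-to-T-end interval (Tpe, a surrogate of
dispersion of repolarization) with the RR interval, evaluated between
stationary states.  Because free-living RR is never stationary, each beat's
Tpe is regressed against a **memory-compensated surrogate RR**,
`z(k) = sum_i w_i rr(k-i)`: a weighted average of the preceding RR intervals
(weights nonnegative, summing to one over a 300 s history window) fitted so
that `Tpe ~ g(z)` with a monotone stationary curve `g`.  The same filter
yields the rate-adaptation times `t90` — the time for QT or Tpe to complete
90% of its adjustment after an abrupt heart-rate change — as the 90% point
of the filter's step response.

The package provides:

* **I/O and delineation** — a CSV interchange dialect and a minimal WFDB
  (format 16) reader; SNR-based analysis-lead selection; QRS detection and
  T-wave delineation by the tangent method.
* **Rate-memory modelling** — `fit_memory_model()`, `surrogate_rr()`,
  `compute_t90()`.
* **Biomarkers** — `fridericia()`, `bazett()`, `estimate_drest()`
  (Theil–Sen slope with bootstrap CI), `subject_report()`.
* **Cohort statistics** — exact Mann–Whitney U (`mann_whitney_exact()`),
  Welch's t (`welch_t()`), 20–80 percentile tables, standardized separation
  distances.
* **Synthetic data** — seeded generators for RR processes with sustained
  heart-rate changes, beat series with known memory and slope structure,
  raw waveforms with analytically placed QRS/T landmarks, and two-group
  cohorts calibrated to published healthy/TdP biomarker ranges.
* **Tissue simulation** — the ten Tusscher–Panfilov (2006) human myocyte
  model (Rcpp) in a 1D transmural cable (endo → M → epi), dynamic
  restitution over stationary cycle lengths 500–1500 ms, pseudo-ECG readout,
  and the 50% IKr-block experiment (`dynamic_restitution()`,
  `tissue_config()`).

## Worked example

A synthetic cohort of 25 healthy subjects and 3 TdP-profile subjects,
calibrated to published biomarker ranges, analyzed end to end:

```r
library(restdisp)
res <- run_pipeline(run_config(n_boot = 0, seed = 1))
print(res)
```

```
Cohort pipeline: 28 subjects, 2 groups

Group summary:
        group  n mean_rr_ms_lo mean_rr_ms_hi drest_lo drest_hi qtc_ms_lo
1     healthy 25         803.6         920.7  0.03256  0.05197     390.4
2 tdp_sotalol  3         873.3        1141.9  0.18401  0.19634     436.3
  qtc_ms_hi t90_tpe_s_lo t90_tpe_s_hi t90_qt_s_lo t90_qt_s_hi tpec_ms_lo
1     412.0        134.3        189.4       129.7       187.7      81.66
2     550.2        203.8        215.0       204.4       216.6      88.86
  tpec_ms_hi
1      97.91
2     138.99

Discrimination tests:
  metric             comparison mwu_u     mwu_p mwu_method welch_t   welch_p
1  drest healthy vs tdp_sotalol     0 0.0006105      exact -33.459 5.164e-05
2 qtc_ms healthy vs tdp_sotalol     5 0.0097680      exact  -2.436 1.306e-01
```

Reading the output: estimated DRest separates the groups completely (healthy
20–80 band 0.033–0.052 versus TdP 0.18–0.20; the exact Mann–Whitney p under
complete separation at these group sizes is 2/3276 ≈ 6.1e-4), while the QTc
ranges overlap — one TdP-profile subject has a QTc of about 436 ms, inside
the healthy span — and Welch's t on QTc is far from significant (p = 0.13).
This is the qualitative pattern that motivates DRest as a stratifier.

Single subject, from raw waveform to biomarkers:

```r
p   <- subject_profile(drest_true = 0.05, t90_true_s = 100, seed = 7)
bs  <- generate_beat_series(p, duration_s = 1800)
rec <- synthesize_waveform(bs[1:100, ], fs = 180)     # raw ECG, 180 Hz
lead <- rank_leads(rec)$lead_name[1]
del <- delineate(rec, lead, detect_beats(rec, lead))  # RR/QT/Tpe per beat
subject_report(bs, "S01", "healthy")                  # full-length series
```

And the in-silico arm (scaled-down profile):

```r
ctrl  <- dynamic_restitution(tissue_config_fast(gkr_scale = 1.0))
block <- dynamic_restitution(tissue_config_fast(gkr_scale = 0.5))
drest_ecg_at(ctrl, 750) - drest_ecg_at(ctrl, 1100)
```

A thin command-line front-end with `ingest`, `delineate`, `adapt`,
`biomarkers`, `compare`, `simulate` and `synth` subcommands is installed at
`system.file("exec", "restdisp.R", package = "restdisp")`.

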