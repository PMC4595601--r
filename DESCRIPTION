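Package: restdisp
Title: ECG Restitution-Dispersion Biomarkers and Transmural Tissue Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of ventricular repolarization biomarkers from ECG
    beat series: rate-corrected QT and T-peak-to-T-end intervals (Fridericia,
    Bazett), rate-adaptation times (t90) of QT and Tpe via a weighted
    rate-memory filter, and the restitution-dispersion index DRest, the slope
    of Tpe against a memory-compensated surrogate RR.  Includes T-wave
    delineation (tangent method), cohort discrimination statistics (exact
    Mann-Whitney U, Welch's t, percentile tables), seeded synthetic-data
    generators for validation, and a companion in-silico experiment: dynamic
    restitution of a 1D transmural strand of ten Tusscher-Panfilov (2006)
    human ventricular myocytes with pseudo-ECG readout, in control and under
    50% IKr block.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
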