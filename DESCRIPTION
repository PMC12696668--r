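Package: tusmep
Title: Analysis Pipeline for TUS-TMS Corticospinal Excitability Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of combined transcranial ultrasound
    stimulation (TUS) and transcranial magnetic stimulation (TMS)
    experiments on motor cortex. Provides trial-level motor-evoked
    potential (MEP) preprocessing with iterative Grubbs outlier removal,
    pre-contraction and noise screening; excitability summaries (SICI,
    ICF, baseline-normalised amplitudes); ultrasound pulse-train and
    intensity dosimetry (Isppa, mechanical index, duty cycle, coupling
    depth bookkeeping); acoustic-focus targeting metrics from 3D
    intensity volumes (full-width half-maximum focus, M1 region-of-
    interest overlap, landmark distances, axis-shift tests); trial-level
    linear mixed models with Satterthwaite degrees of freedom and
    repeated-measures ANOVA with Greenhouse-Geisser correction; and
    noncentral-F power analysis for repeated-measures designs. A seeded
    synthetic-cohort generator emulates the statistical structure of
    such studies so every stage is testable without participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
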