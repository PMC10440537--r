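Package: prtms
Title: EEG Alpha-Band Parametrization and Personalized rTMS Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG spectral biomarker analysis and
    EEG-guided personalized repetitive transcranial magnetic stimulation
    (PrTMS) planning. Computes Welch power spectra on a fixed 0.1 Hz grid
    over 2-20 Hz, parametrizes the alpha-band peak per lead (center
    frequency, amplitude, full width at half maximum), estimates the 1/f
    aperiodic component of region-averaged spectra by iteratively
    reweighted robust regression in log-log space, derives the intrinsic
    alpha frequency from occipital leads and plans stimulation targets and
    session schedules, scores PCL-5/HAM-A/HAM-D psychometrics with
    responder classification, and runs the cohort-level statistics
    (change-from-baseline t-tests, binned sign tests, mixed repeated
    measures ANOVA, threshold-exceedance proportions, Fisher exact tests).
    A seeded synthetic-cohort generator emulates responder and
    nonresponder spectral and symptom dynamics so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
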