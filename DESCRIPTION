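Package: septrial
Title: Single-Trial Median-Nerve Somatosensory Evoked Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for eliciting and quantifying robust
    single-trial median-nerve somatosensory evoked potentials (SEPs). Provides a
    seeded generator of synthetic stimulation sessions (SNAP/CMAP recruitment with
    strength-duration thresholds, jittered stimulus trains, 19-channel EEG with
    embedded P50/N70 components over 1/f background), nerve/muscle response
    processing (band-pass filtering, epoching, background estimation, recruitment
    curves, target-intensity selection, afferent-excitation maintenance), EEG
    preprocessing (notch and band-pass Butterworth filtering, surface Laplacian,
    epoching with baseline correction, trial/channel rejection), averaged and
    single-trial SEP analysis (P50/N70 peaks, windowed RMS features, ROC AUC
    separability), and a repeated-measures statistics battery (SNR, coefficient of
    variation, r-squared topography, Friedman test with exact small-sample p,
    Kendall's w, Wilcoxon signed-rank with Holm correction, Lilliefors normality,
    and ICC(2,1) test-retest reliability with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
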