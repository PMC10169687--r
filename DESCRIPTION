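Package: eegpsi
Title: Spatial Correlation of Infraslow EEG Amplitude Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying long-range spatial correlations of the
    infraslow (0.05-0.1 Hz) amplitude fluctuations of band-limited EEG
    oscillations. Implements the instantaneous phase-difference spatial
    correlation statistic psi and its per-condition median M-psi, the
    surrounding signal chain (edge trimming, Hamming-window FIR band-pass
    with zero-phase application, spherical-spline surface Laplacian,
    Hilbert envelopes and envelope-band phases), a region-pair group
    screen based on one-tailed Wilcoxon rank-sum tests with
    Benjamini-Hochberg false discovery rate control, a leave-one-subject-out
    median-closeness discrimination procedure, and a synthetic resting-state
    cohort generator with controllable inter-channel envelope-phase coupling
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
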