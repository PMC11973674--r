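Package: coiwave
Title: Current-of-Injury Dynamics in Intracardiac Electrograms After
    Cardiac Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies ablation-induced changes in bipolar and unipolar
    intracardiac electrograms (iEGMs). Detects QRS complexes with an
    adaptive slope-threshold detector, isolates per-beat atrial windows,
    decomposes 10-second signal segments with a Daubechies-6 discrete
    wavelet transform into dyadic frequency sub-bands, and tracks
    peak-to-peak amplitudes of the high-frequency (63-500 Hz) content of
    bipolar iEGMs and the low-frequency (1-16 Hz) current-of-injury
    content of unipolar iEGMs over time. Provides linear mixed-effects
    group comparisons of post-ablation recovery dynamics, per-timepoint
    two-group tests, and an early lesion-transmurality call from
    unipolar current-of-injury recovery after pulsed field ablation.
    Includes a synthetic multichannel signal generator with ground-truth
    beat times, ablation effect trajectories, amplifier saturation and
    movement artifacts, so the whole pipeline is testable without animal
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    generics,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
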