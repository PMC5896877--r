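Package: icmsmap
Title: Design and Analysis of Intracortical Microstimulation Percept-Mapping
    Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing single-electrode
    intracortical microstimulation (ICMS) percept-detection experiments in
    human somatosensory cortex. Provides schedule generators for
    amplitude-mapping blocks with catch-trial interleaving and
    electrode-adjacency constraints, charge-safety validation for biphasic
    pulse trains, a calibrated generative simulator of per-trial percept
    reports (detection, modality, descriptor, receptive field, intensity,
    duration), self-contained nonparametric statistics (tie-corrected
    Kruskal-Wallis, two-sample Kolmogorov-Smirnov, Pearson correlation,
    Dunn-Sidak correction, Gaussian kernel density estimation), bootstrap
    resampling of modality proportions with slope distributions, a
    permutation null for trial-history dependence, and an end-to-end
    analysis pipeline producing summary counts, electrode modality
    classes, descriptor tables and impedance, intensity and duration
    analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
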