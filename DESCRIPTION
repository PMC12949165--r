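Package: gaitmep
Title: Corticospinal Excitability and Dynamic Stability Analysis for
    Laterally Destabilised Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing corticospinal excitability and gait
    stability during treadmill walking with mediolateral platform
    oscillations. Detects heel strikes and toe-offs from heel-marker
    kinematics, computes spatiotemporal gait metrics, estimates the local
    divergence exponent (Rosenstein's algorithm) from thorax velocity,
    fits the linear foot-placement-control model over the step cycle,
    extracts motor evoked potentials (MEPs) and MEP gain from EMG around
    transcranial magnetic stimulation pulses, reconstructs continuous
    gait-cycle profiles from sparse stimulation samples by von Mises
    (circular) kernel regression with density weighting, and compares
    conditions with cyclic cluster-based permutation tests. Includes a
    synthetic-session generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
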