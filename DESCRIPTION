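Package: gazecraft
Title: Task-Dependent Eye-Movement Analysis for Art-Viewing Studies
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing eye-movement recordings from task-driven
    image-viewing experiments. Detects saccades and fixations from raw gaze
    samples with combined velocity/acceleration thresholds, applies blink and
    trajectory-artifact exclusion rules, computes leave-one-out Normalized
    Scanpath Saliency (NSS), spatial dispersion and duration-weighted fixation
    density maps, and fits the associated linear mixed models with
    likelihood-ratio tests as well as repeated-measures correlations. Includes
    a synthetic gaze-study generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
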