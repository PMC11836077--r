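Package: syncadapt
Title: Speech Motor Adaptation and Vocal Convergence During Synchronous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying speech motor adaptation to formant
    perturbations delivered during synchronous (choral) speech, where a
    concurrent vocal-convergence process may aid or oppose adaptation.
    Provides mel-scale F1-F2 vector geometry for perturbations specified by
    joint magnitude and angle, the signed vector-projection adaptation
    statistic with sentence-matched baseline normalisation, convergence and
    adaptation-convergence congruency measures, per-participant
    adapter/follower classification, and group contrasts via linear mixed
    models. Includes a synthetic-cohort simulator built on a single-state
    sensorimotor learning model with auditory-target updating, an LPC-based
    formant extraction stage validated on synthesized vowels, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
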