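Package: avchoice
Title: Audiovisual Localization Choices: Psychometrics, Inactivation
    Statistics, Neural Encoding, and Accumulator Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Analysis toolkit for two-alternative forced-choice audiovisual
    localization experiments in which subjects report the side of a visual
    and/or auditory stimulus by turning a wheel. Implements additive logistic
    psychometric models of choice with maximum-likelihood fitting and
    cross-validated bits-per-trial model comparison; shuffle-test inference for
    optogenetic inactivation effects on choices and model parameters, including
    pulsed-inactivation timing analysis; temporal-kernel (event-aligned ridge
    regression) encoding models of spike trains; population decoding, choice
    probability, d-prime and discrimination-time statistics; and a trainable
    linear integrate-to-bound accumulator driven by surrogate Poisson spike
    trains. Ships synthetic-data generators with the statistical structure the
    analyses assume, so the full pipeline runs without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
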