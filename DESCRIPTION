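Package: codamove
Title: Compositional Analysis of 24-Hour Movement Behaviours and Motor Competence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compositional data analysis of 24-hour movement
    behaviours (sedentary behaviour, light physical activity, and
    moderate-to-vigorous physical activity) in relation to fundamental
    movement skills in young children. Provides epoch-level accelerometer
    processing (cut-point classification, non-wear detection, wear-time
    inclusion rules), closure and isometric log-ratio (ilr) geometry on the
    three-part behaviour simplex, ilr multiple linear regression with
    covariates and type-II Wald tests, five-minute isotemporal substitution
    with confidence intervals, scoring of an adapted twelve-skill gross motor
    battery, and a seeded logistic-normal synthetic cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
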