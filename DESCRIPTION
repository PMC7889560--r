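Package: surrofrax
Title: Surrogate Country-Specific Fracture Probability Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs surrogate country-specific 10-year fracture probability
    models by pairing a reference country's age- and sex-specific hip fracture
    incidence with the index country's mortality, imputing major osteoporotic
    fracture incidence from hip incidence via reference ratio tables. A
    competing-risk probability engine computes 10-year probabilities of hip and
    major osteoporotic fracture for clinical-risk-factor/BMD profiles by exact
    integration over piecewise-constant hazards. Companion tools compare two
    models over a factorial risk-profile grid (correlation, fixed-knot piecewise
    regression, medians with nonparametric tolerance intervals) and project
    national hip fracture burden against population pyramids. A deterministic
    synthetic-data generator supplies Gompertz-shaped incidence, mortality,
    ratio and population fixtures so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
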