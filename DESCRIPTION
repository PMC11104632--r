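Package: noisefield
Title: Noise-Field Campimetry Stimulus Generation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for noise-field (snow-field) campimetry, a subjective
    visual-field screening method in which patients view dynamic random-dot
    noise and report regions that look non-flickering or shadowed. Provides
    seeded pseudorandom stimulus generation (xorshift and linear congruential
    generators), quantitative homogeneity and luminance quality control of
    frame sequences, Humphrey 30-2 visual-field abnormality classification
    (Anderson-Patella criteria, mean-deviation staging), hemifield agreement
    scoring of patient-drawn shadows with physiological blind-spot exclusion,
    and the exact statistics (exact McNemar, exact binomial, chi-square with
    adjusted residuals, Clopper-Pearson intervals) used to summarise paired
    detection-rate studies. A deterministic cohort expander and a seeded
    cohort simulator make every analysis stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
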