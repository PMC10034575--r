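Package: adaptidose
Title: Dosimetric Comparison of Online-Adaptive and Scheduled Radiotherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate online-adaptive radiotherapy (ART) against
    scheduled image-guided radiotherapy (IGRT) at the fraction and series
    level. Computes dose-volume histograms, coverage endpoints (D95/D98/D99,
    V95/V100, minimum dose) and the generalized equivalent uniform dose
    (gEUD) on per-fraction deformed target volumes; expresses them as
    normalized percentage deviations from the planning reference and as
    adaptation gains; performs displacement-field dose accumulation over a
    treatment series; applies an offline monitoring rule that flags series
    for a switch from IGRT to ART; and wraps the nonparametric comparison
    tests used for paired plan evaluation. A seeded simulator generates
    synthetic treatment series (conformal reference dose, interfractional
    rigid and elastic target deformations, re-conformed adapted plans,
    bladder- and rectum-like organs at risk) so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
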