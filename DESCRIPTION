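Package: couplemap
Title: Structure-Function Coupling of Brain Networks and Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives similarity and network-communication matrices (cosine
    similarity, shortest path length, communicability, search information)
    from weighted structural connectomes, couples them region-wise to
    condition-specific functional connectomes, characterizes coupling across
    task states, and predicts a phenotype such as general intelligence with
    the Basic and Expanded Node-Measure Assignment (NMA) cross-validated
    regression frameworks, including permutation-based significance tests and
    cross-sample model generalization. Ships a synthetic connectome-cohort
    generator with planted condition offsets, region-preferred communication
    measures, and region-by-measure phenotype associations so the full
    pipeline can be exercised and calibrated without access to restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    lme4,
    emmeans,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
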