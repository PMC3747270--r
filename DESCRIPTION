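Package: gwasdesign
Title: Power and Genomic Prediction Accuracy for Case-Control GWAS Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytical power calculations for genome-wide association
    studies under five experimental designs (quantitative or binary
    responses in population samples, binary or quantitative responses in
    ascertained case-control samples, and a cases-only quantitative
    mixture design), built on the liability threshold model and the
    non-centrality parameter of the one-degree-of-freedom association
    chi-square test.  Also computes expected genomic prediction accuracy
    for quantitative traits and for disease traits in population and
    ascertained case-control samples, including the observed-scale
    transformation of heritability under case-control ascertainment.  A
    simulation engine generates multilocus liability-threshold cohorts
    with optional case-control ascertainment, runs per-marker association
    scans for empirical power, and runs train/validate marginal-regression
    genomic prediction for empirical accuracy, so every closed form can be
    checked against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
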