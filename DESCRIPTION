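Package: bondmap
Title: Brain-Wide Mapping of Pair-Bonding Neural Networks from c-Fos Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for whole-brain immediate-early-gene (c-Fos)
    activity mapping in pair-bonding studies. Screens regions of interest with
    nested quasi-Poisson generalized linear models compared by ANOVA F tests
    calibrated against a permutation null, with false-discovery-rate control;
    reduces significant regions to an anatomically exclusive set over a
    hierarchical brain atlas; characterizes the resulting network by Ward
    clustering, non-metric multidimensional scaling and a connectome
    permutation test; relates brain activity to behavior through canonical
    correlation analysis with Wilks' lambda tests; and quantifies within-pair
    neural coordination with plain and partial Pearson correlations. Includes
    a synthetic-data generator that emulates the paired cohabitation design
    with overdispersed counts, planted partner effects and a pair-level shared
    latent, plus behavioral group tests and a generalized extreme studentized
    deviate (Rosner) outlier screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
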