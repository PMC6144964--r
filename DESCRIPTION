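Package: otoconnect
Title: Otolith Microchemistry Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of fish population connectivity from otolith
    elemental chemistry. Stage one infers natal (larval) sources from
    near-core laser-ablation chemistry by unsupervised random-forest
    proximity clustering with partitioning-around-medoids and Dunn-index
    selection of the number of clusters. Stage two assigns adults to a
    juvenile whole-otolith baseline by Bayesian mixed-stock analysis that
    propagates baseline uncertainty through a Gibbs sampler. Includes
    LA-ICP-MS calibration (blank subtraction, drift correction, internal
    standardization, Ca-ratio normalization), nonparametric spatial
    statistics (Kruskal-Wallis, Dunn post hoc with compact letter displays,
    Spearman trends, Wilcoxon matched pairs), supervised random-forest site
    discrimination with out-of-bag confusion and permutation importance,
    and a synthetic-data generator emulating a North Sea study design
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    clue,
    optparse
Config/testthat/edition: 3
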