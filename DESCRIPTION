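Package: phylothreat
Title: Expected Phylogenetic Diversity Loss and Threat-Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the expected erosion of phylogenetic
    diversity under probabilistic species extinctions and to relate it to
    the diversity and type of threats affecting species. Implements Faith's
    phylogenetic diversity (PD), expected future PD under independent
    per-species extinction probabilities derived from IUCN Red List
    categories, the relative loss statistic PDloss with whole-tree and
    per-clade permutation tests, three phylogenetic distinctiveness indices
    (fair proportion, equal splits, quadratic-entropy originality), double
    principal coordinate analysis (DPCoA) of threat types on patristic
    distances, correspondence analysis of threat-by-area and
    threat-by-habitat tables, threat co-occurrence (Phi) statistics,
    Moran's I autocorrelation under phylogenetic, geographic, or habitat
    proximities, structure-corrected permutation tests, and a synthetic
    data generator that emulates an imbalanced ultrametric phylogeny with
    phylogenetically structured threats and risk categories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
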