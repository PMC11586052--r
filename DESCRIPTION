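Package: endoniche
Title: Carbon-Use Phenotyping and Resource Niche Overlap for Foliar Endophytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Biolog SF-P2 community-level physiological profiling
    data for bacterial and fungal foliar endophytes. Parses and water-corrects
    96-well plate absorbance tables, computes per-isolate carbon-use metrics
    (niche width, total growth, growth efficiency, Pielou evenness), the
    directional pairwise niche-overlap statistic for sympatric isolate pairs,
    and a downstream inference battery (proportion tests, normality-routed
    two-sample tests with Benjamini-Hochberg correction, Bray-Curtis
    dissimilarity, PERMANOVA, PERMDISP with Tukey HSD, Mantel tests,
    phylogenetic-distance regressions, and kingdom-by-treatment mixed models).
    Includes a synthetic plate-data generator emulating the nested field
    design (treatments, plots, leaves, isolates) so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    ape,
    lme4,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
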