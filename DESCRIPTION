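Package: divpower
Title: Power Analysis and Sample-Size Planning for Microbiome Diversity Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and retrospectively assessing the statistical
    power of microbiome studies that compare groups through alpha diversity
    (observed richness, Faith's phylogenetic diversity, Chao1, Shannon,
    Simpson) or beta diversity (Bray-Curtis, Jaccard, unweighted and weighted
    UniFrac). Provides Kruskal-Wallis and PERMANOVA group tests with
    standardized effect sizes, closed-form power and sample-size calculations
    for the two-sample t and Wilcoxon-Mann-Whitney tests (asymptotic relative
    efficiency method) and balanced one-way ANOVA, an empirical-power engine
    that resamples pilot or simulated count tables with replacement, a
    synthetic community generator with presence/absence and differential
    abundance perturbation scenarios, and renderers for standardized power
    analysis reporting protocols.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
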