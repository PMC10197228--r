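Package: selscape
Title: Selection Scans and Landscape-Genetic Dissection of Climate Adaptation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed selection-signature statistics (Weir-Cockerham FST,
    nucleotide diversity and its log2 ratio, Tajima's D, cross-population
    extended haplotype homozygosity Rsb) and their composite selection score;
    percentile-based calling of positively selected regions and genes;
    genotype-environment association through covariance-corrected Bayes
    factors and redundancy-analysis outliers; bespoke geographic and
    sea-surface-temperature distance construction; and multivariable
    isolation-by-distance / isolation-by-environment dissection with
    single-factor OLS, regularized regression, generalized dissimilarity
    models and commonality analysis. Includes a stepping-stone forward
    simulator with planted hard sweeps and environmental clines that
    generates every input format the pipeline reads, for end-to-end
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    glmnet,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
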