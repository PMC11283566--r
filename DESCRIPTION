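Package: rhizoactive
Title: Active Rhizosphere Microbiome Analysis from Paired rRNA and rRNA
    Gene Amplicon Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies metabolically active taxa from paired 16S rRNA
    (cDNA) and 16S rRNA gene (DNA) amplicon count tables using per-sample
    rRNA:rRNA-gene count ratios with explicit handling of "phantom" taxa
    (cDNA detections without a DNA detection), after prevalence-based
    reagent-contaminant removal and rarefaction to even depth. Provides
    the downstream community statistics used for such data: Bray-Curtis
    dissimilarity, principal coordinates analysis, PERMANOVA with
    sequential sums of squares and permutation p-values, pairwise
    post-hoc PERMANOVA, PERMDISP multivariate dispersion tests,
    group-size-corrected phi-coefficient indicator taxon analysis with
    false-discovery-rate control, rarefaction-resampled richness, and
    baseline-similarity temporal regressions. A companion chemometrics
    toolkit covers metabolite feature tables: presence and interquartile
    range filters, log transformation, pareto scaling, PCA, partial
    least-squares discriminant analysis with variable-importance (VIP)
    scores, and top-VIP heatmap matrices. A seeded synthetic-data
    generator produces paired count tables, factorial metadata, negative
    controls, and metabolite matrices with known ground truth so every
    stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    car
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
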