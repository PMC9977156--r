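Package: homeoscan
Title: Homeobox Gene Discovery and Cluster Architecture in Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects candidate homeobox loci in genome assemblies by
    six-frame translated local alignment against a labelled homeodomain
    reference set, classifies loci into gene families by reciprocal best
    match with a percent-identity rule, reconstructs Hox/NK/PRD gene-cluster
    architecture (order, orientation, spans, tandem Shx arrays,
    rearrangements relative to canonical orders), tests transposable-element
    density enrichment in the Shx region of the Hox cluster (windowed
    densities, Wilcoxon rank-sum with Bonferroni correction), and contrasts
    pairwise homeodomain identity between clades. Includes a seeded
    synthetic-genome generator with ground-truth annotations so every stage
    can be validated without real assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
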