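Package: karyofuse
Title: Chromosome Fusion Detection and Comparative 3D-Genome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the consequences of chromosome fusions on
    genome architecture. Detects and classifies fusion events (tandem versus
    Robertsonian) from synteny blocks and assigns phylogenetic age classes;
    builds and balances Hi-C contact matrices (iterative correction), calls
    A/B compartments from the leading eigenvector of the observed/expected
    correlation matrix, detects TADs from insulation-score minima, and calls
    distance-stratified significant chromatin interactions with binomial
    statistics and FDR control; compares compartments, TADs and interactions
    between genomes through a homologous-bin map; mines long reads for
    centromeric satellite, telomeric-repeat and palindrome signatures at
    fusion sites; and implements a male-specific variant filter with neo-Y
    sequence curation and allele-specific expression testing. A synthetic-data
    generator produces genomes, fusion plans, Hi-C maps, long reads, genotype
    tables and allele counts with full ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    rtracklayer,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
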