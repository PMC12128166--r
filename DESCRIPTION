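Package: methylink
Title: Linking Bacterial DNA Base Modifications to Gene Expression
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline connecting SMRT-detected DNA base
    modifications to gene expression in bacterial genomes. Provides
    IUPAC motif scanning on circular chromosomes, classification of
    modification calls into canonical and non-canonical sets,
    chromosome-landscape statistics (GC content, GC skew, modified-base
    density, bootstrap Spearman correlation, region-bias Z scores),
    RPKM/TPM expression metrics with equal-size categorisation, and a
    start-codon-relative sliding-window contingency analysis with
    normalised linkage disequilibrium (D'), Benjamini-Hochberg FDR
    control and a full parameter-grid sweep. A synthetic-data module
    generates genomes, methylomes and two-condition expression tables
    with tunable coupling so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
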