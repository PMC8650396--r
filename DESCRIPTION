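Package: methylbench
Title: Benchmarking Toolkit for Multi-Assay DNA Methylation Call Sets
Version: 0.9.0
Authors@R:
    person("EpiBench", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative quality control of whole-methylome
    experiments. Reads and writes per-CpG methylation call sets in the
    six-column MethylDackel bedGraph dialect, merges strand-symmetric CpG
    records and technical replicates, normalizes call sets to a common mean
    coverage by binomial count thinning, and scores coverage, capture,
    conversion efficiency and annotation profiles. Calls per-site
    differential methylation between two groups of genomes with a binomial
    likelihood-ratio test and Benjamini-Hochberg correction, and summarises
    cross-assay concordance of differentially methylated sites. Evaluates
    normalized methylation microarray matrices with a per-site variance
    partition and derives a technical-noise threshold for low-varying
    probes from the genotype clusters of SNP control probes. A seeded
    synthetic-data generator emulates the statistical structure of
    multi-assay methylome benchmarking studies so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
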