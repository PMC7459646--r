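Package: methylRRBS
Title: Differential DNA Methylation Analysis for Reduced Representation
    Bisulfite Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of reduced representation bisulfite
    sequencing (RRBS) methylation calls: Bismark coverage-file import,
    per-sample coverage filtering, uniting of CpG sites across samples,
    per-CpG differential methylation by binomial logistic-regression
    likelihood-ratio tests with SLIM (sliding linear model) q-values,
    TSS-anchored promoter-tier region annotation with precedence-based
    unique labels, differentially methylated cytosine and gene calling,
    global methylation pattern exploration (variance filtering, PCA,
    t-SNE, Ward clustering), and three gene-set enrichment procedures
    (hypergeometric over-representation, pathway-wise Wilcoxon
    signed-rank, and a bootstrap Kolmogorov-Smirnov test against
    regional background). Includes a synthetic-data generator producing
    toy genomes, gene models and group-structured beta-binomial
    methylation counts with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
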