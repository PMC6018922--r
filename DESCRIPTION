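Package: dosagescan
Title: Gene Copy Number from Low-Coverage Read Depth, Allele Dosage, qPCR
    Validation, and Phylogenetic Dosage Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates gene copy numbers from low-coverage whole-genome
    sequencing read counts mapped to a coding-sequence reference, using a
    binomial sampling model with a per-sample linear GC-bias correction
    estimated by class-balanced resampling, and Bonferroni-corrected
    binomial confidence intervals to classify genes as single-copy,
    duplicated or absent.  Companion analyses quantify the contribution of
    duplicate copies to transcript abundance from per-SNP genome and
    transcriptome read depths, validate copy numbers against qPCR Ct
    values with efficiency correction (Pfaffl method), and test for
    correlated evolution of copy number and log transcript abundance
    across gene-family phylogenies with generalized least squares under
    Brownian-motion covariance.  A synthetic-data generator with known
    ground truth supports end-to-end verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
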