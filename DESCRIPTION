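Package: grpstat
Title: Gene Regulation Probability Statistics for Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based differential expression analysis for two-group
    transcriptomics data (microarray intensities or RNA-seq counts) using gene
    regulation probabilities. Expression profiles are mapped into a tri-state
    regulation space and the probability difference T = P(U) - P(D) between
    up- and down-regulation events is estimated either with a hard regulation
    confidence cutoff (GRP) or with a cutoff-free unbiased estimator (aGRP)
    built from exceedance proportions. Significance is assessed by label
    permutation or an asymptotic normal null, with Benjamini-Hochberg
    correction. Includes calibrated simulators for benchmarking (a two-normal
    design and a correlated gene-clump design), evaluation utilities
    (type-I error, power, sensitivity, specificity, AUC, accuracy,
    cross-dataset consistency), expression matrix readers/writers with probe
    collapsing and coefficient-of-variation filtering, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
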