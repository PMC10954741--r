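Package: cladealign
Title: Mapping Single-Cell Expression Profiles to DNA-Defined Tumour Subclones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic integration of independently sampled single-cell RNA
    and single-cell DNA sequencing data from the same tumour cell population.
    Cells profiled by scRNA-seq are assigned to copy-number-defined subclones
    (or, recursively, to clades of an scDNA phylogeny) with a multinomial
    expression model that learns, per gene, whether expression follows copy
    number (a dosage effect) or is copy-number independent. An optional
    binomial allele model exploits allelic imbalance at heterozygous SNPs, and
    both likelihoods can be combined into an integrated model sharing the
    clone-assignment latent. Includes a ground-truth simulator, benchmark
    metrics (accuracy, adjusted Rand index, AUC), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ape,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
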