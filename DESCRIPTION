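Package: serpinscape
Title: Annotation and Molecular Evolution of Serpin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale analysis of serine protease inhibitor
    (serpin) gene families in insects. Locates the reactive-center loop (RCL)
    via the conserved hinge consensus, predicts the P1/P1' scissile bond and
    target-protease specificity, and summarises family composition across
    chromosomes. Provides neighbor-joining phylogenetics with Poisson-corrected
    distances and bootstrap support, YN-style Ka/Ks estimation for paralog
    pairs, GY94 codon site models (M0/M3/M7/M8) with likelihood-ratio tests and
    Bayes empirical Bayes detection of positively selected sites, a
    birth-death model of gene-family size evolution on a dated species tree,
    mutually-exclusive-exon isoform assembly, and expression-profile
    clustering. Ships seeded synthetic-data generators so every stage of the
    pipeline can be exercised and validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
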