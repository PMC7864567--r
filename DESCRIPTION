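Package: medullamatch
Title: Mapping Neuroblastoma Cells onto Fetal Adrenal Medullary Cell States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which normal fetal adrenal cell type tumor
    cells resemble, built around single-cell and bulk transcriptomes of
    neuroblastoma. Implements per-cell quality control with platform presets
    and a cluster-level failure rule, cell similarity scoring by one-vs-rest
    elastic-net logistic regression reported on the logit scale without
    softmax normalization, genotyping of single cells from allelic imbalance
    of phased heterozygous SNPs inside copy-number-altered segments, tf-idf
    marker statistics with hypergeometric tests and stringent marker
    filtering, marker-presence signal in bulk TPM cohorts with risk
    stratification, covariate-adjusted negative binomial differential
    expression with fixed or genewise dispersion, and Gaussian-kernel
    smoothing of expression along genomic coordinates with permutation tests
    against recurrent copy-number regions. A synthetic-data module generates
    all pipeline inputs with known ground truth so the full workflow is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    edgeR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
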