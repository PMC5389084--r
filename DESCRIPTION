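Package: beidc
Title: Backward-Elimination Iterative Distance-Correlation Screening for
    Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Adaptive-threshold feature screening for genomic selection.
    Ranks SNPs (or continuous covariates) by iterative distance-correlation
    sure independence screening (IDC-SIS), then determines how many top-ranked
    features to keep by backward elimination: nested feature pools are scored
    by the out-of-bag mean squared prediction error of SCAD-penalised
    regression models fitted to bootstrap resamples, and the pool size
    minimising this error is the adaptive threshold. Includes the simulation
    designs used to validate the procedure, a SCAD coordinate-descent solver,
    and genotype I/O for delimited text and VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
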