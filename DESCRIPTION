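Package: poolGC
Title: Permutation Disequilibrium Test for Oligoset DNA Pooling Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the sign-flip permutation disequilibrium test for
    stratum-matched case-control association studies that use a small number
    (an "oligoset", J < 30) of DNA pooling sets with genomic control. The
    candidate-marker chi-square statistic is calibrated against the mean
    chi-square of unlinked null markers, and its null distribution is
    approximated by randomly exchanging case/control labels within pooling
    sets (equivalently, flipping the signs of columns of the allele-frequency
    difference matrix). Includes an exhaustive enumeration oracle for small J,
    a large-sample chi-square comparator, a full synthetic-data generator
    (hidden population strata, stratum matching with a mismatch index,
    unequal allelic amplification, logit-normal measurement error), and
    drivers that estimate type-I error and power over scenario grids with
    Monte-Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
biocViews: StatisticalMethod, GeneticVariability, SNP, Genetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
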