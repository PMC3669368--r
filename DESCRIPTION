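Package: snpsetpower
Title: Power of Gene-Based SNP-Set Association Tests in the Presence of
    Non-Causal SNPs and Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates case-control genotype and phenotype data under
    configurable linkage-disequilibrium architectures (independent SNPs,
    exchangeable non-causal blocks, causal-anchored blocks, and realistic
    haplotype-pool sampling), applies five gene-based SNP-set association
    tests (GATES, VEGAS-SUM, VEGAS-MAX, logistic regression, and logistic
    regression on principal components), estimates statistical power over
    factorial simulation grids, and quantifies the cost of including
    non-causal SNPs via regressions of power on design parameters and via
    window- and LD-threshold rules for assigning intergenic SNPs to genes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
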