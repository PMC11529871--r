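Package: sumrhe
Title: SNP Heritability from GWAS Summary Statistics via Randomized
    Haseman-Elston Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates SNP heritability by method of moments. Implements
    the exact Haseman-Elston (HE) estimator and its randomized variant
    (RHE) from individual-level PLINK genotypes, and a summary-statistics
    estimator (SUM-RHE) that combines per-SNP GWAS effect sizes with
    shareable "trace summaries" -- stochastic estimates of the trace of
    the squared genetic relatedness matrix computed once on a reference
    panel.  Includes SNP-block jackknife standard errors, a calibrated
    test of zero heritability, a polygenic phenotype simulator (sparse
    and mixture architectures), readers and writers for PLINK 1 binary
    genotypes and PLINK 2 glm.linear summary statistics, and a
    simulation harness for bias/SE/false-positive-rate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
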