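Package: cdgps
Title: Genotype-Phenotype Association, Risk Scores and Permutation
    Inference for Coeliac Disease Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Case-control allelic association testing for curated SNP panels
    with variant-level quality control (call rate, differential missingness,
    minor allele frequency, exact Hardy-Weinberg test in controls), odds
    ratios with Woolf confidence intervals, sex-adjusted logistic models and
    Breslow-Day homogeneity tests across sex strata; pointwise (EMP1) and
    family-wise max(T) (EMP2) empirical P values by label permutation; a
    weighted genetic risk score analysed in control-derived tertiles; a
    clumping-and-thresholding polygenic risk score with permutation-based
    best-fit selection; and a synthetic cohort generator (Hardy-Weinberg
    genotypes at stated allele frequencies, optional LD blocks, X-chromosome
    variants, additive logistic phenotype models) so that every stage is
    testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
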