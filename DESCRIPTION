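Package: paleoimpute
Title: Simulation and Evaluation of Low-Coverage Ancient DNA Genotype
    Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how reference-panel composition shapes genotype
    imputation of low-coverage, damaged ancient DNA. Simulates structured
    phased haplotype panels (Balding-Nichols drift model), admixed diploid
    targets with post-mortem deamination and Poisson read coverage, imputes
    them with a Li-Stephens haplotype-copying hidden Markov model, and
    evaluates the results with genotype concordance and its error taxonomy,
    information content, minor-allele-frequency and heterozygote
    stratification, reference-affinity profiles, supervised ancestry-shift
    estimates, principal-component displacement, and runs-of-homozygosity
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
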