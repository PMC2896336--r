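Package: snpforest
Title: Random-Forests Screening of Case-Control Genome-Wide SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genotype-specialized Random-Forests workflow for case-control
    genome-wide association (GWA) SNP screening: bagged unpruned
    classification trees over 0/1/2 minor-allele dosages with random
    per-node variable subsets, balanced class weighting, out-of-bag error
    estimation and permutation variable importance; plus the surrounding
    protocol stages - mtry/ntree tuning, iterative sparsity pruning,
    strong-locus masking, linkage-disequilibrium pruning (pairwise r2 and
    sliding-window multiple-correlation R2), tag-SNP identification,
    allelic chi-square association testing, genomic inflation, analytic
    power, seed-change reliability checks and ranked reporting. Includes a
    synthetic case-control GWAS generator with blockwise LD and
    additive/dominant/recessive/epistatic penetrance models, and text
    PLINK (.ped/.map, .raw) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
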