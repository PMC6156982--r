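Package: gxmeth
Title: Simulation and Detection of SNP-by-Methylation Interactions in Family Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates family-based studies of triglyceride response in which
    post-treatment levels are driven by SNP main effects, CpG methylation and
    their interaction, and provides the matching analysis pipeline: derived
    pre/post log-triglyceride traits, four interaction-model
    parameterizations, fixed-effect and mixed-model association tests,
    empirical-null SNP-CpG pairing on effect-free chromosomes with a
    minor-allele-count filter, replicate-level power and Type-I error
    summaries, kinship-based REML heritability and per-SNP b2 estimation, and
    regression-tree / random-forest variable-importance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    lme4,
    sandwich,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
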