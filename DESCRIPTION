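Package: abcdl
Title: Approximate Bayesian Computation with Deep-Learned Site-Frequency-Spectrum Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic model choice and parameter estimation for human archaic-introgression
    history by approximate Bayesian computation on summary statistics learned by a feedforward
    network from the multidimensional joint site frequency spectrum (SFS). Provides eight
    competing introgression models for African, Eurasian and Oceanian populations together with
    Neanderthal and Denisova, a structured-coalescent simulator reducing genomes to joint SFS
    arrays, SFS-like noise injection during network training, ABC rejection with
    multinomial-logistic model posteriors and local-linear parameter adjustment, cross-validation
    confusion matrices, and Patterson's D / F4-ratio statistics with weighted block jackknife
    standard errors, including simulation-based fitting of introgression fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    generics,
    ggplot2,
    nnet,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
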