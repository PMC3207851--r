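Package: heterochiasma
Title: Sex-Specific Crossover Landscapes from Backcross Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing meiotic crossover (CO) landscapes from
    backcross genotype matrices, separately for male and female meiosis.
    Provides per-interval recombination fractions and chromosome-wide genetic
    lengths by two estimators, detection of segregation distortion with a
    model-based correction of genetic lengths under two-locus gametic
    selection, Poisson-null tests of CO-count distributions, maximum-likelihood
    estimation of the gamma interference parameter from thinned gamete data,
    hot/cold interval classification, association of CO rates with genomic
    features, and fits of crossover number against chromosome size including
    an obligate-CO threshold model. A meiosis and population simulator
    (stationary gamma renewal crossover placement, thinning, gametic
    selection, genotyping noise) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
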