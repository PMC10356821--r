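Package: permagrad
Title: Relating Permafrost Metagenome Abundance Tables to Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a statistical workflow for
    panarctic permafrost metagenomics: expectation-maximization imputation of
    environmental covariates, principal component scores as covariates,
    permutational analysis of covariance (PERMANCOVA) on Bray-Curtis
    dissimilarities under a nested mixed design, identification of highly
    variable functional genes by pairwise-site negative-binomial testing with
    hypergeometric set enrichment, k-means sample clustering with
    environmental characterization, and taxonomy-environment ordination and
    diversity analyses.  Includes a synthetic-data generator that emulates the
    nested site structure, correlated environmental variables with
    missingness, negative-binomially distributed gene counts with planted
    environment-linked genes, and pH-unimodal taxonomic diversity, so every
    stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    MASS,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
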