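Package: gutmacro
Title: Macroecological Models and Emergent Patterns of Gut Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the emergent macroecological patterns of microbiome
    species-by-sample count tables (mean abundance distribution, Taylor's
    law, species abundance distribution, abundance-occupancy, occupancy,
    species-area relation, alpha and gamma diversity) and fits three
    constrained compositional generative models with at most three free
    parameters: the Multinomial Dirichlet, the Multinomial Symmetric
    Scaled Dirichlet, and the Poisson Stochastic Logistic Growth model.
    Models are grounded in the stochastic logistic model of population
    dynamics, whose stationary Gamma abundance-fluctuation distribution
    links Taylor's law amplitude to the width of environmental noise.
    Includes exact Scaled Dirichlet samplers and densities, maximum
    likelihood fitting of heavy-tailed mean abundance distributions with
    BIC model selection, bootstrap uncertainties, an R-squared-like
    model-vs-data comparison protocol over detection cutoffs, and a
    seeded synthetic-cohort generator emulating healthy and dysbiotic
    gut communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
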