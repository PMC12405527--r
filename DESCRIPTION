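Package: mutburst
Title: Fluctuation Analysis and Stochastic Models of Transient Mutator
    Bursts in Growing Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify transient hypermutation during clonal colony
    growth. Implements Luria-Delbrueck fluctuation analysis (Ma-Sandri-Sarkar
    maximum-likelihood mutation-rate estimation with plating correction,
    profile-likelihood confidence intervals and likelihood-ratio rate
    comparison), generation-synchronous stochastic simulation of mutation
    accumulation in an exponentially growing colony under a null
    (constant-rate) model and a refined model with a transient mutator
    subpopulation, a parameter-space sweep constraining the size, strength
    and duration of mutator episodes, a binomial model of genome-wide
    non-selected mutation burden, and generators for synthetic fluctuation
    assay data with Luria-Delbrueck statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
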