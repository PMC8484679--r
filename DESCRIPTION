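Package: phylosel
Title: Phylogenetic Comparative Analysis of Sex-Biased Selection and Parental Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for testing how the strength of sexual selection covaries
    with gametic investment, parental care and sexual size dimorphism across
    species. Computes per-species sex-bias effect sizes (lnCVR contrasts of
    the opportunity for selection and for sexual selection, Hedges' d
    contrasts of Bateman gradients, log-ratio size dimorphism and gametic
    bias indices, a five-level parental-care score), fits phylogenetic
    generalized least squares regressions with maximum-likelihood Pagel's
    lambda, performs phylogenetic multiple imputation of missing traits
    under a multivariate Brownian-motion model with a common lambda
    (including leave-one-out reliability checking and mean/SD pooling of
    fits across completed datasets), and simulates phylogenies and trait
    datasets with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
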