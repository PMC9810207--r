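Package: bammi
Title: Bayesian AMMI Models for Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bayesian additive main effects and multiplicative
    interaction (AMMI) models to multi-environment plant trials. Three
    prior families on the singular-value scale (flat, Jeffreys-type
    shrinkage, maximum-entropy inverse-gamma) are available, sampled by a
    Gibbs scheme with truncated-normal and von Mises-Fisher conditionals
    that respect the orthonormality and ordering constraints of the
    bilinear terms. A reversible-jump MCMC sampler selects the number of
    bilinear axes during sampling. Includes information-criterion model
    comparison (AIC, BIC, AICM), highest-posterior-density intervals,
    bivariate biplot credibility regions with stability classification,
    10-fold predictive cross-validation under whole-cell genotype loss,
    Raftery-Lewis and Heidelberger-Welch chain diagnostics, and a
    synthetic multi-environment-trial generator with an SVD truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
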