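Package: vitalNe
Title: Age-Specific Vital Rates, Effective Population Size, and Genetic
    Diversity in Iteroparous Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how age-specific survivorship and fecundity
    schedules shape the lifetime variance in reproductive success (Vk), the
    effective-to-census population size ratio (Ne/N), and ultimately neutral
    genetic diversity, with marine teleost fishes as the motivating system.
    Builds empirical life tables from Von Bertalanffy growth and
    fecundity-length relationships, and theoretical life tables from Weibull
    survivorship curves spanning Type I-III shapes crossed with age-fecundity
    models. Computes Vk, generation length, Ne and Ne/N with a
    Hill/Felsenstein-style analytic engine for overlapping generations,
    cross-checked by a Monte-Carlo cohort simulator. Includes an
    individual-based forward simulator (compiled core) tracking per-individual
    heterozygosity to mutation-drift equilibrium, maximum-likelihood beta
    regression with logit link for diversity-trait analyses including
    exhaustive leave-k-out subset scans, survivorship-by-fecundity grid scans
    of the Ne/N vs adult-lifespan relationship, and a bundled trait table for
    16 northeast Atlantic and Mediterranean teleosts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
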