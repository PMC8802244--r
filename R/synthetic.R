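#' Simulate noisy age-length observations from a growth curve
#'
#' Draws `n_per_age` length observations at each requested age as the Von
#' Bertalanffy mean plus independent Gaussian noise - the structure of the
#' age-length samples from which growth parameters are estimated in
#' fisheries data. With `noise_sd = 0` the observations lie exactly on the
#' curve, so a round-trip through [fit_von_bertalanffy()] recovers the
#' generating parameters.
#'
#' @param growth A `"growth_model"`.
#' @param ages Ages (years) at which lengths are observed; non-empty.
#' @param noise_sd Gaussian measurement/individual noise SD (cm), `>= 0`.
#' @param n_per_age Observations per age.
#' @param seed Optional integer seed.
#' @param species,sex Labels written into the output columns.
#' @return A `data.frame` with columns `species`, `sex`, `age_years`,
#'   `length_cm`.
#' @export
gen_age_length_data <- function(growth, ages, noise_sd = 0, n_per_age = 1,
                                seed = NULL, species = "synthetic",
                                sex = "both") {
  if (length(ages) == 0) stop("ages must be non-empty")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  a <- rep(ages, each = n_per_age)
  len <- vb_length(a, growth) + stats::rnorm(length(a), 0, noise_sd)
  data.frame(species = species, sex = sex, age_years = a, length_cm = len)
}

#' Specify a synthetic species cohort
#'
#' Parameters of the synthetic trait-table generator
#' [gen_synthetic_species_set()]: how many species, the range their
#' lifespans are drawn from, how maturity follows lifespan, and the true
#' logit-linear dependence of diversity on adult lifespan with
#' beta-distributed noise. The beta mean/precision parameterisation matches
#' the regression model fitted downstream, so parameter-recovery tests are
#' exact-model checks.
#'
#' @param n_species Number of species, at least 2.
#' @param lifespan_range Integer range (length-2) lifespans are drawn from
#'   uniformly; must allow variation (a degenerate range is rejected at
#'   generation time).
#' @param maturity_rule Function lifespan -> maturity; the default
#'   `max(0.5, 0.2 * lifespan)` loosely mimics the maturity/lifespan ratios
#'   of the bundled table.
#' @param intercept_true,slope_true True link-scale (logit) intercept and
#'   per-year adult-lifespan effect of the diversity mean.
#' @param precision_true Beta precision `phi` (> 0) of the diversity noise.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(n_species = 100,
                                  lifespan_range = c(3, 21),
                                  maturity_rule = function(l) pmax(0.5, 0.2 * l),
                                  intercept_true = -4.4,
                                  slope_true = -0.1,
                                  precision_true = 800,
                                  seed = 1L) {
  if (n_species < 2) stop("n_species must be at least 2")
  if (length(lifespan_range) != 2 || any(lifespan_range < 1))
    stop("lifespan_range must be two positive bounds")
  if (precision_true <= 0) stop("precision_true must be > 0")
  structure(list(n_species = as.integer(n_species),
                 lifespan_range = as.integer(sort(lifespan_range)),
                 maturity_rule = maturity_rule,
                 intercept_true = intercept_true, slope_true = slope_true,
                 precision_true = precision_true, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic species trait table
#'
#' Draws lifespans uniformly over the spec's range, derives maturity from
#' the maturity rule, and draws each species' diversity from a beta
#' distribution whose logit-scale mean is
#' `intercept_true + slope_true * adult_lifespan` with precision
#' `precision_true`. The remaining trait columns are filled with plausible
#' covarying values (body size growing with lifespan, fecundity with body
#' size) so the table passes [validate_species_traits()] and can be fed to
#' every downstream stage unchanged.
#'
#' @param spec A `"synthetic_cohort_spec"`.
#' @return A validated trait `data.frame` with `nrow = n_species`.
#' @export
gen_synthetic_species_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  span <- seq(spec$lifespan_range[1], spec$lifespan_range[2])
  ls_ <- span[sample.int(length(span), spec$n_species, replace = TRUE)]
  if (length(unique(ls_)) < 2L)
    stop("degenerate lifespan draw: all species share one lifespan; ",
         "widen lifespan_range or change the seed")
  mat <- spec$maturity_rule(ls_)
  if (any(mat > ls_)) stop("maturity_rule produced maturity > lifespan")
  al <- ls_ - mat
  mu <- stats::plogis(spec$intercept_true + spec$slope_true * al)
  div <- stats::rbeta(spec$n_species, mu * spec$precision_true,
                      (1 - mu) * spec$precision_true)
  div <- pmin(pmax(div, 1e-8), 1 - 1e-8)
  body <- round(exp(log(10) + 0.15 * ls_ + stats::rnorm(spec$n_species, 0, 0.3)), 2)
  tr <- data.frame(
    species = sprintf("synthetic_sp_%03d", seq_len(spec$n_species)),
    diversity = div,
    body_size = body,
    trophic_level = round(stats::runif(spec$n_species, 2, 4.5), 2),
    fecundity = round(body^2.5 * exp(stats::rnorm(spec$n_species, 0, 0.5)), 2),
    propagule_size = round(exp(stats::rnorm(spec$n_species, 0, 0.6)), 2),
    maturity = mat,
    lifespan = ls_,
    adult_lifespan = al,
    parental_care = "none",
    hermaphroditism = "none")
  validate_species_traits(tr)
}
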