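#' Von Bertalanffy length at age
#'
#' `L(a) = L_inf * (1 - exp(-K * (a - t0)))`.
#'
#' @param age Age in years (vectorised).
#' @param growth A growth model as returned by [growth_model()].
#' @return Predicted length (cm).
#' @export
vb_length <- function(age, growth) {
  growth$L_inf * (1 - exp(-growth$K * (age - growth$t0)))
}

#' Construct a Von Bertalanffy growth model
#'
#' @param L_inf Asymptotic length (cm), > 0.
#' @param K Growth coefficient (1/year), > 0.
#' @param t0 Theoretical age at length zero (years); defaults to 0, the value
#'   used when age-length data cannot identify it.
#' @return An object of class `"growth_model"`.
#' @export
growth_model <- function(L_inf, K, t0 = 0) {
  if (!is.finite(L_inf) || L_inf <= 0) stop("L_inf must be > 0")
  if (!is.finite(K) || K <= 0) stop("K must be > 0")
  structure(list(L_inf = L_inf, K = K, t0 = t0), class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("Von Bertalanffy growth: L_inf = %.4g cm, K = %.4g /yr, t0 = %.4g yr\n",
              x$L_inf, x$K, x$t0))
  invisible(x)
}

#' Fit a Von Bertalanffy growth curve to age-length data
#'
#' Nonlinear least squares fit of `L(a) = L_inf (1 - exp(-K (a - t0)))` via
#' Levenberg-Marquardt. Starting values come from the usual heuristics:
#' `L_inf` from the largest observed length inflated by 10%, `K` from a
#' log-linear regression of `log(1 - L/L_inf_start)` on age, `t0 = 0`.
#'
#' @param age Numeric vector of ages (years).
#' @param length Numeric vector of lengths (cm), same length as `age`.
#' @param fix_t0 If `TRUE`, hold `t0 = 0` (used when the data cannot identify
#'   it, e.g. no young ages).
#' @return A `"growth_model"` with extra fields `residual_sd`, `n`, and
#'   `convergence` (the optimiser's message).
#' @export
#' @examples
#' g <- growth_model(100, 0.3, -0.5)
#' a <- 1:10
#' fit <- fit_von_bertalanffy(a, vb_length(a, g))
#' c(fit$L_inf, fit$K, fit$t0)  # recovers (100, 0.3, -0.5)
fit_von_bertalanffy <- function(age, length, fix_t0 = FALSE) {
  ok <- is.finite(age) & is.finite(length)
  age <- age[ok]; length <- length[ok]
  if (length(unique(age)) < 3L)
    stop("need at least 3 distinct ages to fit a growth curve")
  dat <- data.frame(age = age, len = length)
  Linf0 <- max(length) * 1.1
  z <- pmax(1 - length / Linf0, 1e-6)
  K0 <- max(1e-3, -unname(stats::coef(stats::lm(log(z) ~ age))[2]))
  fit <- if (fix_t0) {
    minpack.lm::nlsLM(len ~ Linf * (1 - exp(-K * age)),
                      data = dat, start = list(Linf = Linf0, K = K0),
                      lower = c(1e-8, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(len ~ Linf * (1 - exp(-K * (age - t0))),
                      data = dat, start = list(Linf = Linf0, K = K0, t0 = 0),
                      lower = c(1e-8, 1e-8, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  out <- growth_model(cf[["Linf"]], cf[["K"]],
                      t0 = if (fix_t0) 0 else cf[["t0"]])
  out$residual_sd <- stats::sigma(fit)
  out$n <- length(age)
  out$convergence <- fit$convInfo$stopMessage
  out
}

#' Length-based instantaneous natural mortality
#'
#' Natural mortality at age is tied to body length relative to the asymptotic
#' length: `m = (L / L_inf)^(-1.5) * K`. Small (young) fish therefore always
#' die at a higher instantaneous rate than large (old) fish under the same
#' growth model, the typical pattern in marine teleosts.
#'
#' @param length_at_age Length (cm), in (0, `L_inf`].
#' @param growth A `"growth_model"`.
#' @param clamp If `TRUE`, lengths above `L_inf` are clamped to `L_inf`
#'   (giving `m = K`) instead of raising an error.
#' @return Instantaneous mortality rate (1/year), always `>= K`.
#' @export
#' @examples
#' g <- growth_model(100, 0.2)
#' natural_mortality_at_age(100, g)  # = K
#' natural_mortality_at_age(25, g)   # = 8 K
natural_mortality_at_age <- function(length_at_age, growth, clamp = FALSE) {
  if (any(!is.finite(length_at_age)) || any(length_at_age <= 0))
    stop("length_at_age must be positive and finite")
  if (any(length_at_age > growth$L_inf)) {
    if (clamp) length_at_age <- pmin(length_at_age, growth$L_inf)
    else stop("length_at_age exceeds L_inf; use clamp = TRUE to cap at L_inf")
  }
  (length_at_age / growth$L_inf)^(-1.5) * growth$K
}

#' Annual survival probability from an instantaneous mortality rate
#'
#' `s = exp(-m)` for a one-year interval.
#'
#' @param m Instantaneous mortality (1/year), `>= 0`.
#' @return Survival probability in (0, 1].
#' @export
annual_survival <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) stop("mortality rate must be >= 0")
  exp(-m)
}

#' Construct a fecundity-length model
#'
#' Absolute fecundity as a function of body length, in one of the three
#' families reported in the fisheries literature: power law `F = alpha * L^beta`
#' (the usual best fit), exponential `F = alpha * exp(beta * L)`, or linear
#' `F = alpha + beta * L`.
#'
#' @param form One of `"power"`, `"exponential"`, `"linear"`.
#' @param alpha,beta Coefficients of the chosen form.
#' @return An object of class `"fecundity_model"`.
#' @export
fecundity_model <- function(form = c("power", "exponential", "linear"),
                            alpha, beta) {
  form <- match.arg(form)
  structure(list(form = form, alpha = alpha, beta = beta),
            class = "fecundity_model")
}

#' Predict fecundity from length
#'
#' Applies a [fecundity_model()] to a vector of lengths. Negative predictions
#' (possible under the linear form) are clamped to zero with a warning, since
#' fecundity below the size at which the fitted line crosses zero is simply
#' absent rather than negative.
#'
#' @param model A `"fecundity_model"`.
#' @param length Length (cm), > 0.
#' @return Predicted fecundity (eggs), `>= 0`.
#' @export
fecundity_from_length <- function(model, length) {
  if (!inherits(model, "fecundity_model")) stop("not a fecundity_model")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("length must be positive")
  f <- switch(model$form,
    power       = model$alpha * length^model$beta,
    exponential = model$alpha * exp(model$beta * length),
    linear      = model$alpha + model$beta * length)
  if (any(f < 0)) {
    warning("negative predicted fecundity clamped to 0")
    f <- pmax(f, 0)
  }
  f
}
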