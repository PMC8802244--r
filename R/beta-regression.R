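#' Beta regression with a logit link by maximum likelihood
#'
#' Fits the beta-regression model for a response strictly inside (0, 1):
#' `y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)` with `logit(mu_i) = x_i' beta`
#' and a single constant precision `phi`. Estimation is by maximum
#' likelihood over `(beta, log phi)` with analytic gradients
#' (quasi-Newton), started from an ordinary least-squares fit of
#' `logit(y)`; the optimiser is deterministic. Because proportions such as
#' genome-wide heterozygosity live in (0, 1), this is the natural regression
#' family for diversity-trait analyses, and the link-scale slopes it returns
#' are the effect sizes quoted throughout this package.
#'
#' The pseudo-R-squared is the squared Pearson correlation between
#' `logit(y)` and the fitted linear predictor (the Ferrari-Cribari-Neto
#' definition); it equals 1 exactly when the linear predictor is an affine
#' transform of `logit(y)`. Wald p-values use the observed-information
#' covariance at the optimum.
#'
#' @param y Response vector, all values strictly inside (0, 1).
#' @param X Covariate matrix (without intercept; one is added), or `NULL`
#'   for an intercept-only model.
#' @return An object of class `"beta_fit"`: `coefficients` (link scale),
#'   `phi_prec`, `loglik`, `pseudo_R2`, `se`, `wald_z`, `wald_p`, `n`,
#'   `n_par`, `gradient_norm`, `fitted`, `linear_predictor`, `y`, `X`
#'   (with intercept).
#' @export
#' @examples
#' tr <- marine_fish_traits()
#' fit <- fit_beta_regression(tr$diversity, cbind(adult_lifespan = tr$adult_lifespan))
#' coef(fit)[["adult_lifespan"]]  # about -0.089 per year
fit_beta_regression <- function(y, X = NULL) {
  if (any(!is.finite(y)) || any(y <= 0 | y >= 1))
    stop("response must be strictly inside (0, 1)")
  if (!is.null(X)) X <- as.matrix(X)
  X <- if (is.null(X) || ncol(X) == 0L) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    cbind("(Intercept)" = 1, X)
  }
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (qr(X)$rank < ncol(X)) stop("collinear columns in the design matrix")
  p <- ncol(X)
  ystar <- stats::qlogis(y)

  ols <- stats::lm.fit(X, ystar)
  res_var <- sum(ols$residuals^2) / max(1, length(y) - p)
  start <- c(ols$coefficients, log_phi = log(max(1 / res_var, 2)))

  nll <- function(par) {
    mu <- stats::plogis(drop(X %*% par[1:p]))
    phi <- exp(par[p + 1])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  ngr <- function(par) {
    eta <- drop(X %*% par[1:p])
    mu <- stats::plogis(eta)
    phi <- exp(par[p + 1])
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    g_beta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
    g_phi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                   (1 - mu) * digamma((1 - mu) * phi) +
                   mu * log(y) + (1 - mu) * log1p(-y)) * phi
    -c(g_beta, g_phi)
  }
  opt <- stats::optim(start, nll, ngr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # Newton polish: a few damped steps drive the score to machine zero
  par <- opt$par; val <- opt$value
  for (it in 1:25) {
    g <- ngr(par)
    if (sqrt(sum(g^2)) < 1e-10) break
    H <- stats::optimHess(par, nll, ngr)
    step <- tryCatch(solve(H, g), error = function(e) g)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      v <- nll(cand)
      if (is.finite(v) && v <= val + 1e-12) { par <- cand; val <- v; break }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (lambda < 1e-8) break
  }
  opt <- list(par = par, value = val, convergence = 0L,
              hessian = stats::optimHess(par, nll, ngr))
  grad_norm <- sqrt(sum(ngr(opt$par)^2))

  coefs <- opt$par[1:p]
  names(coefs) <- colnames(X)
  eta <- drop(X %*% coefs)
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("observed information is singular; Wald SEs unavailable")
    matrix(NA_real_, p + 1, p + 1)
  })
  se <- sqrt(pmax(diag(vc)[1:p], 0))
  z <- coefs / se
  structure(list(coefficients = coefs, phi_prec = exp(opt$par[p + 1]),
                 loglik = -opt$value,
                 pseudo_R2 = if (stats::sd(eta) == 0) 0 else
                   stats::cor(ystar, eta)^2,
                 se = se, wald_z = z,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 n = length(y), n_par = p + 1,
                 gradient_norm = grad_norm,
                 fitted = stats::plogis(eta), linear_predictor = eta,
                 y = y, X = X,
                 converged = opt$convergence == 0 && grad_norm < 1e-4),
            class = "beta_fit")
}

#' @export
coef.beta_fit <- function(object, ...) object$coefficients

#' @export
logLik.beta_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("beta regression (logit link), n = %d, logLik = %.3f, phi = %.2f, pseudo-R2 = %.3f\n",
              x$n, x$loglik, x$phi_prec, x$pseudo_R2))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$wald_z,
                   p = x$wald_p))
  invisible(x)
}

#' Beta regression from a model formula
#'
#' Formula front-end to [fit_beta_regression()]: builds the design matrix
#' (main effects and interaction products) with [stats::model.matrix()] from
#' a trait table, e.g. `diversity ~ adult_lifespan` or
#' `diversity ~ adult_lifespan * parental_care`.
#'
#' @param formula A model formula whose left side is the proportion response.
#' @param data A `data.frame` holding the variables.
#' @return A `"beta_fit"` with an extra `formula` field.
#' @export
beta_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  fit <- fit_beta_regression(y, X[, -1, drop = FALSE])
  fit$formula <- formula
  fit
}

#' Likelihood-ratio test between nested beta regressions
#'
#' Twice the log-likelihood difference, referred to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference. Both fits must be on the same response; the reduced model
#' must be nested in the full one (checked through parameter counts and the
#' likelihood ordering).
#'
#' @param fit_full,fit_reduced `"beta_fit"` objects.
#' @return List with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  if (!inherits(fit_full, "beta_fit") || !inherits(fit_reduced, "beta_fit"))
    stop("both arguments must be beta_fit objects")
  if (!isTRUE(all.equal(fit_full$y, fit_reduced$y)))
    stop("fits are not on the same response")
  df <- fit_full$n_par - fit_reduced$n_par
  if (df < 0) stop("the first argument must be the larger (full) model")
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6)
    stop("full model has lower likelihood than the reduced one; ",
         "models are not nested or a fit did not converge")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Exhaustive leave-k-out slope distribution
#'
#' Refits the single-covariate beta regression on every subset of `k`
#' species out of `n` (exhaustive enumeration, no sampling) and collects the
#' slope and pseudo-R-squared of each fit, with empirical 2.5% / 97.5%
#' quantile summaries. Used to judge whether an estimate obtained on a
#' particular subset (e.g. the nonbrooders) is typical of subsets of that
#' size.
#'
#' @param traits A trait `data.frame`.
#' @param covariate Name of the covariate column.
#' @param k Subset size (default 11).
#' @param response Name of the response column (default `"diversity"`).
#' @return An object of class `"subset_distribution"`: `slopes`,
#'   `pseudo_R2` (each of length `choose(n, k)` minus skipped subsets),
#'   `quantiles` (2.5/97.5% for both), `k`, `n`, `n_fit`, `n_skipped`.
#' @export
subset_slope_distribution <- function(traits, covariate, k = 11,
                                      response = "diversity") {
  y_all <- traits[[response]]
  x_all <- traits[[covariate]]
  if (is.null(y_all) || is.null(x_all)) stop("unknown response or covariate")
  n <- nrow(traits)
  if (k >= n) stop("k must be smaller than the number of species")
  sets <- utils::combn(n, k)
  slopes <- r2 <- rep(NA_real_, ncol(sets))
  skipped <- 0L
  for (j in seq_len(ncol(sets))) {
    i <- sets[, j]
    if (length(unique(x_all[i])) < 2L) { skipped <- skipped + 1L; next }
    f <- fit_beta_regression(y_all[i], cbind(x = x_all[i]))
    slopes[j] <- f$coefficients[["x"]]
    r2[j] <- f$pseudo_R2
  }
  if (skipped > 0L)
    warning(skipped, " subsets skipped (degenerate covariate values)")
  keep <- !is.na(slopes)
  structure(list(slopes = slopes[keep], pseudo_R2 = r2[keep],
                 quantiles = list(
                   slope = stats::quantile(slopes[keep], c(0.025, 0.975)),
                   pseudo_R2 = stats::quantile(r2[keep], c(0.025, 0.975))),
                 k = k, n = n, n_fit = sum(keep), n_skipped = skipped),
            class = "subset_distribution")
}

#' @export
print.subset_distribution <- function(x, ...) {
  cat(sprintf("exhaustive %d-of-%d subset scan: %d fits\n", x$k, x$n, x$n_fit))
  cat(sprintf("  slope 95%% interval: [%.4f, %.4f]\n",
              x$quantiles$slope[1], x$quantiles$slope[2]))
  cat(sprintf("  pseudo-R2 95%% interval: [%.4f, %.4f]\n",
              x$quantiles$pseudo_R2[1], x$quantiles$pseudo_R2[2]))
  invisible(x)
}

#' Ordinary least-squares slope and R-squared
#'
#' Simple linear regression `y ~ x`, used for the grid-scan surfaces where
#' the response (Ne/N) is not a proportion-with-noise but a deterministic
#' engine output.
#'
#' @param x,y Numeric vectors (at least 3 points; `x` must vary).
#' @return List with `slope`, `intercept`, `R2`, `p_slope`, `n`.
#' @export
ols_slope_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  # exact linear inputs are legitimate here; silence summary.lm's
  # perfect-fit caveat
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       R2 = sm$r.squared,
       p_slope = sm$coefficients[2, 4],
       n = length(x))
}
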