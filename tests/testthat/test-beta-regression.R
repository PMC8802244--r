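test_that("the likelihood is maximised: gradient vanishes at the optimum", {
  tr <- marine_fish_traits()
  for (cov in c("adult_lifespan", "lifespan", "body_size")) {
    fit <- fit_beta_regression(tr$diversity, tr[[cov]])
    expect_lt(fit$gradient_norm, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("pseudo-R2 is 1 exactly when logit(y) is affine in the covariate", {
  x <- 1:20
  y <- plogis(-3 + 0.1 * x)
  fit <- fit_beta_regression(y, cbind(x = x))
  expect_equal(fit$pseudo_R2, 1, tolerance = 1e-9)
  expect_equal(fit$coefficients[["x"]], 0.1, tolerance = 1e-4)
})

test_that("beta regression recovers generating parameters within 2 SE", {
  spec <- synthetic_cohort_spec(n_species = 500, slope_true = -0.10,
                                precision_true = 500, seed = 42)
  tr <- gen_synthetic_species_set(spec)
  fit <- fit_beta_regression(tr$diversity, cbind(al = tr$adult_lifespan))
  expect_lt(abs(fit$coefficients[["al"]] - (-0.10)), 2 * fit$se[["al"]])
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_beta_regression(c(0.2, 1.2, 0.3), cbind(1:3)), "inside")
  expect_error(fit_beta_regression(c(0.2, 0.4, 0.3),
                                   cbind(a = 1:3, b = 2 * (1:3))), "collinear")
})

test_that("the formula interface matches the matrix interface", {
  tr <- marine_fish_traits()
  f1 <- beta_regression(diversity ~ adult_lifespan, tr)
  f2 <- fit_beta_regression(tr$diversity,
                            cbind(adult_lifespan = tr$adult_lifespan))
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-8)
  # interaction designs expand to main effects plus products
  f3 <- beta_regression(diversity ~ adult_lifespan * parental_care, tr)
  expect_equal(f3$n_par, 6 + 1)  # 6 mean parameters + precision
})

test_that("likelihood-ratio tests behave at their boundaries", {
  tr <- marine_fish_traits()
  fit <- beta_regression(diversity ~ adult_lifespan, tr)
  same <- likelihood_ratio_test(fit, fit)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  null <- beta_regression(diversity ~ 1, tr)
  lrt <- likelihood_ratio_test(fit, null)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p, 0.05)
  expect_error(likelihood_ratio_test(null, fit), "full")
})

test_that("parental care modifies the diversity-lifespan relationship", {
  # brooders sit systematically below the nonbrooder trend: adding the
  # brooder term and its interaction improves on the covariate-only model
  tr <- marine_fish_traits()
  tr$brooder <- factor(ifelse(is_brooder(tr), "yes", "no"))
  for (v in c("adult_lifespan", "lifespan", "body_size")) {
    full <- beta_regression(stats::as.formula(paste("diversity ~", v, "* brooder")), tr)
    main <- beta_regression(stats::as.formula(paste("diversity ~", v)), tr)
    lrt <- likelihood_ratio_test(full, main)
    expect_equal(lrt$df, 2)
    expect_lt(lrt$p, 0.01)
  }
})

test_that("the likelihood-ratio test holds its nominal size under the null", {
  # simulate no-interaction data, test interaction at the 5% level
  set.seed(2024)
  n <- 80
  x <- runif(n, 0, 10)
  grp <- factor(rep(c("a", "b"), each = n / 2))
  reject <- logical(300)
  for (i in seq_along(reject)) {
    mu <- plogis(-3 + 0.05 * x)   # same slope in both groups
    y <- rbeta(n, mu * 300, (1 - mu) * 300)
    d <- data.frame(y = y, x = x, grp = grp)
    full <- beta_regression(y ~ x * grp, d)
    red <- beta_regression(y ~ x + grp, d)
    reject[i] <- likelihood_ratio_test(full, red)$p < 0.05
  }
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.11)
})

test_that("Wald and likelihood-ratio statistics agree asymptotically", {
  spec <- synthetic_cohort_spec(n_species = 5000, slope_true = -0.05,
                                precision_true = 400, seed = 7)
  tr <- gen_synthetic_species_set(spec)
  fit <- fit_beta_regression(tr$diversity, cbind(al = tr$adult_lifespan))
  null <- fit_beta_regression(tr$diversity, NULL)
  lr <- likelihood_ratio_test(fit, null)$statistic
  wald <- fit$wald_z[["al"]]^2
  expect_lt(abs(lr - wald) / lr, 0.10)
})

test_that("exhaustive subset scans enumerate every combination", {
  tr <- marine_fish_traits()[1:7, ]
  d <- subset_slope_distribution(tr, "adult_lifespan", k = 5)
  expect_equal(d$n_fit, choose(7, 5))
  expect_true(all(d$quantiles$slope >= min(d$slopes) &
                  d$quantiles$slope <= max(d$slopes)))
  expect_error(subset_slope_distribution(tr, "adult_lifespan", k = 7), "smaller")
})

test_that("OLS helper returns exact fits and respects exchangeability", {
  x <- c(1, 2, 3, 5, 8)
  fit <- ols_slope_r2(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$R2, 1)
  # jointly permuting pairs changes nothing
  set.seed(5)
  y <- rnorm(5)
  p <- sample(5)
  expect_equal(ols_slope_r2(x, y), ols_slope_r2(x[p], y[p]))
  # independent noise has near-zero slope and R2
  set.seed(6)
  big <- ols_slope_r2(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$slope), 0.1)
  expect_lt(big$R2, 0.02)
  expect_error(ols_slope_r2(rep(1, 5), rnorm(5)), "constant")
})
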