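test_that("fecundity scaling enforces cohort replacement", {
  lt <- life_table(1:2, c(0.5, 0), c(1, 1), maturity = 1)
  s <- cohort_schedule(lt)
  expect_equal(s$b_x, c(4 / 3, 4 / 3))              # C = 2 / (1 + 0.5)
  expect_equal(sum(s$l_x * s$b_x), 2)
  expect_equal(sum(s$d_x), 1)
  # scaling invariance: the relative schedule is all that matters
  lt10 <- life_table(1:2, c(0.5, 0), c(10, 10), maturity = 1)
  expect_equal(cohort_schedule(lt10)$b_x, s$b_x)
  # semelparity forces b = 2
  sem <- cohort_schedule(life_table(1L, 0, 5, maturity = 1))
  expect_equal(sem$b_x, 2)
})

test_that("generation length is the mean parental age", {
  sem <- cohort_schedule(life_table(1L, 0, 1, maturity = 1))
  expect_equal(generation_length(sem), 1)
  s <- cohort_schedule(life_table(1:2, c(0.5, 0), c(1, 1), maturity = 1))
  expect_equal(generation_length(s), 4 / 3)
  # delaying all reproduction by one age class (perfect survival through the
  # inserted class) adds exactly one year
  lt <- life_table(1:3, c(0.6, 0.3, 0), c(1, 2, 1), maturity = 1)
  delayed <- life_table(1:4, c(1, 0.6, 0.3, 0), c(0, 1, 2, 1), maturity = 2)
  expect_equal(generation_length(cohort_schedule(delayed)),
               generation_length(cohort_schedule(lt)) + 1)
})

test_that("lifetime variance matches the Poisson limits of semelparity", {
  sem <- life_table(1L, 0, 3, maturity = 1)
  expect_equal(lifetime_rs_moments(cohort_schedule(sem, phi = 1))$Vk, 2)
  expect_equal(lifetime_rs_moments(cohort_schedule(sem, phi = 0))$Vk, 0)
  expect_equal(lifetime_rs_moments(cohort_schedule(sem))$k_bar, 2)
})

test_that("the mean lifetime offspring number is 2 for any schedule", {
  for (seed in 1:25) {
    m <- lifetime_rs_moments(cohort_schedule(random_life_table(seed)))
    expect_equal(m$k_bar, 2, tolerance = 1e-9)
    expect_gte(m$Vk, 0)
  }
})

test_that("semelparous maturity-1 Poisson tables sit at the Wright-Fisher limit", {
  sem <- life_table(1L, 0, 1, maturity = 1)
  res <- effective_size_ratio(sem, sem, N1 = 1000, phi = 1)
  expect_equal(res$ratio, 1)
  # phi = 0 removes all reproductive variance: Ne doubles the newborn count
  res0 <- effective_size_ratio(sem, sem, N1 = 1000, phi = 0)
  expect_equal(res0$Ne, 2000)
})

test_that("Ne/N is invariant to the arbitrary newborn count", {
  for (seed in c(3, 11, 27)) {
    lt <- random_life_table(seed)
    r1 <- effective_size_ratio(lt, N1 = 1000)$ratio
    r2 <- effective_size_ratio(lt, N1 = 10)$ratio
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("the analytic moments agree with the Monte-Carlo cohort oracle", {
  # 50 randomised Weibull-family tables; per-table 3-SE agreement on both
  # moments. With 100 independent 3-SE bands a small number of marginal
  # exceedances is expected by chance, so the ensemble is asserted: no more
  # than 2 bands missed, none by more than 4 SE.
  z_k <- z_v <- numeric(50)
  for (seed in 1:50) {
    lt <- random_life_table(seed)
    an <- lifetime_rs_moments(cohort_schedule(lt, phi = 1))
    mc <- monte_carlo_cohort_vk(lt, n = 20000, phi = 1, seed = seed + 500)
    z_k[seed] <- abs(mc$k_bar_emp - an$k_bar) / (mc$se_k_bar + 1e-12)
    z_v[seed] <- abs(mc$Vk_emp - an$Vk) / (mc$se_Vk + 1e-12)
  }
  expect_lte(sum(c(z_k, z_v) > 3), 2)
  expect_lt(max(z_k, z_v), 4)
  # deterministic reproduction: the oracle honours phi = 0 too
  lt <- random_life_table(7)
  an0 <- lifetime_rs_moments(cohort_schedule(lt, phi = 0))
  mc0 <- monte_carlo_cohort_vk(lt, n = 20000, phi = 0, seed = 99)
  expect_lt(abs(mc0$Vk_emp - an0$Vk), 3 * mc0$se_Vk + 1e-9)
  expect_error(monte_carlo_cohort_vk(lt, n = 10), "1000")
})

test_that("Weibull-table Ne/N declines with lifespan for type III shapes and rising fecundity", {
  # regime where longer adult life concentrates reproduction in rare
  # survivors: newborn-cohort tables, c <= 1, exponentially rising fecundity
  for (c in c(0.1, 0.5, 1)) {
    ratios <- vapply(c(4, 8, 12, 16, 21), function(om) {
      lt <- theoretical_table(1, om, c, f = 0.142, model = "exponential",
                              cohort = "newborn")
      effective_size_ratio(lt, phi = 1, census = "generation")$ratio
    }, numeric(1))
    expect_true(all(diff(ratios) <= 1e-10))
  }
})

test_that("census policies count the intended individuals", {
  lt <- life_table(1:3, c(0.5, 0.5, 0), c(0, 1, 1), maturity = 2)
  res_a <- effective_size_ratio(lt, N1 = 1000, census = "adults")
  res_all <- effective_size_ratio(lt, N1 = 1000, census = "all")
  expect_equal(res_a$N_census, 1000 * (0.5 + 0.25))
  expect_equal(res_all$N_census, 1000 * (1 + 0.5 + 0.25))
  res_g <- effective_size_ratio(lt, N1 = 1000, census = "generation")
  expect_equal(res_g$ratio, 4 / (res_g$Vk + 2))
})
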