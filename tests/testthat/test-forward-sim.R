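test_that("trajectories are deterministic under a fixed seed", {
  lt <- life_table(1:3, c(0.6, 0.4, 0), c(1, 1, 1), maturity = 1)
  cfg <- sim_config(lt, lt, N_total = 60, mu = 1e-5, L_sites = 2000,
                    years_total = 400, eq_window = 100, replicates = 2,
                    seed = 5, record_every = 5)
  s1 <- simulate_diversity(cfg)
  s2 <- simulate_diversity(cfg)
  expect_identical(s1$H, s2$H)
  expect_false(identical(s1$H[, 1], s1$H[, 2]))  # replicates differ
})

test_that("heterozygosity stays in [0,1] and decays to zero without mutation", {
  lt <- life_table(1:2, c(0.5, 0), c(1, 1), maturity = 1)
  cfg <- sim_config(lt, lt, N_total = 50, mu = 0, L_sites = 1000,
                    years_total = 2000, eq_window = 200, replicates = 1,
                    seed = 2, record_every = 10)
  s <- simulate_diversity(cfg)
  expect_true(all(s$H >= 0 & s$H <= 1))
  expect_equal(s$H_eq, 0)  # drift alone removes all variation
})

test_that("a reproduction-less population aborts with a diagnostic", {
  lt <- life_table(1:2, c(0.5, 0), c(0, 1), maturity = 2)
  cfg <- sim_config(lt, lt, N_total = 20, mu = 1e-5, L_sites = 500,
                    years_total = 500, eq_window = 100, replicates = 1,
                    seed = 1)
  # with maturity-2 fecundity filled down, reproduction works; but an
  # all-male draw cannot happen at N = 20 -- so force failure with a
  # single-sex-sterile table passed directly to the core
  expect_error(
    vitalNe:::.sim_core(c(0.5, 0), c(0, 0), c(0.5, 0), c(1, 1),
                        20, 1e-5, 500, 100, 1),
    "cannot reproduce")
})

test_that("the Wright-Fisher control reaches theta/(1+theta) heterozygosity", {
  # small, fast control: N = 100, theta = 4e-3
  w <- wright_fisher_control(N = 100, mu = 1e-5, L_sites = 10000,
                             replicates = 6, seed = 31, record_every = 10,
                             eq_window = 4000)
  expected <- w$theta / (1 + w$theta)
  expect_true(w$burnin_ok)
  expect_lt(abs(w$H_eq - expected), 3 * w$H_eq_se)
  # invariance of theta: same 4*N*mu at rescaled N agrees within noise
  w2 <- wright_fisher_control(N = 50, mu = 2e-5, L_sites = 10000,
                              replicates = 6, seed = 32, record_every = 10,
                              eq_window = 4000)
  expect_lt(abs(w2$H_eq - w$H_eq),
            3 * sqrt(w$H_eq_se^2 + w2$H_eq_se^2))
})

test_that("age structure never raises diversity above the Wright-Fisher control", {
  # same census and mutation rate; Poisson tables have Vk >= 2, so Ne <= N
  wf <- wright_fisher_control(N = 80, mu = 1e-5, L_sites = 8000,
                              replicates = 5, seed = 41, record_every = 10,
                              eq_window = 3000)
  lt <- life_table(1:5, c(0.8, 0.7, 0.6, 0.5, 0), c(1, 2, 4, 8, 16),
                   maturity = 1, masked = FALSE)
  cfg <- sim_config(lt, lt, N_total = 80, mu = 1e-5, L_sites = 8000,
                    eq_window = 3000, replicates = 5, seed = 42,
                    record_every = 10)
  st <- simulate_diversity(cfg)
  expect_lt(st$H_eq, wf$H_eq + 3 * sqrt(wf$H_eq_se^2 + st$H_eq_se^2))
})

test_that("population size is constant every recorded year by construction", {
  # indirect assertion through the core's bookkeeping: a varying census
  # would break determinism of trajectory lengths and the H normalisation;
  # verify H is finite and defined at every recorded year for a structured
  # table where deaths fluctuate year to year
  lt <- life_table(1:4, c(0.7, 0.5, 0.3, 0), c(0, 1, 2, 3), maturity = 2)
  cfg <- sim_config(lt, lt, N_total = 40, mu = 1e-4, L_sites = 500,
                    years_total = 300, eq_window = 50, replicates = 1,
                    seed = 3)
  s <- simulate_diversity(cfg)
  expect_equal(sum(is.finite(s$H)), length(s$H))
})

test_that("equilibrium summaries detect trends and constancy", {
  cst <- equilibrium_summary(rep(0.25, 100), 50)
  expect_equal(cst$sd, 0)
  expect_true(cst$converged)
  expect_equal(cst$mean, 0.25)

  trend <- equilibrium_summary(seq(0, 1, length.out = 200), 100)
  expect_false(trend$converged)

  set.seed(77)
  noise <- 0.3 + rnorm(400, 0, 0.01)
  eq <- equilibrium_summary(noise, 200)
  expect_true(eq$converged)
  expect_equal(eq$mean, 0.3, tolerance = 0.01)
  expect_error(equilibrium_summary(noise, 401), "longer")
})
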