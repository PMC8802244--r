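test_that("life-table invariants are enforced by the validator", {
  expect_error(life_table(1:3, c(0.5, 0.5, 0.1), c(0, 1, 1), maturity = 2),
               "terminal survival")
  expect_error(life_table(c(1, 3), c(0.5, 0), c(1, 1), maturity = 1),
               "contiguous")
  expect_error(life_table(1:2, c(1.2, 0), c(1, 1), maturity = 1), "\\[0, 1\\]")
  expect_error(life_table(1:2, c(0.5, 0), c(0, 0), maturity = 1), "zero")
  expect_error(life_table(1:3, c(0.5, 0.5, 0), c(1, 1, 1), maturity = 3),
               "below the age at maturity")
})

test_that("the Weibull scale pins survivorship to 1% at the maximum age", {
  expect_equal(weibull_scale(10, 1), 10 / 4.605170, tolerance = 1e-6)
  for (c in c(0.01, 0.1, 0.5, 1, 2, 5, 30)) {
    b <- weibull_scale(10, c)
    expect_equal(exp(-(10 / b)^c), 0.01, tolerance = 1e-12)
  }
})

test_that("annual Weibull mortality reproduces the three survivorship types", {
  lifespan <- 10
  # type II (c = 1): identical mortality at every age
  s2 <- weibull_survivorship(lifespan, 1)
  M2 <- weibull_annual_mortality(0:(lifespan - 1), s2)
  expect_equal(M2, rep(1 - 0.01^(1 / lifespan), lifespan))
  # type III (c << 1): first-year mortality dwarfs last-year mortality
  s3 <- weibull_survivorship(lifespan, 0.1)
  expect_gt(weibull_annual_mortality(0, s3),
            10 * weibull_annual_mortality(lifespan - 1, s3))
  # type I (c >> 1): almost no deaths early, near-certain death at the end
  s1 <- weibull_survivorship(lifespan, 30)
  expect_lt(weibull_annual_mortality(0, s1), 1e-6)
  expect_gt(weibull_annual_mortality(lifespan - 1, s1), 0.9)
  # cumulative survival over the full span is exactly the pinned 1%
  for (c in c(0.01, 0.3, 1, 3, 30)) {
    sv <- weibull_survivorship(lifespan, c)
    M <- weibull_annual_mortality(0:(lifespan - 1), sv)
    expect_equal(prod(1 - M), 0.01, tolerance = 1e-9)
  }
  expect_error(weibull_annual_mortality(lifespan, s2), "lifespan")
})

test_that("age-fecundity schedules scale to 1 and respect maturity", {
  ages <- 1:10
  expect_equal(age_fecundity(age_fecundity_model("constant"), ages, 3),
               c(0, 0, rep(1, 8)))
  f <- age_fecundity(age_fecundity_model("exponential", f = 0.142), ages, 1)
  expect_equal(f[5] / f[4], exp(0.142), tolerance = 1e-12)
  expect_equal(max(f), 1)
  # decreasing schedule peaks at the age of maturity after scaling
  fneg <- age_fecundity(age_fecundity_model("exponential", f = -0.3), ages, 4)
  expect_equal(which.max(fneg), 4L)
  expect_equal(fneg[4], 1)
})

test_that("theoretical tables satisfy the invariants across the default grid", {
  for (c in default_c_grid()[seq(1, 61, by = 6)]) {
    for (f in c(-1, 0, 0.5, 1)) {
      lt <- theoretical_table(3, 8, c, f, "exponential")
      expect_s3_class(lt, "life_table")   # construction runs the validator
      expect_true(all(diff(survivorship(lt)) <= 1e-12))
      nb <- theoretical_table(3, 8, c, f, "exponential", cohort = "newborn")
      expect_identical(nb$ages[1], 0L)
      # newborn cohort carries the full curve: 1% alive at the maximum age
      expect_equal(survivorship(nb)[nb$ages == 8], 0.01, tolerance = 1e-9)
    }
  }
})

test_that("component toggles produce 16 variants anchored at null and full", {
  g <- growth_model(80, 0.25, -0.5)
  bio <- build_empirical_life_table(g, fecundity_model("power", 0.01, 3),
                                    maturity = 3, lifespan = 8)
  # null model: maturity 1, constant survival with 1e-4 of the cohort left
  null <- toggle_life_table_components(bio, 1)
  omega <- 8
  expect_equal(null$female$survival,
               c(rep((1e-4)^(1 / (omega - 1)), omega - 1), 0))
  expect_equal(survivorship(null$female)[omega], 1e-4, tolerance = 1e-12)
  expect_equal(null$female$rel_fecundity, rep(1, omega))
  expect_equal(null$female$maturity, 1)
  # all toggles on reproduces the biological tables
  full <- toggle_life_table_components(bio, 16)
  expect_equal(full$female[c("survival", "rel_fecundity", "maturity")],
               bio$female[c("survival", "rel_fecundity", "maturity")])
  expect_equal(full$male[c("survival", "rel_fecundity", "maturity")],
               bio$male[c("survival", "rel_fecundity", "maturity")])
  # 16 distinct toggle combinations
  sets <- vapply(1:16, function(i) paste(toggle_set(i), collapse = ""),
                 character(1))
  expect_equal(length(unique(sets)), 16L)
  expect_error(toggle_set(17), "1..16")
})

test_that("empirical tables mask fecundity below maturity and mirror symmetric sexes", {
  g <- growth_model(60, 0.4, 0)
  tabs <- build_empirical_life_table(g, fecundity_model("power", 1, 3),
                                     maturity = 3, lifespan = 6)
  expect_equal(tabs$female$rel_fecundity[1:2], c(0, 0))
  expect_gt(tabs$female$rel_fecundity[3], 0)
  expect_equal(tabs$female$survival[6], 0)
  expect_equal(tabs$female[-5], tabs$male[-5])  # identical apart from the label
  # survival follows the mortality-at-length chain at interior ages
  len <- vb_length(1:6, g)
  expect_equal(tabs$female$survival[1:5],
               exp(-(len[1:5] / 60)^(-1.5) * 0.4))
})

test_that("life tables survive a TSV round trip", {
  g <- growth_model(80, 0.25, -0.5)
  tabs <- build_empirical_life_table(g, fecundity_model("power", 0.01, 3),
                                     maturity = 2.5, lifespan = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_life_table(tabs, path, species = "roundtrip test")
  back <- read_life_table(path)
  expect_equal(back$female$survival, tabs$female$survival)
  expect_equal(back$female$rel_fecundity, tabs$female$rel_fecundity)
  expect_equal(back$female$maturity, 2.5)
})
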