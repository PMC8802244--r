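# Shared fixture builders: every fixture is generated in code.

# Random biologically-shaped life tables: survivorship drawn from the
# Weibull family across the full Type III..I range (c in [0.01, 30]),
# random lifespan, maturity in the first half of life, and one of three
# age-fecundity shapes.
random_life_table <- function(seed, max_omega = 15) {
  set.seed(seed)
  omega <- sample(2:max_omega, 1)
  c_shape <- exp(runif(1, log(0.01), log(30)))
  maturity <- sample(seq_len(max(1, ceiling(omega / 2))), 1)
  f_rate <- sample(c(0, 0.25, -0.25), 1)
  build_theoretical_life_table(maturity, omega, c_shape,
                               age_fecundity_model("exponential", f = f_rate),
                               cohort = "recruit")
}

# a Weibull-survivorship recruit table with given shape, for sweep tests
theoretical_table <- function(maturity, lifespan, c, f = 0,
                              model = "constant", cohort = "recruit") {
  build_theoretical_life_table(maturity, lifespan, c,
                               age_fecundity_model(model, f = f),
                               cohort = cohort)
}
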