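#' Construct a life table
#'
#' A life table holds, for one sex of one species, the per-age annual
#' survival probabilities `s_x` (probability of surviving from age x to
#' x + 1) and the non-negative relative fecundities `f_x` over a contiguous
#' integer age range. The terminal survival is always zero: no individual
#' outlives the maximum age. Fecundity is on an arbitrary relative scale;
#' every downstream consumer rescales it (the analytic engine to the
#' replacement level, the forward simulator to sampling weights), so only the
#' shape matters.
#'
#' Two cohort conventions are supported. The usual `"recruit"` convention
#' starts the table at age 1 (the cohort enters after its first year) and
#' masks fecundity below `ceiling(maturity)`. The `"newborn"` convention
#' starts at age 0 and is used for theoretical survivorship scans where the
#' entire Weibull curve, including first-year mortality, belongs to the
#' cohort; such tables carry `masked = FALSE` and fecundity is not zeroed
#' below maturity (see [build_theoretical_life_table()]).
#'
#' @param ages Contiguous integer ages, starting at 0 or 1.
#' @param survival Numeric vector in \[0, 1\], same length as `ages`; the last
#'   element must be 0.
#' @param rel_fecundity Non-negative numeric vector, same length as `ages`.
#' @param maturity Age at first maturity (years, may be fractional). Used for
#'   the adult census and, when `masked = TRUE`, enforced as the fecundity
#'   mask boundary (`f_x = 0` for `x < ceiling(maturity)`).
#' @param sex `"female"`, `"male"` or `"both"`.
#' @param masked Whether fecundity below maturity has been zeroed (default
#'   `TRUE`).
#' @return An object of class `"life_table"`.
#' @export
life_table <- function(ages, survival, rel_fecundity, maturity,
                       sex = c("both", "female", "male"), masked = TRUE) {
  sex <- match.arg(sex)
  lt <- structure(list(ages = as.integer(ages), survival = as.numeric(survival),
                       rel_fecundity = as.numeric(rel_fecundity),
                       maturity = maturity, sex = sex, masked = masked),
                  class = "life_table")
  validate_life_table(lt)
}

#' Validate a life table
#'
#' Enforces the structural invariants: contiguous integer ages starting at 0
#' or 1; survival probabilities in \[0, 1\] with terminal survival exactly 0;
#' non-negative fecundities with at least one positive value; and, for masked
#' tables, zero fecundity below `ceiling(maturity)`.
#'
#' @param lt A `"life_table"`.
#' @return `lt`, invisibly, or an error naming the violated invariant.
#' @export
validate_life_table <- function(lt) {
  if (!inherits(lt, "life_table")) stop("not a life_table")
  n <- length(lt$ages)
  if (n < 1L) stop("life table has no age classes")
  if (!(lt$ages[1] %in% c(0L, 1L)))
    stop("ages must start at 0 or 1")
  if (n > 1L && any(diff(lt$ages) != 1L))
    stop("ages must be contiguous integers")
  if (length(lt$survival) != n || length(lt$rel_fecundity) != n)
    stop("survival and rel_fecundity must match ages in length")
  if (any(!is.finite(lt$survival)) || any(lt$survival < 0 | lt$survival > 1))
    stop("survival probabilities must lie in [0, 1]")
  if (lt$survival[n] != 0)
    stop("terminal survival must be 0 (no individual outlives the maximum age)")
  if (any(!is.finite(lt$rel_fecundity)) || any(lt$rel_fecundity < 0))
    stop("relative fecundities must be non-negative")
  if (all(lt$rel_fecundity == 0))
    stop("all fecundities are zero; the cohort cannot replace itself")
  if (isTRUE(lt$masked)) {
    juv <- lt$ages < ceiling(lt$maturity)
    if (any(lt$rel_fecundity[juv] > 0))
      stop("fecundity must be zero below the age at maturity in a masked table")
  }
  invisible(lt)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("life_table (%s, %s cohort): ages %d..%d, maturity %.3g\n",
              x$sex, if (x$ages[1] == 0L) "newborn" else "recruit",
              x$ages[1], x$ages[length(x$ages)], x$maturity))
  print(data.frame(age = x$ages, survival = x$survival,
                   rel_fecundity = x$rel_fecundity), row.names = FALSE)
  invisible(x)
}

#' Cumulative survivorship of a life table
#'
#' `l_x`, the probability of being alive at age x given presence in the first
#' age class (`l` at the first age is 1 by convention).
#'
#' @param lt A `"life_table"`.
#' @return Numeric vector aligned with `lt$ages`.
#' @export
survivorship <- function(lt) {
  n <- length(lt$survival)
  cumprod(c(1, lt$survival[-n]))
}

# ---- empirical tables (growth + fecundity-length) --------------------------

#' Build an empirical life table from growth and fecundity-length models
#'
#' Survival at each integer age comes from the length-based natural mortality
#' chain: predict length from the Von Bertalanffy model (or use supplied
#' observed lengths), convert to instantaneous mortality
#' `m = (L/L_inf)^(-1.5) K`, then to annual survival `s = exp(-m)`. Survival
#' at the maximum age is set to zero. Fecundity at age is the fecundity-length
#' model evaluated at the age-specific length, zeroed below
#' `ceiling(maturity)`.
#'
#' When male and female growth differ, pass per-sex models to obtain per-sex
#' tables; identical inputs give identical tables.
#'
#' @param growth A `"growth_model"`, or a named list `list(female=, male=)`.
#' @param fecundity A `"fecundity_model"` (female fecundity-length relation;
#'   applied to both sexes as the relative reproductive-output schedule).
#' @param maturity Age at first maturity (years).
#' @param lifespan Maximum age (years, integer >= 1); or a named list
#'   `list(female=, male=)` for sex-specific lifespan.
#' @param lengths_at_age Optional observed lengths at ages `1..lifespan`
#'   (vector, or named list per sex) overriding the growth-curve prediction.
#' @return A named list `list(female=, male=)` of `"life_table"` objects
#'   (ages `1..lifespan`).
#' @export
build_empirical_life_table <- function(growth, fecundity, maturity, lifespan,
                                       lengths_at_age = NULL) {
  per_sex <- function(obj, sex) {
    if (inherits(obj, "growth_model") || !is.list(obj)) obj else obj[[sex]]
  }
  one <- function(sex) {
    g <- per_sex(growth, sex)
    om <- per_sex(lifespan, sex)
    if (om < 1 || om != round(om)) stop("lifespan must be a positive integer")
    if (maturity > om) stop("maturity must not exceed lifespan")
    ages <- seq_len(om)
    len <- if (is.null(lengths_at_age)) vb_length(ages, g)
           else as.numeric(per_sex(lengths_at_age, sex))
    if (length(len) != om) stop("lengths_at_age must cover ages 1..lifespan")
    if (any(len <= 0)) stop("non-positive length at age; check t0/growth model")
    m <- natural_mortality_at_age(len, g, clamp = TRUE)
    s <- annual_survival(m)
    s[om] <- 0
    f <- fecundity_from_length(fecundity, len)
    f[ages < ceiling(maturity)] <- 0
    life_table(ages, s, f, maturity = maturity, sex = sex, masked = TRUE)
  }
  list(female = one("female"), male = one("male"))
}

# ---- theoretical tables (Weibull survivorship x age-fecundity) -------------

#' Weibull scale parameter pinning 1% survivorship at the maximum age
#'
#' For cumulative survivorship `S(t) = exp(-(t/b)^c)`, returns the scale `b`
#' such that `S(lifespan) = 0.01`: `b = lifespan / (-log(0.01))^(1/c)`
#' (natural log).
#'
#' @param lifespan Maximum age (years), > 0.
#' @param c Weibull shape, > 0. `c < 1` gives Type III survivorship (high
#'   juvenile, low adult mortality; fish-like), `c = 1` Type II (constant
#'   mortality; bird-like), `c > 1` Type I (mammal-like).
#' @return Scale `b` (years).
#' @export
#' @examples
#' b <- weibull_scale(10, 1)       # 2.171472
#' exp(-(10 / b)^1)                # 0.01
weibull_scale <- function(lifespan, c) {
  if (!is.finite(lifespan) || lifespan <= 0) stop("lifespan must be > 0")
  if (any(!is.finite(c)) || any(c <= 0)) stop("shape c must be > 0")
  lifespan / (-log(0.01))^(1 / c)
}

#' Construct a Weibull survivorship curve
#'
#' @inheritParams weibull_scale
#' @return An object of class `"weibull_survivorship"` with fields `c`, `b`,
#'   `lifespan`.
#' @export
weibull_survivorship <- function(lifespan, c) {
  structure(list(c = c, b = weibull_scale(lifespan, c), lifespan = lifespan),
            class = "weibull_survivorship")
}

#' Annual mortality probability under a Weibull survivorship curve
#'
#' Probability of dying in the interval \[age, age + 1) given survival to
#' `age`: `M = 1 - exp((age/b)^c - ((age+1)/b)^c)` (the one-year hazard of
#' `S(t) = exp(-(t/b)^c)`). The product of `1 - M` over ages
#' `0..lifespan - 1` recovers the 1% survivorship pinned by
#' [weibull_scale()].
#'
#' @param age Integer age(s) in `0..lifespan - 1`.
#' @param surv A `"weibull_survivorship"`.
#' @return Mortality probability in \[0, 1\].
#' @export
weibull_annual_mortality <- function(age, surv) {
  if (any(age < 0) || any(age >= surv$lifespan))
    stop("age must lie in [0, lifespan)")
  1 - exp((age / surv$b)^surv$c - ((age + 1) / surv$b)^surv$c)
}

#' Construct an age-fecundity model
#'
#' Parametric relative fecundity as a function of age: `"constant"` (equal at
#' all reproductive ages), `"exponential"` (`F = exp(f * age)`; `f > 0` for
#' the increase with age typical of marine fishes, `f < 0` for senescent
#' decline), `"powerlaw"` (`F = age^f`), `"linear"` (`F = 1 + f * age`,
#' clamped at 0), or `"polynomial"` (`F = sum(coef[i] * age^(i-1))`, clamped
#' at 0).
#'
#' @param model One of `"constant"`, `"exponential"`, `"powerlaw"`,
#'   `"linear"`, `"polynomial"`.
#' @param f Shape constant (rate/exponent/slope); ignored for `"constant"`
#'   and `"polynomial"`.
#' @param coef Polynomial coefficients (constant term first), for
#'   `"polynomial"` only.
#' @return An object of class `"age_fecundity_model"`.
#' @export
age_fecundity_model <- function(model = c("constant", "exponential", "powerlaw",
                                          "linear", "polynomial"),
                                f = 0, coef = NULL) {
  model <- match.arg(model)
  if (model == "polynomial" && is.null(coef))
    stop("polynomial model needs coefficients")
  structure(list(model = model, f = f, coef = coef),
            class = "age_fecundity_model")
}

#' Relative fecundity at age, scaled to a maximum of 1
#'
#' Evaluates an [age_fecundity_model()] over a vector of ages, zeroes values
#' below `ceiling(maturity)`, and rescales so the maximum over the admissible
#' (mature) ages is exactly 1. With a negative exponential rate the maximum
#' therefore sits at the age of maturity; with a positive rate at the oldest
#' age.
#'
#' @param model An `"age_fecundity_model"`.
#' @param ages Integer ages (the full age vector of the table being built).
#' @param maturity Age at first maturity; use 0 (with ages starting at 0) for
#'   an unmasked schedule.
#' @return Numeric vector aligned with `ages`, max 1.
#' @export
age_fecundity <- function(model, ages, maturity) {
  if (!inherits(model, "age_fecundity_model")) stop("not an age_fecundity_model")
  if (any(ages < 0)) stop("ages must be >= 0")
  f <- switch(model$model,
    constant    = rep(1, length(ages)),
    exponential = exp(model$f * ages),
    powerlaw    = ifelse(ages > 0, ages^model$f, 0),
    linear      = pmax(1 + model$f * ages, 0),
    polynomial  = pmax(drop(outer(ages, seq_along(model$coef) - 1, `^`)
                            %*% model$coef), 0))
  f[ages < ceiling(maturity)] <- 0
  mx <- max(f)
  if (mx <= 0) stop("age-fecundity schedule is zero at every admissible age")
  f / mx
}

#' Build a theoretical life table from a Weibull survivorship curve
#'
#' Combines [weibull_annual_mortality()] survival with an
#' [age_fecundity()] schedule into a sex-symmetric life table.
#'
#' Under the default `"recruit"` cohort the table spans ages `1..lifespan`
#' with fecundity masked below `ceiling(maturity)`. Under the `"newborn"`
#' cohort the table spans ages `0..lifespan` so that the full survivorship
#' curve, including first-year mortality, belongs to the cohort, and
#' fecundity is applied at every age without maturity masking: this is the
#' convention used by the survivorship-by-fecundity grid scan (see
#' [scan_grid()] and the methods vignette for why).
#'
#' @param maturity Age at first maturity (years).
#' @param lifespan Maximum age (years, integer >= 1).
#' @param c Weibull shape (see [weibull_scale()]).
#' @param fec_model An `"age_fecundity_model"`.
#' @param cohort `"recruit"` (age-1 based, masked) or `"newborn"` (age-0
#'   based, unmasked).
#' @return A `"life_table"` (`sex = "both"`).
#' @export
build_theoretical_life_table <- function(maturity, lifespan, c, fec_model,
                                         cohort = c("recruit", "newborn")) {
  cohort <- match.arg(cohort)
  if (lifespan < 1 || lifespan != round(lifespan))
    stop("lifespan must be a positive integer")
  if (maturity > lifespan) stop("maturity must not exceed lifespan")
  surv <- weibull_survivorship(lifespan, c)
  if (cohort == "recruit") {
    ages <- seq_len(lifespan)
    s <- c(1 - weibull_annual_mortality(ages[-lifespan], surv), 0)
    f <- age_fecundity(fec_model, ages, maturity)
    life_table(ages, s, f, maturity = maturity, sex = "both", masked = TRUE)
  } else {
    ages <- 0:lifespan
    s <- c(1 - weibull_annual_mortality(0:(lifespan - 1), surv), 0)
    f <- age_fecundity(fec_model, ages, maturity = 0)
    lt <- life_table(ages, s, f, maturity = maturity, sex = "both",
                     masked = FALSE)
    lt
  }
}

# ---- component-toggle tables (null model and its 16 variants) --------------

#' Enumerate the component toggles of life-table model variants
#'
#' Four life-table components can differ between species: age at maturity,
#' age-specific survival, age-specific fecundity, and sex-specific
#' differences. Model variants are numbered 1..16 by the binary expansion of
#' `id - 1` with bit weights maturity = 1, age_survival = 2,
#' age_fecundity = 4, sex_specific = 8. Model 1 is the null model (all
#' toggles off); model 16 has every component switched on.
#'
#' @param id Integer in 1..16.
#' @return Named logical vector with elements `maturity`, `age_survival`,
#'   `age_fecundity`, `sex_specific`.
#' @export
toggle_set <- function(id) {
  if (length(id) != 1L || !id %in% 1:16) stop("model id must be in 1..16")
  bits <- as.logical(bitwAnd(id - 1L, c(1L, 2L, 4L, 8L)))
  names(bits) <- c("maturity", "age_survival", "age_fecundity", "sex_specific")
  bits
}

#' Build one of the 16 component-toggle life-table variants
#'
#' Starting from the biological per-sex tables of a species, substitutes
#' constant reference values for every component whose toggle is off:
#' maturity off means maturity 1 (no fecundity masking beyond age 1);
#' age-specific survival off means a constant annual survival chosen so that
#' a fraction 1e-4 (0.01%) of the cohort remains at the maximum age,
#' `s = (1e-4)^(1/(lifespan - 1))`; age-specific fecundity off means equal
#' fecundity at all reproductive ages; sex-specific off means the female
#' components (including lifespan) are used for both sexes. The species'
#' lifespan is always its own: even the null model differs between species
#' through lifespan alone.
#'
#' With every toggle on, the output is identical to the biological input
#' tables.
#'
#' @param tables A named list `list(female=, male=)` of `"life_table"`
#'   objects (e.g. from [build_empirical_life_table()]).
#' @param toggles A named logical vector as returned by [toggle_set()], or a
#'   model id 1..16.
#' @return A named list `list(female=, male=)` of `"life_table"` objects.
#' @export
toggle_life_table_components <- function(tables, toggles) {
  if (is.numeric(toggles)) toggles <- toggle_set(toggles)
  need <- c("maturity", "age_survival", "age_fecundity", "sex_specific")
  if (!all(need %in% names(toggles)))
    stop("toggles must name: ", paste(need, collapse = ", "))
  if (!identical(sort(names(tables)), c("female", "male")))
    stop("tables must be a list(female=, male=)")
  one <- function(sex) {
    bio <- if (toggles[["sex_specific"]]) tables[[sex]] else tables$female
    om <- length(bio$ages)
    stopifnot(bio$ages[1] == 1L)
    s <- if (toggles[["age_survival"]]) bio$survival
         else c(rep((1e-4)^(1 / (om - 1)), om - 1L), 0)
    mat <- if (toggles[["maturity"]]) bio$maturity else 1
    f <- if (toggles[["age_fecundity"]]) {
      bio$rel_fecundity
    } else rep(1, om)
    f[bio$ages < ceiling(mat)] <- 0
    if (toggles[["age_fecundity"]] && !toggles[["maturity"]]) {
      # biological shape without the maturity component: extend the mature
      # schedule's first positive value down to age 1
      first_pos <- which(bio$rel_fecundity > 0)[1]
      f <- bio$rel_fecundity
      f[seq_len(first_pos - 1L)] <- bio$rel_fecundity[first_pos]
    }
    life_table(bio$ages, s, f, maturity = mat, sex = sex, masked = TRUE)
  }
  list(female = one("female"), male = one("male"))
}

# ---- TSV interchange -------------------------------------------------------

#' Write life tables to TSV
#'
#' One row per age per sex, columns `species`, `sex`, `age`, `survival`,
#' `rel_fecundity`. Provenance (maturity, cohort convention) goes into `#`
#' comment lines above the header.
#'
#' @param tables A single `"life_table"` or a `list(female=, male=)`.
#' @param path Output path.
#' @param species Species label written into the first column.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(tables, path, species = "species") {
  if (inherits(tables, "life_table")) tables <- list(both = tables)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  mat <- vapply(tables, function(t) t$maturity, numeric(1))
  writeLines(sprintf("# life table for %s; maturity: %s; cohort: %s", species,
                     paste(unique(mat), collapse = "/"),
                     if (tables[[1]]$ages[1] == 0L) "newborn" else "recruit"),
             con)
  rows <- do.call(rbind, lapply(names(tables), function(sx) {
    t <- tables[[sx]]
    data.frame(species = species, sex = sx, age = t$ages,
               survival = t$survival, rel_fecundity = t$rel_fecundity)
  }))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read life tables from TSV
#'
#' Inverse of [write_life_table()]. The maturity recorded in the `#`
#' provenance line is restored; tables whose first age is 0 are read as
#' unmasked newborn-cohort tables.
#'
#' @param path Path to a life-table TSV.
#' @return A named list of `"life_table"` objects, one per `sex` level in the
#'   file.
#' @export
read_life_table <- function(path) {
  header <- readLines(path, n = 1L)
  mat <- 1
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("maturity: ([0-9.]+)", header))[[1]]
    if (length(m) == 2L) mat <- as.numeric(m[2])
  }
  d <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  out <- lapply(split(d, d$sex), function(dd) {
    dd <- dd[order(dd$age), ]
    life_table(dd$age, dd$survival, dd$rel_fecundity, maturity = mat,
               sex = if (dd$sex[1] %in% c("female", "male")) dd$sex[1] else "both",
               masked = dd$age[1] == 1L)
  })
  out
}
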