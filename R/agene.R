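#' Scale a life table into a stable-population cohort schedule
#'
#' Under constant population size and stable age structure, each newborn
#' cohort must exactly replace itself: the expected lifetime offspring number
#' of a cohort member equals 2 (one for each parent of every offspring). This
#' function rescales the table's relative fecundities `f_x` into absolute
#' per-year means `b_x = C f_x` with `C` chosen so that
#' `sum(l_x * b_x) = 2`, and assembles the quantities the analytic engine
#' needs: cumulative survivorship `l_x`, age-at-death distribution
#' `d_x = l_x - l_{x+1}`, cumulative expected offspring `K_x`, and the
#' within-age variance-to-mean ratio `phi_x`.
#'
#' @param lt A `"life_table"`.
#' @param phi Ratio of variance to mean of same-year offspring numbers among
#'   same-age individuals. `phi = 1` is Poisson (no sweepstakes
#'   overdispersion among same-age individuals, the default); `phi = 0` makes
#'   reproduction deterministic given age.
#' @return An object of class `"cohort_schedule"` with fields `ages`, `l_x`,
#'   `b_x`, `d_x`, `K_x`, `phi_x`, `maturity`.
#' @export
#' @examples
#' lt <- life_table(1:2, c(0.5, 0), c(1, 1), maturity = 1)
#' s <- cohort_schedule(lt)
#' s$b_x            # 4/3, 4/3: scaled so 1*b1 + 0.5*b2 = 2
#' sum(s$d_x)       # 1: every individual dies at some age
cohort_schedule <- function(lt, phi = 1) {
  validate_life_table(lt)
  if (any(!is.finite(phi)) || any(phi < 0)) stop("phi must be >= 0")
  lx <- survivorship(lt)
  denom <- sum(lx * lt$rel_fecundity)
  if (denom <= 0) stop("all reproductive output is zero; cannot scale")
  b <- 2 * lt$rel_fecundity / denom
  n <- length(lx)
  d <- lx - c(lx[-1], 0)
  structure(list(ages = lt$ages, l_x = lx, b_x = b, d_x = d,
                 K_x = cumsum(b), phi_x = rep_len(phi, n),
                 maturity = lt$maturity),
            class = "cohort_schedule")
}

#' Generation length of a scaled cohort schedule
#'
#' Mean age of the parents of a newborn cohort at stable age structure:
#' `T = sum(x * l_x * b_x) / sum(l_x * b_x)`.
#'
#' @param sched A `"cohort_schedule"`.
#' @return Generation length (years).
#' @export
generation_length <- function(sched) {
  sum(sched$ages * sched$l_x * sched$b_x) / sum(sched$l_x * sched$b_x)
}

#' Lifetime reproductive-success moments of a cohort
#'
#' Mean and variance across a newborn cohort of the total number of offspring
#' produced over life, by the law of total variance over the age at death:
#' an individual dying at age x has produced `Poisson`-type offspring at each
#' age `j <= x` (variance `phi_j * b_j`) around the cumulative mean `K_x`, so
#'
#' `Vk = sum_x d_x * ( sum_{j<=x} phi_j b_j + (K_x - k_bar)^2 )`,
#'
#' with `k_bar = sum_x d_x K_x = 2` under the stable-population scaling. The
#' first term is within-trajectory reproductive noise; the second is the
#' between-individual inequality generated purely by differences in
#' survival and age-specific fecundity — the component life tables control.
#'
#' @param sched A `"cohort_schedule"`.
#' @return A list with `k_bar` (= 2 up to rounding) and `Vk`.
#' @export
lifetime_rs_moments <- function(sched) {
  k_bar <- sum(sched$d_x * sched$K_x)
  Vk <- sum(sched$d_x * (cumsum(sched$phi_x * sched$b_x) +
                           (sched$K_x - k_bar)^2))
  list(k_bar = k_bar, Vk = Vk)
}

#' Effective population size and Ne/N from two-sex life tables
#'
#' The analytic engine: per-sex cohort schedules are scaled with
#' [cohort_schedule()], lifetime variances combined with sex-ratio weights
#' (both sexes share mean 2, so no between-sex mean component at a 0.5 sex
#' ratio), generation length averaged, and the effective size obtained from
#' Hill's overlapping-generations formula
#'
#' `Ne = 4 * N1 * T / (Vk + 2)`,
#'
#' where `N1` newborns enter the population each year. `N1` cancels from
#' `Ne/N`, so its value is arbitrary.
#'
#' Three census policies for the denominator `N` are exposed, because which
#' individuals "count" is a modelling convention, not a fact:
#' \describe{
#'   \item{`"adults"`}{individuals at ages `>= ceiling(maturity)` (mature
#'     census), the default.}
#'   \item{`"all"`}{all individuals at ages `>= 1`.}
#'   \item{`"generation"`}{one generation's worth of newborns, `N = N1 * T`,
#'     which reduces the ratio to the classic variance form
#'     `Ne/N = 4 / (Vk + 2)`. The survivorship-by-fecundity grid scan uses
#'     this policy; see the methods vignette.}
#' }
#'
#' @param table_f Female `"life_table"`.
#' @param table_m Male `"life_table"`; defaults to the female table
#'   (sex-symmetric).
#' @param N1 Newborns entering per year (both sexes combined). Arbitrary;
#'   affects `Ne` and `N` proportionally, never their ratio.
#' @param sex_ratio Proportion of newborns that are female.
#' @param phi Within-age variance-to-mean ratio (see [cohort_schedule()]).
#' @param census Census policy, see above.
#' @return An object of class `"agene_result"`: list with `Vk_f`, `Vk_m`,
#'   `Vk`, `k_bar`, `T`, `N1`, `Ne`, `N_census`, `ratio`, `census`, `phi`.
#' @export
#' @examples
#' # a semelparous, maturity-1 table is the Wright-Fisher limit: Ne/N = 1
#' lt <- life_table(1L, 0, 1, maturity = 1)
#' effective_size_ratio(lt)$ratio
effective_size_ratio <- function(table_f, table_m = table_f, N1 = 1000,
                                 sex_ratio = 0.5, phi = 1,
                                 census = c("adults", "all", "generation")) {
  census <- match.arg(census)
  if (!is.finite(N1) || N1 <= 0) stop("N1 must be > 0")
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("sex_ratio must be in (0, 1)")
  sf <- cohort_schedule(table_f, phi)
  sm <- cohort_schedule(table_m, phi)
  mf <- lifetime_rs_moments(sf)
  mm <- lifetime_rs_moments(sm)
  Vk <- sex_ratio * mf$Vk + (1 - sex_ratio) * mm$Vk
  Tg <- sex_ratio * generation_length(sf) +
        (1 - sex_ratio) * generation_length(sm)
  Ne <- 4 * N1 * Tg / (Vk + 2)
  count <- function(s, share, keep) N1 * share * sum(s$l_x[keep])
  N_census <- switch(census,
    adults = count(sf, sex_ratio, sf$ages >= ceiling(sf$maturity) & sf$ages >= 1) +
             count(sm, 1 - sex_ratio, sm$ages >= ceiling(sm$maturity) & sm$ages >= 1),
    all = count(sf, sex_ratio, sf$ages >= 1) +
          count(sm, 1 - sex_ratio, sm$ages >= 1),
    generation = N1 * Tg)
  if (N_census <= 0) stop("census is empty under policy '", census, "'")
  structure(list(Vk_f = mf$Vk, Vk_m = mm$Vk, Vk = Vk,
                 k_bar = sex_ratio * mf$k_bar + (1 - sex_ratio) * mm$k_bar,
                 T = Tg, N1 = N1, Ne = Ne, N_census = N_census,
                 ratio = Ne / N_census, census = census, phi = phi),
            class = "agene_result")
}

#' @export
print.agene_result <- function(x, ...) {
  cat(sprintf(paste0("Vk = %.4f (f %.4f / m %.4f), T = %.3f yr, ",
                     "Ne = %.1f, N[%s] = %.1f, Ne/N = %.4f\n"),
              x$Vk, x$Vk_f, x$Vk_m, x$T, x$Ne, x$census, x$N_census, x$ratio))
  invisible(x)
}

#' Monte-Carlo cohort oracle for lifetime reproductive success
#'
#' Simulates `n` independent cohort members through the life table: at each
#' age an individual alive draws its year's offspring (Poisson with mean
#' `b_x` when `phi = 1`, exactly `b_x` when `phi = 0`), then survives to the
#' next age with probability `s_x`. Returns the empirical mean and variance
#' of lifetime offspring with asymptotic (delta-method) standard errors, for
#' checking [lifetime_rs_moments()] against an implementation that shares
#' none of its algebra.
#'
#' @param lt A `"life_table"`.
#' @param n Cohort size, at least 1000.
#' @param phi 0 or 1 (deterministic or Poisson within-age reproduction).
#' @param seed Optional integer seed (set for reproducibility).
#' @return List with `k_bar_emp`, `Vk_emp`, `se_k_bar`, `se_Vk`, `n`.
#' @export
monte_carlo_cohort_vk <- function(lt, n = 200000, phi = 1, seed = NULL) {
  validate_life_table(lt)
  if (n < 1000) stop("n must be at least 1000 for a usable oracle")
  if (!phi %in% c(0, 1)) stop("the Monte-Carlo oracle supports phi = 0 or 1")
  if (!is.null(seed)) set.seed(seed)
  sched <- cohort_schedule(lt, phi)
  k <- numeric(n)
  alive <- rep(TRUE, n)
  for (i in seq_along(sched$ages)) {
    na <- sum(alive)
    if (na == 0L) break
    k[alive] <- k[alive] + if (phi == 1) stats::rpois(na, sched$b_x[i])
                           else sched$b_x[i]
    alive[alive] <- stats::runif(na) < lt$survival[i]
  }
  m <- mean(k); v <- stats::var(k)
  m4 <- mean((k - m)^4)
  list(k_bar_emp = m, Vk_emp = v,
       se_k_bar = stats::sd(k) / sqrt(n),
       se_Vk = sqrt(pmax(m4 - (n - 3) / (n - 1) * v^2, 0) / n),
       n = n)
}
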