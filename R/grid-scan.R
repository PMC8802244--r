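#' Default survivorship-shape and fecundity-exponent grids
#'
#' The shape grid spans `c` in \[0.01, 30\] (60 log-spaced values) with the
#' landmark shapes 0.1 and 1.03 appended exactly; the fecundity-exponent
#' grid spans `f` in \[-1, 1\] (41 linear values, including 0 and the
#' empirical median rate 0.142 appended exactly).
#'
#' @return Numeric vector of grid values.
#' @export
default_c_grid <- function() {
  sort(unique(c(exp(seq(log(0.01), log(30), length.out = 60)), 0.1, 1.03)))
}

#' @rdname default_c_grid
#' @export
default_f_grid <- function() {
  sort(unique(c(seq(-1, 1, length.out = 41), 0.142)))
}

#' Specify a survivorship-by-fecundity grid scan
#'
#' @param c_values Weibull shape values (> 0); default [default_c_grid()].
#' @param f_values Age-fecundity shape constants; default [default_f_grid()]
#'   (collapsed to 0 for the constant model).
#' @param fecundity_model One of `"constant"`, `"exponential"`,
#'   `"powerlaw"`, `"linear"`, `"polynomial"`.
#' @param species A `data.frame` with columns `species`, `maturity`,
#'   `lifespan` (and `adult_lifespan`, recomputed if absent); defaults to
#'   the bundled 16-species trait table.
#' @param poly_coef Polynomial coefficients when
#'   `fecundity_model = "polynomial"`.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(c_values = default_c_grid(),
                      f_values = default_f_grid(),
                      fecundity_model = c("constant", "exponential",
                                          "powerlaw", "linear", "polynomial"),
                      species = marine_fish_traits(),
                      poly_coef = NULL) {
  fecundity_model <- match.arg(fecundity_model)
  if (length(c_values) == 0 || any(c_values <= 0))
    stop("c_values must be positive and non-empty")
  if (fecundity_model == "constant") f_values <- 0
  if (length(f_values) == 0) stop("f_values must be non-empty")
  if (!all(c("maturity", "lifespan") %in% names(species)))
    stop("species must have maturity and lifespan columns")
  if (is.null(species$adult_lifespan))
    species$adult_lifespan <- species$lifespan - species$maturity
  structure(list(c_values = sort(c_values), f_values = sort(f_values),
                 fecundity_model = fecundity_model, species = species,
                 poly_coef = poly_coef),
            class = "grid_spec")
}

#' Scan the Ne/N vs adult-lifespan relationship over a vital-rates grid
#'
#' For every combination of Weibull survivorship shape `c` and age-fecundity
#' constant `f`, builds one theoretical life table per species (newborn
#' cohort: the full survivorship curve from age 0 belongs to the cohort and
#' fecundity is applied at every age; see the methods vignette), computes
#' Ne/N with the analytic engine under the generation census
#' (`Ne/N = 4 / (Vk + 2)`, Poisson within-age variance), and regresses the
#' 16 Ne/N values on adult lifespan by OLS. The stage is fully
#' deterministic: identical specs give bit-identical surfaces.
#'
#' @param spec A `"grid_spec"`.
#' @return An object of class `"grid_surface"`: a long-format `data.frame`
#'   with columns `c`, `f`, `model`, `slope`, `R2`, `p`, plus attributes
#'   `spec` and `ratios` (matrix of per-species Ne/N at each grid point).
#' @export
#' @examples
#' surf <- scan_grid(grid_spec(c_values = c(0.1, 1), fecundity_model = "constant"))
#' surf[, c("c", "slope", "R2")]
scan_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  sp <- spec$species
  grid <- expand.grid(c = spec$c_values, f = spec$f_values,
                      KEEP.OUT.ATTRS = FALSE)
  ratios <- matrix(NA_real_, nrow(grid), nrow(sp))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fec <- age_fecundity_model(spec$fecundity_model, f = grid$f[g],
                               coef = spec$poly_coef)
    r <- vapply(seq_len(nrow(sp)), function(i) {
      lt <- build_theoretical_life_table(sp$maturity[i], sp$lifespan[i],
                                         grid$c[g], fec, cohort = "newborn")
      effective_size_ratio(lt, phi = 1, census = "generation")$ratio
    }, numeric(1))
    ratios[g, ] <- r
    fit <- ols_slope_r2(sp$adult_lifespan, r)
    rows[[g]] <- data.frame(c = grid$c[g], f = grid$f[g],
                            model = spec$fecundity_model,
                            slope = fit$slope, R2 = fit$R2, p = fit$p_slope)
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$slope)) stop("grid scan produced incomplete cells")
  class(out) <- c("grid_surface", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "ratios") <- ratios
  out
}

#' Locate the extremes of a grid surface
#'
#' Reports the steepest negative slope of the Ne/N vs adult-lifespan
#' regression with the grid point where it occurs, the maximum R-squared
#' cell, and the region (if any) of significantly positive slopes.
#'
#' @param surface A `"grid_surface"`.
#' @param alpha Significance level used to flag positive-slope cells.
#' @return List with `steepest` (one-row data.frame), `max_R2` (one-row
#'   data.frame), and `positive` (data.frame of significantly positive
#'   cells, possibly empty).
#' @export
summarize_extremes <- function(surface, alpha = 0.05) {
  stopifnot(inherits(surface, "grid_surface"))
  df <- as.data.frame(surface)
  list(steepest = df[which.min(df$slope), , drop = FALSE],
       max_R2 = df[which.max(df$R2), , drop = FALSE],
       positive = df[df$slope > 0 & df$p < alpha, , drop = FALSE])
}
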