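#' Deterministic synthetic growth and fecundity parameters for a trait table
#'
#' The per-species Von Bertalanffy and fecundity-length parameters behind
#' the empirical life tables come from species-specific fisheries studies
#' and are not bundled with this package. This helper derives a synthetic
#' stand-in set from the trait table itself, using robust fisheries
#' rules-of-thumb: asymptotic length slightly above the recorded body size
#' (`L_inf = body_size / 0.85`), growth coefficient inversely proportional
#' to lifespan (`K = 3 / lifespan`, so growth is ~95% complete at the
#' maximum age), `t0 = -0.5`, and a cubic fecundity-length power law
#' (`F = 0.01 L^3.05`). It exists so the empirical pipeline can be exercised
#' end-to-end and is clearly labelled synthetic; results derived from it
#' are structural, not species-specific.
#'
#' @param traits A trait `data.frame`.
#' @return A `data.frame` with columns `species`, `L_inf`, `K`, `t0`,
#'   `fec_form`, `fec_alpha`, `fec_beta` and attribute `synthetic = TRUE`.
#' @export
synthetic_growth_params <- function(traits = marine_fish_traits()) {
  out <- data.frame(species = traits$species,
                    L_inf = traits$body_size / 0.85,
                    K = 3 / traits$lifespan,
                    t0 = -0.5,
                    fec_form = "power",
                    fec_alpha = 0.01,
                    fec_beta = 3.05)
  attr(out, "synthetic") <- TRUE
  out
}

#' Build per-species empirical life tables from a growth-parameter table
#'
#' @param traits A trait `data.frame` (maturity and lifespan per species).
#' @param params A growth-parameter `data.frame` as in
#'   [synthetic_growth_params()] (one row per species, or per species and
#'   sex with a `sex` column using levels `female`/`male`).
#' @return Named list (by species) of `list(female=, male=)` life tables;
#'   species present in `traits` but absent from `params` are skipped with
#'   a warning.
#' @export
species_life_tables <- function(traits, params) {
  out <- list()
  for (i in seq_len(nrow(traits))) {
    sp <- traits$species[i]
    pr <- params[params$species == sp, , drop = FALSE]
    if (nrow(pr) == 0L) {
      warning("no growth parameters for ", sp, "; species skipped")
      next
    }
    pick <- function(sex) {
      if ("sex" %in% names(pr) && sex %in% pr$sex) pr[pr$sex == sex, ][1, ]
      else pr[1, ]
    }
    g <- lapply(c(female = "female", male = "male"), function(sx) {
      p <- pick(sx); growth_model(p$L_inf, p$K, p$t0)
    })
    p1 <- pr[1, ]
    fec <- fecundity_model(p1$fec_form, p1$fec_alpha, p1$fec_beta)
    out[[sp]] <- build_empirical_life_table(
      g, fec, maturity = traits$maturity[i], lifespan = traits$lifespan[i])
  }
  out
}

#' Hash a run configuration
#'
#' Canonical-JSON MD5 of a configuration list; embedded in every output file
#' so results can be traced to the exact configuration that produced them.
#' Any parameter change changes the hash.
#'
#' @param config A list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  config <- config[!vapply(config, is.function, logical(1))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file with optional blocks `traits`,
#'   `growth_params`, `agene` (`n1`, `phi`, `sex_ratio`, `census`,
#'   `models`), `grid` (`model`, `c_values`, `f_values`), `forward`
#'   (`species`, `n_total`, `mu`, `l_sites`, `years`, `window`,
#'   `replicates`), and a top-level `seed`.
#' @return The configuration as a named list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

.load_inputs <- function(config) {
  traits <- if (is.null(config$traits)) marine_fish_traits()
            else read_species_traits(config$traits)
  params <- if (is.null(config$growth_params) ||
                identical(config$growth_params, "synthetic"))
              synthetic_growth_params(traits)
            else utils::read.delim(config$growth_params,
                                   stringsAsFactors = FALSE)
  list(traits = traits, params = params)
}

.provenance <- function(config, seed) {
  sprintf("# vitalNe %s; config_hash %s; seed %s",
          as.character(utils::packageVersion("vitalNe")),
          config_hash(config), seed)
}

.write_tsv <- function(df, path, header_lines) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the empirical pipeline: life tables to Ne/N to diversity regressions
#'
#' For each requested component-toggle model (1..16, see [toggle_set()]):
#' build every species' toggled life tables, compute Ne/N with the analytic
#' engine, scale Ne/N and observed diversity by their maxima, and fit the
#' beta regression of scaled diversity on scaled Ne/N for the full species
#' set and for the nonbrooders. Scaling is by refitting on the scaled
#' variables, never by rescaling coefficients.
#'
#' @param config A configuration list (see [read_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `ratios` (species x model matrix of Ne/N)
#'   and `report` (per-model regression summaries, also written to TSV).
#' @export
run_empirical <- function(config = list(), out_dir = tempfile("empirical_")) {
  inputs <- .load_inputs(config)
  traits <- inputs$traits
  ag <- config$agene
  n1 <- ag$n1 %||% 1000; phi <- ag$phi %||% 1
  sr <- ag$sex_ratio %||% 0.5; census <- ag$census %||% "adults"
  models <- ag$models %||% 1:16
  tabs <- species_life_tables(traits, inputs$params)
  traits <- traits[traits$species %in% names(tabs), , drop = FALSE]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ratios <- matrix(NA_real_, nrow(traits), length(models),
                   dimnames = list(traits$species, paste0("model_", models)))
  rows <- list()
  for (j in seq_along(models)) {
    id <- models[j]
    res <- lapply(traits$species, function(sp) {
      t2 <- toggle_life_table_components(tabs[[sp]], id)
      effective_size_ratio(t2$female, t2$male, N1 = n1, sex_ratio = sr,
                           phi = phi, census = census)
    })
    ratios[, j] <- vapply(res, `[[`, numeric(1), "ratio")
    for (subset_name in c("all", "nonbrooders")) {
      keep <- if (subset_name == "all") rep(TRUE, nrow(traits))
              else !is_brooder(traits)
      r_sc <- ratios[keep, j] / max(ratios[keep, j])
      d_sc <- traits$diversity[keep] / max(traits$diversity[keep])
      d_sc <- pmin(d_sc, 1 - 1e-9)  # the maximum itself must stay inside (0,1)
      fit <- fit_beta_regression(d_sc, cbind(ratio = r_sc))
      rows[[length(rows) + 1L]] <- data.frame(
        model = id, subset = subset_name, n = sum(keep),
        slope = fit$coefficients[["ratio"]], pseudo_R2 = fit$pseudo_R2,
        p = fit$wald_p[["ratio"]])
    }
  }
  report <- do.call(rbind, rows)
  prov <- .provenance(config, config$seed %||% 1L)
  .write_tsv(data.frame(species = rownames(ratios), ratios),
             file.path(out_dir, "ne_ratios.tsv"), prov)
  .write_tsv(report, file.path(out_dir, "regressions.tsv"), prov)
  invisible(list(ratios = ratios, report = report, out_dir = out_dir))
}

#' Run the theoretical grid scan and write its surface
#'
#' @param config Configuration list; the `grid` block may set `model`,
#'   `c_values`, `f_values` (`"default"` or numeric vectors).
#' @param out_dir Output directory.
#' @return Invisibly, the `"grid_surface"` (also written to
#'   `grid_surface.tsv`).
#' @export
run_grid <- function(config = list(), out_dir = tempfile("grid_")) {
  inputs <- .load_inputs(config)
  gr <- config$grid
  cvals <- gr$c_values
  if (is.null(cvals) || identical(cvals, "default")) cvals <- default_c_grid()
  fvals <- gr$f_values
  if (is.null(fvals) || identical(fvals, "default")) fvals <- default_f_grid()
  spec <- grid_spec(c_values = as.numeric(cvals), f_values = as.numeric(fvals),
                    fecundity_model = gr$model %||% "constant",
                    species = inputs$traits)
  surf <- scan_grid(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(as.data.frame(surf), file.path(out_dir, "grid_surface.tsv"),
             .provenance(config, config$seed %||% 1L))
  invisible(surf)
}

#' Run forward simulations for selected species and write trajectories
#'
#' @param config Configuration list; the `forward` block selects `species`
#'   (default: first species of the trait table), `n_total`, `mu`,
#'   `l_sites`, `years`, `window`, `replicates`, `record_every`.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of `"diversity_sim"` results; per-species
#'   trajectory and summary TSVs are written to `out_dir`.
#' @export
run_forward <- function(config = list(), out_dir = tempfile("forward_")) {
  inputs <- .load_inputs(config)
  fw <- config$forward
  traits <- inputs$traits
  species <- fw$species %||% traits$species[1]
  seed <- as.integer(config$seed %||% 1L)
  tabs <- species_life_tables(traits[traits$species %in% species, ],
                              inputs$params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(config, seed)
  out <- list()
  for (sp in names(tabs)) {
    cfg <- sim_config(tabs[[sp]]$female, tabs[[sp]]$male,
                      N_total = fw$n_total %||% 200,
                      mu = fw$mu %||% 1e-6,
                      L_sites = fw$l_sites %||% 10000,
                      years_total = fw$years,
                      eq_window = fw$window %||% 2000,
                      replicates = fw$replicates %||% 2,
                      seed = seed, record_every = fw$record_every %||% 10)
    sim <- simulate_diversity(cfg)
    traj <- data.frame(year = rep(sim$years, ncol(sim$H)),
                       replicate = rep(seq_len(ncol(sim$H)), each = nrow(sim$H)),
                       H = as.vector(sim$H))
    safe <- gsub("[^A-Za-z0-9]+", "_", sp)
    .write_tsv(traj, file.path(out_dir, paste0("trajectory_", safe, ".tsv")), prov)
    .write_tsv(cbind(species = sp, sim$equilibrium),
               file.path(out_dir, paste0("summary_", safe, ".tsv")), prov)
    out[[sp]] <- sim
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
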