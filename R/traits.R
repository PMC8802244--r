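#' Species trait table for 16 northeast Atlantic / Mediterranean teleosts
#'
#' Returns the bundled life-history trait table for the 16 marine teleost
#' species with broadly overlapping Atlantic-Mediterranean distributions that
#' motivate this package. One row per species with its observed genome-wide
#' genetic diversity (median individual heterozygosity, stored as a
#' proportion, i.e. fraction of heterozygous sites) and eight life-history
#' traits compiled from the fisheries literature.
#'
#' Columns: `species`, `diversity` (proportion in (0,1)), `body_size` (cm),
#' `trophic_level`, `fecundity` (eggs/day; `NA` where no estimate exists),
#' `propagule_size` (mm), `maturity` (age at first maturity, years; may be
#' fractional), `lifespan` (maximum age, years), `adult_lifespan`
#' (`lifespan - maturity`, years), `parental_care` (one of `"none"`,
#' `"nest_guarder"`, `"brood_pouch"`), `hermaphroditism` (one of `"none"`,
#' `"protogynous"`, `"protandrous"`, `"rudimentary"`).
#'
#' Species whose males guard nests or carry eggs in a brood pouch
#' (`parental_care != "none"`) are referred to as brooders throughout the
#' package; the remaining 11 species are the nonbrooders.
#'
#' @return A `data.frame` with 16 rows and the 11 columns above, validated by
#'   [validate_species_traits()].
#' @seealso [read_species_traits()] to load a user-supplied table with the
#'   same layout.
#' @export
#' @examples
#' tr <- marine_fish_traits()
#' nrow(tr)                       # 16
#' sum(tr$parental_care != "none")  # 5 brooding species
marine_fish_traits <- function() {
  path <- system.file("extdata", "marine_fish_traits.tsv", package = "vitalNe",
                      mustWork = TRUE)
  read_species_traits(path)
}

#' Read a species trait table from TSV
#'
#' Reads a tab-separated trait table with the column layout documented in
#' [marine_fish_traits()] ("." decimal separator, one header line, UTF-8) and
#' validates it.
#'
#' @param path Path to a TSV file.
#' @return A validated trait `data.frame`.
#' @export
read_species_traits <- function(path) {
  tr <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  validate_species_traits(tr)
}

#' Write a species trait table to TSV
#'
#' @param traits A trait `data.frame` (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_traits <- function(traits, path) {
  traits <- validate_species_traits(traits)
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a species trait table
#'
#' Checks the structural invariants every trait table must satisfy before it
#' enters the pipeline: all diversities strictly inside (0, 1); maturity at
#' least half a year; lifespan no smaller than maturity; `adult_lifespan`
#' equal to `lifespan - maturity`; parental-care and hermaphroditism levels
#' drawn from their closed vocabularies.
#'
#' @param traits A `data.frame` with the columns of [marine_fish_traits()].
#' @return `traits`, with `brooder` derivable via `parental_care != "none"`,
#'   invisibly returned as a plain `data.frame`. Errors describe the first
#'   violated invariant.
#' @export
validate_species_traits <- function(traits) {
  required <- c("species", "diversity", "body_size", "trophic_level",
                "fecundity", "propagule_size", "maturity", "lifespan",
                "adult_lifespan", "parental_care", "hermaphroditism")
  missing <- setdiff(required, names(traits))
  if (length(missing) > 0L)
    stop("trait table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(traits) < 1L) stop("trait table has no rows")
  if (anyDuplicated(traits$species))
    stop("duplicated species names in trait table")
  if (any(!is.finite(traits$diversity)) ||
      any(traits$diversity <= 0 | traits$diversity >= 1))
    stop("diversity must be a proportion strictly inside (0, 1); ",
         "divide printed percentages by 100")
  if (any(traits$maturity < 0.5))
    stop("maturity must be at least 0.5 years")
  if (any(traits$lifespan < traits$maturity))
    stop("lifespan must be >= maturity")
  if (any(abs(traits$adult_lifespan - (traits$lifespan - traits$maturity)) > 1e-8))
    stop("adult_lifespan must equal lifespan - maturity")
  care_levels <- c("none", "nest_guarder", "brood_pouch")
  if (!all(traits$parental_care %in% care_levels))
    stop("parental_care must be one of: ", paste(care_levels, collapse = ", "))
  herm_levels <- c("none", "protogynous", "protandrous", "rudimentary")
  if (!all(traits$hermaphroditism %in% herm_levels))
    stop("hermaphroditism must be one of: ", paste(herm_levels, collapse = ", "))
  traits
}

#' Flag brooding species
#'
#' @param traits A trait `data.frame`.
#' @return Logical vector, `TRUE` for species providing parental care
#'   (nest guarding or a male brood pouch).
#' @export
is_brooder <- function(traits) {
  traits$parental_care != "none"
}
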