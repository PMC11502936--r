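#' Analysis configuration
#'
#' Bundles the scalar parameters that drive the energy-budget carrying
#' capacity calculation.
#'
#' @param daily_requirement_low_kJ Lower daily energy requirement of a red
#'   squirrel, kJ/day. The *upper* capacity bound divides by this value.
#'   Default 400.
#' @param daily_requirement_high_kJ Upper daily energy requirement, kJ/day.
#'   The *lower* capacity bound divides by this value. Default 700.
#' @param horizon_days Number of days the seasonal cone crop is assumed to
#'   feed the population. Default 365 (one year per crop).
#' @param area_density_per_ha Squirrel density (animals/ha) used by the
#'   area-based capacity estimate, taken from a comparable Sitka
#'   spruce/lodgepole pine forest. Default 0.32.
#' @param maturity_age_years Stand age (years since planting) at which a
#'   conifer stand is considered to produce a usable cone crop; the
#'   comparison is inclusive ("25 years or older"). Default 25.
#' @param seeds_per_scale Seeds assumed per cone scale for the scale-count
#'   method (Sitka spruce). Default 1 (one seed per scale).
#'
#' @return A list of class `analysis_config`.
#' @export
#' @examples
#' analysis_config()
analysis_config <- function(daily_requirement_low_kJ = 400,
                            daily_requirement_high_kJ = 700,
                            horizon_days = 365,
                            area_density_per_ha = 0.32,
                            maturity_age_years = 25,
                            seeds_per_scale = 1) {
  assert_positive(daily_requirement_low_kJ, "daily_requirement_low_kJ")
  assert_positive(daily_requirement_high_kJ, "daily_requirement_high_kJ")
  assert_positive(horizon_days, "horizon_days")
  assert_positive(area_density_per_ha, "area_density_per_ha")
  assert_positive(maturity_age_years, "maturity_age_years")
  assert_positive(seeds_per_scale, "seeds_per_scale")
  if (daily_requirement_low_kJ >= daily_requirement_high_kJ) {
    cc_abort("`daily_requirement_low_kJ` must be below `daily_requirement_high_kJ`.",
             class = "conecap_domain_error")
  }
  structure(
    list(daily_requirement_low_kJ = daily_requirement_low_kJ,
         daily_requirement_high_kJ = daily_requirement_high_kJ,
         horizon_days = as.integer(horizon_days),
         area_density_per_ha = area_density_per_ha,
         maturity_age_years = as.integer(maturity_age_years),
         seeds_per_scale = seeds_per_scale),
    class = "analysis_config"
  )
}

#' Per-species seed energy and allometry parameters
#'
#' Each species carries the energy value of a single seed (kJ) and, where the
#' scale-count method is unreliable (lodgepole pine), an allometric function
#' mapping mean cone length (mm) to seeds per cone. The allometric spec is a
#' list with a `family` ("linear") and coefficients `slope` (seeds/mm) and
#' `intercept` (seeds).
#'
#' The default lodgepole calibration is linear through the origin with slope
#' 54/42.8 seeds per mm, anchored at the published point (mean length 42.8 mm
#' corresponding to 54 seeds per cone); alternative coefficients can be
#' injected here.
#'
#' @return A named list (by species) of `species_params` lists with fields
#'   `species`, `seed_energy_kJ`, `allometric`.
#' @export
#' @examples
#' default_species_params()$lodgepole_pine
default_species_params <- function() {
  list(
    sitka_spruce = species_params("sitka_spruce", seed_energy_kJ = 0.04),
    lodgepole_pine = species_params(
      "lodgepole_pine", seed_energy_kJ = 0.098,
      allometric = list(family = "linear", slope = 54 / 42.8, intercept = 0)
    )
  )
}

#' @param species One of `"sitka_spruce"`, `"lodgepole_pine"`.
#' @param seed_energy_kJ Energy value of one seed, kJ (> 0).
#' @param allometric Optional allometric spec (see Details in
#'   [default_species_params()]).
#' @rdname default_species_params
#' @export
species_params <- function(species, seed_energy_kJ, allometric = NULL) {
  assert_species(species)
  assert_positive(seed_energy_kJ, "seed_energy_kJ")
  if (!is.null(allometric)) {
    if (!is.list(allometric) || is.null(allometric$family)) {
      cc_abort("`allometric` must be a list with a `family` field.",
               class = "conecap_config_error")
    }
    if (!identical(allometric$family, "linear")) {
      cc_abort(sprintf("Unsupported allometric family '%s'.", allometric$family),
               class = "conecap_config_error")
    }
    if (is.null(allometric$slope)) {
      cc_abort("Linear allometric spec needs a `slope` coefficient.",
               class = "conecap_config_error")
    }
    if (is.null(allometric$intercept)) allometric$intercept <- 0
  }
  structure(list(species = species,
                 seed_energy_kJ = seed_energy_kJ,
                 allometric = allometric),
            class = "species_params")
}

#' Read configuration from YAML
#'
#' Reads an `analysis_config` and optional per-species parameters from a YAML
#' file. Top-level keys mirror the arguments of [analysis_config()]; an
#' optional `species:` map carries `seed_energy_kJ` and `allometric` entries
#' per species. Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (an `analysis_config`) and `species`
#'   (a named list of `species_params`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    cc_abort(sprintf("Config file not found: %s", path), class = "conecap_io_error")
  }
  raw <- yaml::read_yaml(path)
  cfg_args <- raw[intersect(names(raw), names(formals(analysis_config)))]
  cfg <- do.call(analysis_config, cfg_args)
  sp <- default_species_params()
  for (nm in names(raw$species %||% list())) {
    entry <- raw$species[[nm]]
    sp[[nm]] <- species_params(
      nm,
      seed_energy_kJ = entry$seed_energy_kJ %||% sp[[nm]]$seed_energy_kJ,
      allometric = entry$allometric %||% sp[[nm]]$allometric
    )
  }
  list(config = cfg, species = sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
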