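#' Extrapolate an energy density over a stand area
#'
#' @param energy_per_m2 kJ per square metre (>= 0).
#' @param area_ha Stand area in hectares (>= 0); hectares convert to square
#'   metres by exactly 10,000.
#' @return Total kJ, unrounded.
#' @export
#' @examples
#' total_energy(18.83, 91)
total_energy <- function(energy_per_m2, area_ha) {
  assert_non_negative(energy_per_m2, "energy_per_m2")
  assert_non_negative(area_ha, "area_ha")
  energy_per_m2 * area_ha * 10000
}

#' Forest-wide energy budget for one survey year
#'
#' Extrapolates per-species energy densities over stand areas. Available
#' energy is extrapolated over the full *mature* area of each species;
#' consumed energy over the area known to be *occupied* by squirrels, which
#' may differ per species and year. When an occupied area is unrecorded
#' (`NA`) it defaults to the mature area (the convention for surveys where
#' squirrel signs were observed in all surveyed stands).
#'
#' @param densities Energy-density rows for one year, as produced by
#'   [energy_density_table()] (columns `species`, `year`,
#'   `energy_per_m2_available_kJ`, `energy_per_m2_consumed_kJ`).
#' @param areas A tibble with columns `species`, `mature_ha` and optionally
#'   `occupied_ha`, one row per species present in `densities`.
#' @param year Survey year (integer); defaults to the single year present in
#'   `densities`.
#' @return An object of class `forest_energy`: a list with `year`,
#'   `per_species` (tibble of areas and energy totals), `mature_total_ha`,
#'   `forest_total_available_kJ`, `forest_total_consumed_kJ` and
#'   `percent_consumed`.
#' @export
forest_energy <- function(densities, areas, year = NULL) {
  d <- as_tibble(densities)
  a <- as_tibble(areas)
  if (is.null(year)) {
    yrs <- unique(d$year)
    if (length(yrs) != 1) {
      cc_abort("`densities` spans several years; pass `year` explicitly.",
               class = "conecap_validation_error")
    }
    year <- yrs
  } else if ("year" %in% names(d)) {
    d <- d[d$year == year, , drop = FALSE]
  }
  if ("year" %in% names(a)) a <- a[a$year == year, , drop = FALSE]
  missing <- setdiff(d$species, a$species)
  if (length(missing) > 0) {
    cc_abort(sprintf("No area entry for species: %s (year %s).",
                     paste(missing, collapse = ", "), year),
             class = "conecap_config_error")
  }
  if (!"occupied_ha" %in% names(a)) a$occupied_ha <- NA_real_
  per <- left_join(d, a[, c("species", "mature_ha", "occupied_ha")],
                   by = "species") %>%
    mutate(
      occupied_ha = ifelse(is.na(.data$occupied_ha), .data$mature_ha,
                           .data$occupied_ha),
      total_available_kJ = total_energy(.data$energy_per_m2_available_kJ,
                                        .data$mature_ha),
      total_consumed_kJ = total_energy(.data$energy_per_m2_consumed_kJ,
                                       .data$occupied_ha)
    )
  avail <- sum(per$total_available_kJ)
  cons <- sum(per$total_consumed_kJ)
  structure(
    list(year = as.integer(year),
         per_species = per,
         mature_total_ha = sum(per$mature_ha),
         forest_total_available_kJ = avail,
         forest_total_consumed_kJ = cons,
         percent_consumed = if (avail > 0) 100 * cons / avail else NA_real_),
    class = "forest_energy"
  )
}

#' @export
print.forest_energy <- function(x, ...) {
  cat(sprintf(
    "Forest energy budget, %d (%g ha mature)\n  available: %s kJ\n  consumed:  %s kJ (%.2f%% of available)\n",
    x$year, x$mature_total_ha,
    format(x$forest_total_available_kJ, big.mark = ","),
    format(x$forest_total_consumed_kJ, big.mark = ","),
    x$percent_consumed))
  invisible(x)
}

#' Squirrels sustainable on an energy supply
#'
#' Divides a total energy supply by one squirrel's requirement over the
#' horizon and rounds half away from zero. The *lower* population bound uses
#' the high daily requirement; the *upper* bound uses the low requirement.
#'
#' @param total_kJ Total energy available or consumed, kJ (>= 0).
#' @param daily_req_kJ Daily requirement of one squirrel, kJ/day (> 0).
#' @param horizon_days Days the crop must last (> 0), default 365.
#' @return Integer number of squirrels.
#' @export
#' @examples
#' squirrels_from_energy(20831600, 700) # lower capacity bound
#' squirrels_from_energy(20831600, 400) # upper capacity bound
squirrels_from_energy <- function(total_kJ, daily_req_kJ, horizon_days = 365) {
  assert_non_negative(total_kJ, "total_kJ")
  assert_positive(daily_req_kJ, "daily_req_kJ")
  assert_positive(horizon_days, "horizon_days")
  as.integer(round_half_up(total_kJ / (daily_req_kJ * horizon_days)))
}

#' Area-based carrying capacity
#'
#' A capacity estimate that ignores the cone crop entirely: mature forest
#' area times a per-hectare squirrel density observed in a comparable
#' conifer forest.
#'
#' @param mature_area_ha Mature conifer area, ha (>= 0).
#' @param density_per_ha Squirrels per hectare (>= 0), default 0.32.
#' @return Integer number of squirrels (rounded half away from zero).
#' @export
#' @examples
#' area_based_capacity(432, 0.32)
area_based_capacity <- function(mature_area_ha, density_per_ha = 0.32) {
  assert_non_negative(mature_area_ha, "mature_area_ha")
  assert_non_negative(density_per_ha, "density_per_ha")
  as.integer(round_half_up(mature_area_ha * density_per_ha))
}

#' Capacity and actual-population estimate for one year
#'
#' Converts a [forest_energy()] budget into the feeding-survey carrying
#' capacity interval (from available energy), the estimated actual
#' population interval (from consumed energy) and the area-based capacity.
#'
#' @param fe A `forest_energy` object.
#' @param cfg An [analysis_config()].
#' @return A one-row tibble: `year`, `mature_ha`, `area_capacity`,
#'   `fs_capacity_low`, `fs_capacity_high`, `fs_actual_low`,
#'   `fs_actual_high`.
#' @export
capacity_estimate <- function(fe, cfg = analysis_config()) {
  stopifnot(inherits(fe, "forest_energy"))
  h <- cfg$horizon_days
  tibble(
    year = fe$year,
    mature_ha = fe$mature_total_ha,
    area_capacity = area_based_capacity(fe$mature_total_ha,
                                        cfg$area_density_per_ha),
    fs_capacity_low = squirrels_from_energy(fe$forest_total_available_kJ,
                                            cfg$daily_requirement_high_kJ, h),
    fs_capacity_high = squirrels_from_energy(fe$forest_total_available_kJ,
                                             cfg$daily_requirement_low_kJ, h),
    fs_actual_low = squirrels_from_energy(fe$forest_total_consumed_kJ,
                                          cfg$daily_requirement_high_kJ, h),
    fs_actual_high = squirrels_from_energy(fe$forest_total_consumed_kJ,
                                           cfg$daily_requirement_low_kJ, h)
  )
}

#' Multi-year capacity table
#'
#' Runs [forest_energy()] and [capacity_estimate()] for every survey year
#' present in the density table.
#'
#' @param densities Energy-density rows spanning one or more years.
#' @param areas Per-species, per-year `mature_ha`/`occupied_ha` table.
#' @param cfg An [analysis_config()].
#' @return A tibble with one row per year (columns as [capacity_estimate()]).
#' @export
capacity_table <- function(densities, areas, cfg = analysis_config()) {
  yrs <- sort(unique(as_tibble(densities)$year))
  bind_rows(lapply(yrs, function(y) {
    capacity_estimate(forest_energy(densities, areas, year = y), cfg)
  }))
}
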