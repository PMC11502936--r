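#' Run the full feeding-survey analysis
#'
#' Orchestrates every stage: validates the inputs, derives per-cone energies
#' from the cone measurements (scale-length regression for Sitka spruce,
#' length allometry for lodgepole pine), pools transect counts into energy
#' densities, builds the multi-year area ledger, extrapolates energy over
#' mature/occupied areas, and derives per-year capacity estimates and
#' cross-year change metrics. Identical inputs and configuration produce
#' identical tables.
#'
#' Each of `transects`, `cones`, `stands` may be a file path (read with the
#' corresponding reader, and checksummed into the manifest) or an in-memory
#' data frame.
#'
#' @param transects Transect records (tibble or CSV path).
#' @param cones Cone measurements (tibble or CSV path).
#' @param stands Stand ledger (tibble or CSV path).
#' @param config Either an [analysis_config()], a list with `config` and
#'   `species` entries (as from [read_config()]), or `NULL` for defaults.
#' @param densities Optional pre-computed energy-density table (schema of
#'   [energy_density_table()] rows plus `year`). Needed when historical
#'   surveys are available only as published densities rather than raw
#'   counts; when supplied it is used for the extrapolation, and any
#'   disagreement with the count-derived densities for overlapping years is
#'   reported in the manifest notes.
#' @param areas Optional per-species, per-year `mature_ha`/`occupied_ha`
#'   table; derived from the stand ledger when `NULL`.
#' @param out_dir Optional output directory; when given, writes
#'   `area_ledger.csv`, `energy_density.csv`, `capacity.csv`, `changes.csv`
#'   and `manifest.json`.
#' @return A list with `area_ledger`, `energy_density`, `energy_totals`,
#'   `capacity`, `changes` and `manifest`.
#' @export
#' @examples
#' fx <- derryclare_fixture()
#' res <- run_pipeline(fx$transects, fx$cones, fx$stands, fx$config,
#'                     densities = fx$densities, areas = fx$areas)
#' res$capacity
run_pipeline <- function(transects, cones, stands, config = NULL,
                         densities = NULL, areas = NULL, out_dir = NULL) {
  checksums <- list()
  if (is.character(transects)) {
    checksums$transects <- unname(tools::md5sum(transects))
    transects <- read_transects(transects)
  } else {
    transects <- validate_transects(transects)
  }
  if (is.character(cones)) {
    checksums$cones <- unname(tools::md5sum(cones))
    cones <- read_cone_measurements(cones)
  } else {
    cones <- validate_cone_measurements(cones)
  }
  if (is.character(stands)) {
    checksums$stands <- unname(tools::md5sum(stands))
    stands <- read_stand_ledger(stands)
  } else {
    stands <- validate_stands(stands)
  }
  cs <- normalise_config(config)
  cfg <- cs$config
  sp <- cs$species

  unknown_stand <- setdiff(unique(transects$stand_id), unique(stands$stand_id))
  if (length(unknown_stand) > 0) {
    cc_abort(sprintf("Transects reference unknown stand(s): %s.",
                     paste(unknown_stand, collapse = ", ")),
             class = "conecap_join_error")
  }

  epc <- energy_per_cone_by_species(cones, sp, cfg)
  count_densities <- energy_density_table(transects, epc)

  notes <- character(0)
  if (is.null(densities)) {
    densities <- count_densities
  } else {
    densities <- as_tibble(densities)
    ov <- dplyr::inner_join(
      count_densities, densities,
      by = c("species", "year"), suffix = c("_counts", "_supplied"))
    if (nrow(ov) > 0) {
      delta <- abs(ov$cones_per_m2_available_counts -
                     ov$cones_per_m2_available_supplied)
      for (i in which(delta > 0.005)) {
        notes <- c(notes, sprintf(
          "%s %d: count-derived availability %.2f cones/m2 differs from supplied %.2f cones/m2.",
          ov$species[i], ov$year[i],
          ov$cones_per_m2_available_counts[i],
          ov$cones_per_m2_available_supplied[i]))
      }
    }
  }

  ledger <- build_area_ledger(stands, cfg)
  if (is.null(areas)) areas <- derive_areas(stands, cfg)

  capacity <- capacity_table(densities, areas, cfg)
  energy_totals <- bind_rows(lapply(sort(unique(densities$year)), function(y) {
    fe <- forest_energy(densities, areas, year = y)
    tibble(year = fe$year,
           mature_ha = fe$mature_total_ha,
           total_available_kJ = fe$forest_total_available_kJ,
           total_consumed_kJ = fe$forest_total_consumed_kJ,
           percent_consumed = fe$percent_consumed)
  }))
  changes <- summarize_changes(ledger, capacity, densities, energy_totals, cfg)

  manifest <- list(
    package = "conecap",
    version = as.character(utils::packageVersion("conecap")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(cfg),
    input_checksums = checksums,
    row_counts = list(transects = nrow(transects), cones = nrow(cones),
                      stands = nrow(stands), densities = nrow(densities),
                      capacity = nrow(capacity)),
    notes = notes
  )

  res <- list(area_ledger = ledger, energy_density = densities,
              energy_totals = energy_totals, capacity = capacity,
              changes = changes, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(ledger, file.path(out_dir, "area_ledger.csv"))
    write_report(densities, file.path(out_dir, "energy_density.csv"))
    write_report(capacity, file.path(out_dir, "capacity.csv"))
    write_report(changes, file.path(out_dir, "changes.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Cross-year change report
#'
#' Percent reductions between the first and last ledger years (mature
#' habitat, per-species coverage, area-based capacity) and between the first
#' and last survey years (forest energy, consumed energy, per-species cone
#' densities, and the cross-paired carrying-capacity decline range).
#'
#' @param ledger Area ledger ([build_area_ledger()]) spanning >= 2 years.
#' @param capacity Capacity table ([capacity_table()]).
#' @param densities Energy-density table spanning the survey years.
#' @param energy_totals Optional per-year forest energy totals (tibble with
#'   `year`, `total_available_kJ`, `total_consumed_kJ`).
#' @param cfg An [analysis_config()].
#' @return A tibble with columns `metric`, `value`, `from_year`, `to_year`.
#'   Values are unrounded; display with [round_half_up()].
#' @export
summarize_changes <- function(ledger, capacity, densities,
                              energy_totals = NULL, cfg = analysis_config()) {
  ledger <- as_tibble(ledger)
  if (length(unique(ledger$year)) < 2) {
    cc_abort("Need at least two ledger years to summarise change.",
             class = "conecap_validation_error")
  }
  first <- ledger[which.min(ledger$year), ][1, ]
  last <- ledger[which.max(ledger$year), ][1, ]
  rows <- list(
    tibble(metric = "mature_habitat_reduction_pct",
           value = percent_reduction(first$mature_conifer_ha,
                                     last$mature_conifer_ha),
           from_year = first$year, to_year = last$year),
    tibble(metric = "sitka_coverage_reduction_pct",
           value = percent_reduction(first$sitka_ha, last$sitka_ha),
           from_year = first$year, to_year = last$year),
    tibble(metric = "lodgepole_coverage_reduction_pct",
           value = percent_reduction(first$lodgepole_ha, last$lodgepole_ha),
           from_year = first$year, to_year = last$year),
    tibble(metric = "area_capacity_reduction_pct",
           value = percent_reduction(
             area_based_capacity(first$mature_conifer_ha,
                                 cfg$area_density_per_ha),
             area_based_capacity(last$mature_conifer_ha,
                                 cfg$area_density_per_ha)),
           from_year = first$year, to_year = last$year)
  )

  capacity <- as_tibble(capacity)
  if (nrow(capacity) >= 2) {
    cap_first <- capacity[which.min(capacity$year), ][1, ]
    cap_last <- capacity[which.max(capacity$year), ][1, ]
    dr <- decline_range(c(cap_first$fs_capacity_low, cap_first$fs_capacity_high),
                        c(cap_last$fs_capacity_low, cap_last$fs_capacity_high))
    rows <- c(rows, list(
      tibble(metric = c("fs_capacity_decline_min_pct",
                        "fs_capacity_decline_max_pct"),
             value = c(dr$min_percent, dr$max_percent),
             from_year = cap_first$year, to_year = cap_last$year)
    ))
  }

  densities <- as_tibble(densities)
  dy <- sort(unique(densities$year))
  if (length(dy) >= 2) {
    d1 <- densities[densities$year == dy[1], ]
    d2 <- densities[densities$year == dy[length(dy)], ]
    for (spp in intersect(d1$species, d2$species)) {
      b <- d1$cones_per_m2_available[d1$species == spp]
      a <- d2$cones_per_m2_available[d2$species == spp]
      if (b > 0) {
        rows <- c(rows, list(
          tibble(metric = paste0(spp, "_density_fold_change"),
                 value = fold_change(b, a),
                 from_year = dy[1], to_year = dy[length(dy)]),
          tibble(metric = paste0(spp, "_density_reduction_pct"),
                 value = percent_reduction(b, a),
                 from_year = dy[1], to_year = dy[length(dy)])
        ))
      }
    }
  }

  if (!is.null(energy_totals) && nrow(as_tibble(energy_totals)) >= 2) {
    et <- as_tibble(energy_totals)
    e1 <- et[which.min(et$year), ][1, ]
    e2 <- et[which.max(et$year), ][1, ]
    rows <- c(rows, list(
      tibble(metric = "forest_energy_reduction_pct",
             value = percent_reduction(e1$total_available_kJ,
                                       e2$total_available_kJ),
             from_year = e1$year, to_year = e2$year),
      tibble(metric = "consumed_energy_reduction_pct",
             value = percent_reduction(e1$total_consumed_kJ,
                                       e2$total_consumed_kJ),
             from_year = e1$year, to_year = e2$year)
    ))
  }
  bind_rows(rows)
}

#' Derive per-species mature and occupied areas from the stand ledger
#'
#' For each survey year, sums mature stand areas per conifer species, and
#' occupied areas over stands flagged as squirrel-occupied. A year in which
#' no stand carries an occupied flag is treated as having no occupancy
#' record (`occupied_ha = NA`), which downstream defaults to the mature
#' area. When a year holds several labelled snapshots (e.g. pre/post
#' disturbance), the first-listed snapshot is used.
#'
#' @param stands A validated stand ledger.
#' @param cfg An [analysis_config()].
#' @return A tibble: `year`, `species`, `mature_ha`, `occupied_ha`.
#' @export
derive_areas <- function(stands, cfg = analysis_config()) {
  df <- validate_stands(stands)
  out <- lapply(sort(unique(df$year)), function(y) {
    sub <- df[df$year == y, ]
    lbl <- sub$label[1]           # first-listed snapshot for this year
    sub <- sub[sub$label == lbl, ]
    cls <- classify_stands(sub, cfg)
    any_occ <- any(sub$occupied)
    bind_rows(lapply(CONIFER_SPECIES, function(spp) {
      m <- cls == "mature" & sub$species == spp
      tibble(year = y, species = spp,
             mature_ha = sum(sub$area_ha[m]),
             occupied_ha = if (any_occ) sum(sub$area_ha[m & sub$occupied])
                           else NA_real_)
    }))
  })
  bind_rows(out)
}

#' Per-species energy per cone from measurements
#'
#' Applies the species-appropriate seed estimate: the scale-length
#' regression's mean scale count for Sitka spruce, the length allometry for
#' lodgepole pine; multiplies by the species' seed energy.
#'
#' @param cones Validated cone measurements for the species present.
#' @param species_params Named list of `species_params`
#'   ([default_species_params()]).
#' @param cfg An [analysis_config()] (supplies `seeds_per_scale`).
#' @return Named numeric vector of kJ per cone by species.
#' @export
energy_per_cone_by_species <- function(cones,
                                       species_params = default_species_params(),
                                       cfg = analysis_config()) {
  cones <- validate_cone_measurements(cones)
  out <- numeric(0)
  for (spp in unique(cones$species)) {
    sub <- cones[cones$species == spp, ]
    pars <- species_params[[spp]]
    if (is.null(pars)) {
      cc_abort(sprintf("No species parameters for '%s'.", spp),
               class = "conecap_config_error")
    }
    seeds <- if (spp == "sitka_spruce") {
      fit <- fit_scale_length_regression(sub)
      seeds_per_cone(spp, fit, pars, seeds_per_scale = cfg$seeds_per_scale)
    } else {
      seeds_per_cone(spp, mean(sub$length_mm), pars)
    }
    out[spp] <- energy_per_cone(seeds, pars$seed_energy_kJ)
  }
  out
}

# internal: accept analysis_config, read_config()-style list, or NULL
normalise_config <- function(config) {
  if (is.null(config)) {
    list(config = analysis_config(), species = default_species_params())
  } else if (inherits(config, "analysis_config")) {
    list(config = config, species = default_species_params())
  } else if (is.list(config) && inherits(config$config, "analysis_config")) {
    list(config = config$config,
         species = config$species %||% default_species_params())
  } else {
    cc_abort("`config` must be an analysis_config or a read_config() list.",
             class = "conecap_config_error")
  }
}
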