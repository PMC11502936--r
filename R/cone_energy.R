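#' Fit the scale-count on cone-length regression
#'
#' Ordinary least-squares fit of the number of scales per cone (one seed per
#' scale by default) on cone length, used to characterise the Sitka spruce
#' seed content of an average cone. Alongside the line, the fit carries the
#' sample mean scale count and its standard error, which is what the energy
#' calculation actually consumes.
#'
#' @param measurements Cone measurements (tibble or data frame) with columns
#'   `length_mm` and `scale_count`; rows with missing scale counts are
#'   dropped. At least 3 usable rows are required.
#' @return An object of class `scale_length_fit`: a list with `slope`
#'   (seeds/mm), `intercept` (seeds), `r`, `r_squared`, `n`, `mean_seeds`
#'   and `se_mean_seeds`.
#' @export
fit_scale_length_regression <- function(measurements) {
  df <- as_tibble(measurements)
  df <- df[is.finite(df$length_mm) & !is.na(df$scale_count), ]
  if (nrow(df) < 3) {
    cc_abort("Need at least 3 cones with both length and scale count.",
             class = "conecap_validation_error")
  }
  if (length(unique(df$length_mm)) < 2) {
    cc_abort("All cone lengths are identical; the regression is degenerate.",
             class = "conecap_degenerate_fit")
  }
  fit <- lm(scale_count ~ length_mm, data = df)
  r <- stats::cor(df$length_mm, df$scale_count)
  structure(
    list(slope = unname(coef(fit)[["length_mm"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r = r,
         r_squared = r^2,
         n = nrow(df),
         mean_seeds = mean(df$scale_count),
         se_mean_seeds = stats::sd(df$scale_count) / sqrt(nrow(df))),
    class = "scale_length_fit"
  )
}

#' @export
print.scale_length_fit <- function(x, ...) {
  cat(sprintf(
    "Scale-length regression (n = %d)\n  seeds = %.3f + %.3f * length_mm\n  r = %.3f, R^2 = %.3f\n  mean seeds per cone: %.1f (SE %.2f)\n",
    x$n, x$intercept, x$slope, x$r, x$r_squared, x$mean_seeds, x$se_mean_seeds))
  invisible(x)
}

#' Seeds in an average cone
#'
#' For Sitka spruce the seed count comes directly from counted scales (the
#' mean scale count of a [fit_scale_length_regression()] fit, or a raw
#' vector of scale counts), scaled by the seeds-per-scale factor. For
#' lodgepole pine, where scale counting is unreliable, the species'
#' allometric function is applied to the mean cone length.
#'
#' @param species `"sitka_spruce"` or `"lodgepole_pine"`.
#' @param summary For Sitka spruce: a `scale_length_fit` or a numeric vector
#'   of scale counts. For lodgepole pine: the mean cone length in mm.
#' @param params A `species_params` for this species (see
#'   [default_species_params()]); required for lodgepole pine.
#' @param seeds_per_scale Seeds per scale (default 1).
#' @return Seeds per average cone (positive real).
#' @export
#' @examples
#' sp <- default_species_params()
#' seeds_per_cone("lodgepole_pine", 42.8, sp$lodgepole_pine)
seeds_per_cone <- function(species, summary, params = NULL, seeds_per_scale = 1) {
  assert_species(species)
  assert_positive(seeds_per_scale, "seeds_per_scale")
  if (species == "sitka_spruce") {
    seeds <- if (inherits(summary, "scale_length_fit")) {
      summary$mean_seeds
    } else {
      if (!is.numeric(summary) || length(summary) < 1) {
        cc_abort("Sitka spruce needs a scale-length fit or scale counts.",
                 class = "conecap_config_error")
      }
      mean(summary)
    }
    seeds <- seeds * seeds_per_scale
  } else {
    if (is.null(params) || is.null(params$allometric)) {
      cc_abort("Lodgepole pine needs allometric coefficients in `params`.",
               class = "conecap_config_error")
    }
    if (!is.numeric(summary) || length(summary) != 1) {
      cc_abort("Lodgepole pine needs a single mean cone length (mm).",
               class = "conecap_validation_error")
    }
    assert_positive(summary, "mean cone length")
    al <- params$allometric
    seeds <- al$slope * summary + al$intercept
  }
  assert_positive(seeds, "seeds per cone")
  seeds
}

#' Energy content of an average cone
#'
#' @param seeds Seeds per cone (> 0).
#' @param seed_energy_kJ Energy of one seed, kJ (> 0).
#' @return kJ per cone, unrounded.
#' @export
#' @examples
#' energy_per_cone(117, 0.04)
energy_per_cone <- function(seeds, seed_energy_kJ) {
  assert_positive(seeds, "seeds")
  assert_positive(seed_energy_kJ, "seed_energy_kJ")
  seeds * seed_energy_kJ
}

#' Pooled cone density over transects
#'
#' Total cones divided by total surveyed area: the pooling is count-sum over
#' area-sum, i.e. the area-weighted mean of per-transect densities, not the
#' unweighted mean.
#'
#' @param records Transect records for one species (and typically one year).
#' @param which `"available"` (all cones) or `"consumed"`.
#' @return Cones per square metre, at full precision.
#' @export
density_per_m2 <- function(records, which = c("available", "consumed")) {
  which <- match.arg(which)
  df <- as_tibble(records)
  if (nrow(df) == 0) {
    cc_abort("No transect records supplied.", class = "conecap_validation_error")
  }
  area <- sum(df$length_m * df$width_m)
  if (!(area > 0)) {
    cc_abort("Total surveyed area must be positive.", class = "conecap_domain_error")
  }
  counts <- if (which == "available") df$cones_total else df$cones_consumed
  sum(counts) / area
}

#' Energy density per square metre
#'
#' @param density Cones per m2 (>= 0).
#' @param energy_per_cone kJ per cone (>= 0).
#' @return kJ per m2, unrounded.
#' @export
energy_density <- function(density, energy_per_cone) {
  assert_non_negative(density, "density")
  assert_non_negative(energy_per_cone, "energy_per_cone")
  density * energy_per_cone
}

#' Per-species, per-year energy density table
#'
#' Pools transect counts by species and year and converts them to available
#' and consumed cone and energy densities using the supplied per-cone
#' energies.
#'
#' @param transects Validated transect records.
#' @param energy_per_cone_kJ Named numeric vector of kJ per cone, by species.
#' @return A tibble with one row per (species, year): `cones_per_m2_available`,
#'   `cones_per_m2_consumed`, `energy_per_m2_available_kJ`,
#'   `energy_per_m2_consumed_kJ`.
#' @export
energy_density_table <- function(transects, energy_per_cone_kJ) {
  df <- validate_transects(transects)
  missing <- setdiff(unique(df$species), names(energy_per_cone_kJ))
  if (length(missing) > 0) {
    cc_abort(sprintf("No per-cone energy supplied for: %s.",
                     paste(missing, collapse = ", ")),
             class = "conecap_config_error")
  }
  df %>%
    group_by(.data$species, .data$year) %>%
    summarise(
      cones_per_m2_available = sum(.data$cones_total) /
        sum(.data$length_m * .data$width_m),
      cones_per_m2_consumed = sum(.data$cones_consumed) /
        sum(.data$length_m * .data$width_m),
      .groups = "drop"
    ) %>%
    mutate(
      energy_per_m2_available_kJ = .data$cones_per_m2_available *
        unname(energy_per_cone_kJ[.data$species]),
      energy_per_m2_consumed_kJ = .data$cones_per_m2_consumed *
        unname(energy_per_cone_kJ[.data$species])
    ) %>%
    arrange(.data$year, .data$species)
}
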