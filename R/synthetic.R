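#' Define a synthetic feeding-survey design
#'
#' Describes the ground truth for a simulated cone survey: transect layout,
#' per-species true cone densities, consumed fractions and cone-morphology
#' parameters (length distribution and the linear scales-on-length
#' relationship). Per-transect counts are drawn negative-binomially by
#' default, since cone counts on 50 m2 strips under masting are
#' overdispersed relative to Poisson; set `dispersion = "poisson"` for
#' equidispersed counts.
#'
#' Default parameter values emulate the 2021 Derryclare survey: 33 transects
#' of 50 m x 1 m, Sitka spruce density 4.02 cones/m2 (mean length 48.1 mm),
#' lodgepole pine density 0.63 cones/m2 (mean length 42.8 mm), with
#' consumed fractions matching the consumed/available density ratios.
#'
#' @param year Survey year.
#' @param n_transects Number of transects (>= 1).
#' @param transect_length_m,width_m Transect dimensions in metres.
#' @param species A tibble with one row per species: `species`,
#'   `true_density_per_m2`, `consumed_fraction`, `length_mean_mm`,
#'   `length_sd_mm`, `scales_per_mm_slope`, `scales_intercept`,
#'   `scale_noise_sd`.
#' @param dispersion `"negative_binomial"` (default) or `"poisson"`.
#' @param overdispersion Negative-binomial size parameter (default 1.5;
#'   smaller is more overdispersed). Ignored for Poisson.
#' @param rng_seed Integer root seed; all draws flow from it.
#' @return A list of class `survey_design`.
#' @export
survey_design <- function(year = 2021,
                          n_transects = 33,
                          transect_length_m = 50,
                          width_m = 1,
                          species = default_design_species(),
                          dispersion = c("negative_binomial", "poisson"),
                          overdispersion = 1.5,
                          rng_seed = 1L) {
  dispersion <- match.arg(dispersion)
  if (n_transects < 1) {
    cc_abort("`n_transects` must be >= 1.", class = "conecap_config_error")
  }
  assert_positive(transect_length_m, "transect_length_m")
  assert_positive(width_m, "width_m")
  if (dispersion == "negative_binomial") {
    assert_positive(overdispersion, "overdispersion")
  }
  sp <- as_tibble(species)
  assert_species(sp$species)
  assert_non_negative(sp$true_density_per_m2, "true_density_per_m2")
  if (any(sp$consumed_fraction < 0 | sp$consumed_fraction > 1)) {
    cc_abort("`consumed_fraction` must lie in [0, 1].",
             class = "conecap_config_error")
  }
  assert_positive(sp$length_sd_mm, "length_sd_mm")
  structure(
    list(year = as.integer(year),
         n_transects = as.integer(n_transects),
         transect_length_m = transect_length_m,
         width_m = width_m,
         species = sp,
         dispersion = dispersion,
         overdispersion = overdispersion,
         rng_seed = as.integer(rng_seed)),
    class = "survey_design"
  )
}

#' @rdname survey_design
#' @export
default_design_species <- function() {
  tibble(
    species = c("sitka_spruce", "lodgepole_pine"),
    true_density_per_m2 = c(4.02, 0.63),
    consumed_fraction = c(0.08 / 4.02, 0.04 / 0.63),
    length_mean_mm = c(48.1, 42.8),
    length_sd_mm = c(8.2, 7.1),
    scales_per_mm_slope = c(2.4, NA_real_),
    scales_intercept = c(1.6, NA_real_),
    scale_noise_sd = c(13, NA_real_)
  )
}

#' Generate synthetic transect records
#'
#' Draws per-transect available cone counts with mean `density x area` from
#' the design's count distribution, then consumed counts binomially from the
#' available count with the species' consumed fraction. The draw order is
#' fixed (species in design row order; for each species all available
#' counts, then all consumed counts) so a given `rng_seed` reproduces the
#' same table on any platform.
#'
#' @param design A [survey_design()].
#' @return A tibble of transect records (same schema as [read_transects()]).
#' @export
generate_transects <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  set.seed(design$rng_seed)
  area <- design$transect_length_m * design$width_m
  nt <- design$n_transects
  out <- lapply(seq_len(nrow(design$species)), function(i) {
    row <- design$species[i, ]
    mu <- row$true_density_per_m2 * area
    avail <- if (mu == 0) {
      rep(0L, nt)
    } else if (design$dispersion == "poisson") {
      stats::rpois(nt, lambda = mu)
    } else {
      rnbinom(nt, mu = mu, size = design$overdispersion)
    }
    consumed <- rbinom(nt, size = avail, prob = row$consumed_fraction)
    tibble(
      transect_id = sprintf("T%02d", seq_len(nt)),
      year = design$year,
      stand_id = sprintf("SYN-%s", toupper(substr(row$species, 1, 2))),
      species = row$species,
      cones_total = as.numeric(avail),
      cones_consumed = as.numeric(consumed),
      length_m = design$transect_length_m,
      width_m = design$width_m
    )
  })
  validate_transects(bind_rows(out))
}

#' Generate synthetic cone measurements
#'
#' Cone lengths are Gaussian (mean/sd from the design), truncated positive
#' by redrawing; scale counts follow the design's linear scales-on-length
#' relationship with Gaussian noise, rounded to integer and floored at 0.
#' Species without scale parameters get `NA` scale counts (the scale-count
#' method is unreliable for lodgepole pine).
#'
#' @param design A [survey_design()].
#' @param n Number of cones to generate (>= 1).
#' @param species Which species to draw (default first in the design).
#' @return A tibble of cone measurements (schema of
#'   [read_cone_measurements()]).
#' @export
generate_cone_measurements <- function(design, n, species = NULL) {
  stopifnot(inherits(design, "survey_design"))
  if (n < 1) cc_abort("`n` must be >= 1.", class = "conecap_config_error")
  species <- species %||% design$species$species[1]
  row <- design$species[design$species$species == species, ]
  if (nrow(row) != 1) {
    cc_abort(sprintf("Species '%s' is not in the design.", species),
             class = "conecap_config_error")
  }
  set.seed(design$rng_seed + 1L)
  lengths <- rnorm(n, row$length_mean_mm, row$length_sd_mm)
  while (any(lengths <= 5)) {
    lengths[lengths <= 5] <- rnorm(sum(lengths <= 5), row$length_mean_mm,
                                   row$length_sd_mm)
  }
  scales <- if (is.na(row$scales_per_mm_slope)) {
    rep(NA_real_, n)
  } else {
    pmax(0, round(row$scales_per_mm_slope * lengths + row$scales_intercept +
                    rnorm(n, 0, row$scale_noise_sd)))
  }
  validate_cone_measurements(tibble(
    species = species,
    length_mm = lengths,
    scale_count = scales,
    consumed = rbinom(n, 1, row$consumed_fraction) == 1
  ))
}

#' The packaged Derryclare survey fixture
#'
#' A fully deterministic encoding of the published Derryclare feeding-survey
#' data: the 2021 transect counts (5599 Sitka spruce cones, 136 consumed;
#' 1032 lodgepole pine cones, 63 consumed; 33 transects of 50 m x 1 m),
#' synthetic-but-anchored cone measurements (351 Sitka lengths with mean
#' 48.1 mm, 110 of them with scale counts averaging exactly 117; 179
#' lodgepole lengths with mean 42.8 mm), the multi-year stand ledger
#' (2005-2021 composition, including pre- and post-fire 2011 snapshots),
#' the published per-m2 cone/energy densities for every survey year
#' 2008-2021 and the mature/occupied areas they extrapolate over.
#'
#' The cone length and scale values are deterministic constructions (not
#' field measurements): symmetric deviations around the published means, so
#' the sample means reproduce the published summaries exactly while
#' individual cones are synthetic. The `densities` table carries the
#' published per-m2 values directly because the raw 2008-2011 transect
#' records are not part of this package; note that the published 2021 Sitka
#' availability (4.02 cones/m2) is not the pooled count density
#' (5599/1650 = 3.39), and the pipeline reports that discrepancy rather
#' than hiding it.
#'
#' @return A list with elements `transects`, `cones`, `stands`, `config`
#'   (a list with `config` and `species` as from [read_config()]),
#'   `densities` and `areas`. No randomness is involved.
#' @export
#' @examples
#' fx <- derryclare_fixture()
#' sum(fx$transects$cones_total[fx$transects$species == "sitka_spruce"])
derryclare_fixture <- function() {
  nt <- 33

  # split a total over transects deterministically, largest remainders first
  split_total <- function(total, n) {
    base <- total %/% n
    extra <- total %% n
    base + c(rep(1, extra), rep(0, n - extra))
  }
  transects <- bind_rows(
    tibble(transect_id = sprintf("T%02d", 1:nt), year = 2021L,
           stand_id = "DC-SS", species = "sitka_spruce",
           cones_total = split_total(5599, nt),
           cones_consumed = split_total(136, nt),
           length_m = 50, width_m = 1),
    tibble(transect_id = sprintf("T%02d", 1:nt), year = 2021L,
           stand_id = "DC-LP", species = "lodgepole_pine",
           cones_total = split_total(1032, nt),
           cones_consumed = split_total(63, nt),
           length_m = 50, width_m = 1)
  )
  transects <- validate_transects(transects)

  # symmetric integer-scaled deviations: the sample mean is the anchor exactly
  sym_dev <- function(n_half, step) c(-(n_half:1), 0, 1:n_half) * step

  sitka_len <- 48.1 + sym_dev(175, 0.09)            # 351 cones, mean 48.1
  lp_len <- 42.8 + sym_dev(89, 0.2)                 # 179 cones, mean 42.8

  # scale counts for a 110-cone subset: linear in length plus a fixed
  # mean-zero wiggle, then adjusted so the mean is exactly 117
  sub_idx <- round(seq(1, 351, length.out = 110))
  sub_len <- sitka_len[sub_idx]
  wiggle <- rep(c(-9, 3, 6, -12, 9, 0, 12, -3, -6, 0), 11)
  scales <- round(2.4 * (sub_len - 48.1)) + 117 + wiggle
  d <- 110 * 117 - sum(scales)
  scales <- scales + d %/% 110
  rem <- d %% 110
  if (rem > 0) scales[seq_len(rem)] <- scales[seq_len(rem)] + 1

  sitka_scales <- rep(NA_real_, 351)
  sitka_scales[sub_idx] <- scales
  cones <- bind_rows(
    tibble(species = "sitka_spruce", length_mm = sitka_len,
           scale_count = sitka_scales,
           consumed = rep(c(TRUE, FALSE), c(136, 215))),
    tibble(species = "lodgepole_pine", length_mm = lp_len,
           scale_count = NA_real_, consumed = FALSE)
  )
  cones <- validate_cone_measurements(cones)

  stand <- function(year, label, id, species, status, area, occ = FALSE,
                    planting = NA_integer_) {
    tibble(stand_id = id, year = as.integer(year), species = species,
           planting_year = planting, status = status, area_ha = area,
           occupied = occ, label = label)
  }
  py <- 1965L  # plantation era; all surveyed conifer stands are mature
  stands <- bind_rows(
    # 2005 (establishment)
    stand(2005, "", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2005, "", "SS", "sitka_spruce", "mature", 156, planting = py),
    stand(2005, "", "LP", "lodgepole_pine", "mature", 276, planting = py),
    stand(2005, "", "UNS", "other", "bare_or_felled", 138),
    # 2008
    stand(2008, "", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2008, "", "SS", "sitka_spruce", "mature", 123, planting = py),
    stand(2008, "", "LP-OCC", "lodgepole_pine", "mature", 74, TRUE, py),
    stand(2008, "", "LP-REST", "lodgepole_pine", "mature", 195, planting = py),
    stand(2008, "", "UNS", "other", "bare_or_felled", 178),
    # 2009
    stand(2009, "", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2009, "", "SS", "sitka_spruce", "mature", 108, planting = py),
    stand(2009, "", "LP-OCC", "lodgepole_pine", "mature", 104, TRUE, py),
    stand(2009, "", "LP-REST", "lodgepole_pine", "mature", 142, planting = py),
    stand(2009, "", "UNS", "other", "bare_or_felled", 216),
    # 2010
    stand(2010, "", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2010, "", "SS-OCC", "sitka_spruce", "mature", 36, TRUE, py),
    stand(2010, "", "SS-REST", "sitka_spruce", "mature", 71, planting = py),
    stand(2010, "", "LP-OCC", "lodgepole_pine", "mature", 119, TRUE, py),
    stand(2010, "", "LP-REST", "lodgepole_pine", "mature", 107, planting = py),
    stand(2010, "", "UNS", "other", "bare_or_felled", 237),
    # 2011 pre fire (the 2011 survey areas)
    stand(2011, "pre_fire", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2011, "pre_fire", "SS-OCC", "sitka_spruce", "mature", 64, TRUE, py),
    stand(2011, "pre_fire", "SS-REST", "sitka_spruce", "mature", 29, planting = py),
    stand(2011, "pre_fire", "LP-OCC", "lodgepole_pine", "mature", 126, TRUE, py),
    stand(2011, "pre_fire", "LP-REST", "lodgepole_pine", "mature", 94, planting = py),
    stand(2011, "pre_fire", "UNS", "other", "bare_or_felled", 257),
    # 2011 post fire (58 ha of lodgepole burned)
    stand(2011, "post_fire", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2011, "post_fire", "SS", "sitka_spruce", "mature", 93, planting = py),
    stand(2011, "post_fire", "LP", "lodgepole_pine", "mature", 162, planting = py),
    stand(2011, "post_fire", "BURN", "lodgepole_pine", "burned", 58, planting = py),
    stand(2011, "post_fire", "UNS", "other", "bare_or_felled", 257),
    # 2021 (regulation; signs observed in all surveyed stands)
    stand(2021, "", "NR", "broadleaf", "broadleaf_reserve", 13),
    stand(2021, "", "DC-SS", "sitka_spruce", "mature", 91, TRUE, py),
    stand(2021, "", "DC-LP", "lodgepole_pine", "mature", 111, TRUE, py),
    stand(2021, "", "UNS", "other", "bare_or_felled", 368)
  )
  stands <- validate_stands(stands)

  # published per-m2 cone and energy densities, every survey year
  densities <- tibble(
    year = rep(c(2008L, 2009L, 2010L, 2011L, 2021L), each = 2),
    species = rep(c("sitka_spruce", "lodgepole_pine"), 5),
    cones_per_m2_available = c(0.48, 3.7, 0.02, 3.37, 5.3, 1.42,
                               2.12, 1.35, 4.02, 0.63),
    energy_per_m2_available_kJ = c(2.25, 21.84, 0.09, 19.89, 24.84, 8.38,
                                   9.93, 7.97, 18.83, 3.33),
    cones_per_m2_consumed = c(0, 0.53, 0, 0.71, 0.3, 0.2,
                              0.14, 0.37, 0.08, 0.04),
    energy_per_m2_consumed_kJ = c(0, 3.13, 0, 4.19, 1.41, 1.18,
                                  0.66, 2.18, 0.37, 0.21)
  )

  areas <- tibble(
    year = rep(c(2008L, 2009L, 2010L, 2011L, 2021L), each = 2),
    species = rep(c("sitka_spruce", "lodgepole_pine"), 5),
    mature_ha = c(123, 269, 108, 246, 107, 226, 93, 220, 91, 111),
    occupied_ha = c(0, 74, 0, 104, 36, 119, 64, 126, 91, 111)
  )

  list(
    transects = transects,
    cones = cones,
    stands = stands,
    config = list(config = analysis_config(), species = default_species_params()),
    densities = densities,
    areas = areas
  )
}
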