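fx <- derryclare_fixture()
sp <- default_species_params()

test_that("scale-length regression recovers a perfect line and rejects degenerate input", {
  perfect <- tibble::tibble(length_mm = seq(20, 80, by = 5),
                            scale_count = 2 * seq(20, 80, by = 5))
  fit <- fit_scale_length_regression(perfect)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-9)

  flat <- tibble::tibble(length_mm = rep(50, 10), scale_count = 90 + 1:10)
  expect_error(fit_scale_length_regression(flat), class = "conecap_degenerate_fit")
  expect_error(fit_scale_length_regression(perfect[1:2, ]),
               class = "conecap_validation_error")
})

test_that("regression coefficients match the normal-equations oracle", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(10:200, 1)
    x <- runif(n, 20, 90)
    y <- 1.5 * x + rnorm(n, 0, 10)
    fit <- fit_scale_length_regression(tibble::tibble(length_mm = x, scale_count = y))
    oracle <- ols_normal_equations(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
  }
})

test_that("regression recovers a known slope within 3 SE on a synthetic sample", {
  set.seed(42)
  n <- 110
  b <- 2.4
  x <- rnorm(n, 48, 8)
  y <- b * x + 2 + rnorm(n, 0, 13)
  fit <- fit_scale_length_regression(tibble::tibble(length_mm = x, scale_count = y))
  se_slope <- 13 / (stats::sd(x) * sqrt(n))
  expect_lt(abs(fit$slope - b), 3 * se_slope)
})

test_that("seeds per cone follows the species-appropriate route", {
  sitka <- fx$cones[fx$cones$species == "sitka_spruce", ]
  fit <- fit_scale_length_regression(sitka)
  expect_equal(fit$mean_seeds, 117)
  expect_equal(seeds_per_cone("sitka_spruce", fit, sp$sitka_spruce), 117)
  expect_equal(seeds_per_cone("sitka_spruce", c(110, 117, 124)), 117)

  expect_equal(seeds_per_cone("lodgepole_pine", 42.8, sp$lodgepole_pine), 54,
               tolerance = 1e-9)
  expect_error(seeds_per_cone("lodgepole_pine", 0, sp$lodgepole_pine),
               class = "conecap_domain_error")
  expect_error(seeds_per_cone("lodgepole_pine", 42.8,
                              species_params("lodgepole_pine", 0.098)),
               class = "conecap_config_error")
})

test_that("cone energy is the unrounded seeds-times-seed-energy product", {
  expect_equal(energy_per_cone(117, 0.04), 4.68)
  expect_equal(energy_per_cone(54, 0.098), 5.292)
  expect_equal(energy_per_cone(1, 1), 1)
  expect_error(energy_per_cone(0, 0.04), class = "conecap_domain_error")
  expect_error(energy_per_cone(117, -1), class = "conecap_domain_error")
})

test_that("pooled densities are count-sum over area-sum at survey scale", {
  lp <- fx$transects[fx$transects$species == "lodgepole_pine", ]
  ss <- fx$transects[fx$transects$species == "sitka_spruce", ]
  expect_equal(round_half_up(density_per_m2(lp, "available"), 2), 0.63)
  expect_equal(density_per_m2(lp, "available"), 1032 / 1650)
  expect_equal(round_half_up(density_per_m2(ss, "consumed"), 2), 0.08)
  zero <- lp
  zero$cones_total <- 0
  zero$cones_consumed <- 0
  expect_equal(density_per_m2(zero, "available"), 0)
  expect_error(density_per_m2(lp[0, ]), class = "conecap_validation_error")
})

test_that("pooled density over a partition equals the area-weighted mean of parts", {
  set.seed(7)
  recs <- generate_transects(survey_design(rng_seed = 7))
  recs <- recs[recs$species == "sitka_spruce", ]
  split_at <- 12
  a <- recs[1:split_at, ]
  b <- recs[-(1:split_at), ]
  area <- function(d) sum(d$length_m * d$width_m)
  weighted <- (density_per_m2(a) * area(a) + density_per_m2(b) * area(b)) /
    (area(a) + area(b))
  expect_equal(density_per_m2(recs), weighted, tolerance = 1e-12)
})

test_that("energy density is bilinear and commutative in its factors", {
  expect_equal(round_half_up(energy_density(4.02, 4.684), 2), 18.83)
  expect_equal(energy_density(0, 123), 0)
  expect_equal(energy_density(2 * 3.1, 5.2), 2 * energy_density(3.1, 5.2))
  expect_equal(energy_density(3.1, 5.2), energy_density(5.2, 3.1))
  expect_error(energy_density(-1, 2), class = "conecap_domain_error")
})

test_that("the energy density table pools by species and year", {
  epc <- c(sitka_spruce = 4.68, lodgepole_pine = 5.292)
  tab <- energy_density_table(fx$transects, epc)
  expect_equal(nrow(tab), 2)
  ss <- tab[tab$species == "sitka_spruce", ]
  expect_equal(ss$cones_per_m2_available, 5599 / 1650)
  expect_equal(ss$energy_per_m2_available_kJ, 5599 / 1650 * 4.68)
  expect_true(all(tab$cones_per_m2_consumed <= tab$cones_per_m2_available))
})
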