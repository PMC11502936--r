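fx <- derryclare_fixture()
cfg <- analysis_config()

test_that("hectare extrapolation converts by exactly 10,000 m2/ha", {
  expect_equal(total_energy(18.83, 91), 17135300)
  expect_equal(total_energy(2.25, 123), 2767500)
  expect_equal(total_energy(0, 500), 0)
  expect_error(total_energy(-1, 10), class = "conecap_domain_error")
})

test_that("forest energy sums species totals over mature and occupied areas", {
  fe08 <- forest_energy(fx$densities, fx$areas, year = 2008)
  expect_equal(fe08$forest_total_available_kJ, 61517100)
  fe11 <- forest_energy(fx$densities, fx$areas, year = 2011)
  expect_equal(fe11$forest_total_available_kJ, 26768900)
  expect_equal(fe11$mature_total_ha, 313)

  zero <- fx$densities
  zero[, 3:6] <- 0
  fe0 <- forest_energy(zero, fx$areas, year = 2021)
  expect_equal(fe0$forest_total_available_kJ, 0)
  expect_equal(fe0$forest_total_consumed_kJ, 0)

  expect_error(forest_energy(fx$densities,
                             fx$areas[fx$areas$species != "sitka_spruce", ],
                             year = 2021),
               class = "conecap_config_error")
})

test_that("unrecorded occupied area defaults to the mature area", {
  a <- fx$areas[fx$areas$year == 2021, ]
  a$occupied_ha <- NA_real_
  fe <- forest_energy(fx$densities, a, year = 2021)
  expect_equal(fe$per_species$occupied_ha, fe$per_species$mature_ha)
  expect_equal(fe$forest_total_consumed_kJ,
               forest_energy(fx$densities, fx$areas, year = 2021)$forest_total_consumed_kJ)
})

test_that("energy-to-squirrel conversion rounds half away from zero over the horizon", {
  expect_equal(squirrels_from_energy(20831600, 400, 365), 143L)
  expect_equal(squirrels_from_energy(20831600, 700, 365), 82L)
  expect_equal(squirrels_from_energy(0, 400, 365), 0L)
  expect_error(squirrels_from_energy(100, 0, 365), class = "conecap_domain_error")
})

test_that("squirrel counts are monotone in energy, requirement and horizon", {
  es <- seq(0, 5e7, length.out = 20)
  got <- vapply(es, squirrels_from_energy, integer(1), daily_req_kJ = 500,
                horizon_days = 365)
  expect_true(all(diff(got) >= 0))
  reqs <- seq(100, 900, by = 50)
  got <- vapply(reqs, function(r) squirrels_from_energy(3e7, r, 365), integer(1))
  expect_true(all(diff(got) <= 0))
  hs <- seq(30, 730, by = 50)
  got <- vapply(hs, function(h) squirrels_from_energy(3e7, 500, h), integer(1))
  expect_true(all(diff(got) <= 0))
})

test_that("per-year capacity estimates combine available, consumed and area routes", {
  est08 <- capacity_estimate(forest_energy(fx$densities, fx$areas, 2008), cfg)
  expect_equal(est08$fs_capacity_low, 241L)
  expect_equal(est08$fs_capacity_high, 421L)
  expect_equal(est08$fs_actual_low, 9L)
  expect_equal(est08$fs_actual_high, 16L)
  expect_equal(est08$area_capacity, 125L)

  est10 <- capacity_estimate(forest_energy(fx$densities, fx$areas, 2010), cfg)
  expect_equal(c(est10$fs_capacity_low, est10$fs_capacity_high), c(178L, 312L))

  zero <- fx$densities
  zero[, 3:6] <- 0
  est0 <- capacity_estimate(forest_energy(zero, fx$areas, 2021), cfg)
  expect_equal(unlist(est0[, c("fs_capacity_low", "fs_capacity_high",
                               "fs_actual_low", "fs_actual_high")]),
               c(fs_capacity_low = 0L, fs_capacity_high = 0L,
                 fs_actual_low = 0L, fs_actual_high = 0L))
  expect_equal(est0$area_capacity, 65L)
})

test_that("capacity lower bound never exceeds upper bound", {
  cap <- capacity_table(fx$densities, fx$areas, cfg)
  expect_true(all(cap$fs_capacity_low <= cap$fs_capacity_high))
  expect_true(all(cap$fs_actual_low <= cap$fs_actual_high))
  expect_true(all(unlist(cap[, -1]) >= 0))
})

test_that("area-based capacity reproduces the per-hectare density estimates", {
  mature <- c(432, 392, 354, 333, 313, 255, 202)
  expect_equal(vapply(mature, area_based_capacity, integer(1),
                      density_per_ha = 0.32),
               c(138L, 125L, 113L, 107L, 100L, 82L, 65L))
  expect_equal(area_based_capacity(0, 0.32), 0L)
  expect_error(area_based_capacity(-5, 0.32), class = "conecap_domain_error")
})

test_that("scaling all densities by k scales all energy totals by k", {
  k <- 2.5
  scaled <- fx$densities
  scaled[, 3:6] <- scaled[, 3:6] * k
  for (y in unique(fx$densities$year)) {
    base <- forest_energy(fx$densities, fx$areas, y)
    up <- forest_energy(scaled, fx$areas, y)
    expect_equal(up$forest_total_available_kJ,
                 k * base$forest_total_available_kJ, tolerance = 1e-12)
    expect_equal(up$forest_total_consumed_kJ,
                 k * base$forest_total_consumed_kJ, tolerance = 1e-12)
  }
})
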