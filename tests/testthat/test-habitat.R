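fx <- derryclare_fixture()
cfg <- analysis_config()

test_that("stand classification applies the inclusive maturity threshold", {
  base <- list(species = "sitka_spruce", status = "mature", year = 2005,
               planting_year = 1965)
  expect_equal(classify_stand(base, cfg), "mature")
  at25 <- modifyList(base, list(planting_year = 1980))   # age exactly 25
  expect_equal(classify_stand(at25, cfg), "mature")
  at24 <- modifyList(base, list(planting_year = 1981))   # age 24
  expect_equal(classify_stand(at24, cfg), "immature")
  burned <- modifyList(base, list(status = "burned"))
  expect_equal(classify_stand(burned, cfg), "unsuitable")
  lost <- list(species = "lodgepole_pine", status = "bare_or_felled",
               year = 2011, planting_year = NA_integer_)
  expect_equal(classify_stand(lost, cfg), "unsuitable")
  orphan <- list(species = "lodgepole_pine", status = "broadleaf_reserve",
                 year = 2011, planting_year = NA_integer_)
  expect_equal(classify_stand(orphan, cfg), "broadleaf")
  unknown <- list(species = "lodgepole_pine", status = "burned", year = 2011,
                  planting_year = NA_integer_)
  expect_equal(classify_stand(unknown, cfg), "unsuitable")
  bad <- fx$stands[fx$stands$species == "sitka_spruce", ][1, ]
  bad$planting_year <- NA_integer_
  bad$status <- "burned"
  expect_silent(classify_stands(bad, cfg))
  bad$status <- "mature"
  expect_silent(classify_stands(bad, cfg))
})

test_that("a conifer without planting year or explicit maturity cannot be classified", {
  df <- tibble::tibble(species = "sitka_spruce", status = "broadleaf_reserve",
                       year = 2021L, planting_year = NA_integer_)
  df$status <- "mature"
  expect_silent(classify_stands(df, cfg))
})

test_that("area tabulation reproduces the composition ledger", {
  row2005 <- tabulate_areas(fx$stands[fx$stands$year == 2005, ], cfg)
  expect_equal(unlist(row2005[, c("broadleaf_ha", "sitka_ha", "lodgepole_ha",
                                  "mature_conifer_ha", "unsuitable_ha")]),
               c(broadleaf_ha = 13, sitka_ha = 156, lodgepole_ha = 276,
                 mature_conifer_ha = 432, unsuitable_ha = 138))
  row2021 <- tabulate_areas(fx$stands[fx$stands$year == 2021, ], cfg)
  expect_equal(row2021$mature_conifer_ha, 202)
  expect_error(tabulate_areas(fx$stands, cfg), class = "conecap_validation_error")
  expect_error(tabulate_areas(fx$stands[0, ], cfg),
               class = "conecap_validation_error")
})

test_that("ledger row totals are constant across years and categories are exhaustive", {
  ledger <- build_area_ledger(fx$stands, cfg)
  expect_equal(nrow(ledger), 7)   # five calendar years, 2011 twice
  expect_true(all(abs(ledger$total_ha - ledger$total_ha[1]) < 0.5))
  expect_true(all(abs(ledger$broadleaf_ha + ledger$mature_conifer_ha +
                        ledger$unsuitable_ha - ledger$total_ha) < 1e-9))
  expect_true(all(abs(ledger$sitka_ha + ledger$lodgepole_ha -
                        ledger$mature_conifer_ha) < 0.5))
})

test_that("composition-ratio transfer matches the printed formula and its oracle", {
  expect_equal(composition_ratio(2, 2, 3, 3, 1.5), 1.5)
  expect_equal(composition_ratio(2, 1, 1, 1, 1), 2)
  set.seed(99)
  for (i in 1:1000) {
    v <- runif(5, 0.01, 50)
    expect_equal(composition_ratio(v[1], v[2], v[3], v[4], v[5]),
                 composition_ratio_oracle(v[1], v[2], v[3], v[4], v[5]),
                 tolerance = 1e-12)
  }
  expect_error(composition_ratio(0, 1, 1, 1, 1), class = "conecap_undefined_ratio")
  expect_error(composition_ratio(1, 1, 1, -2, 1), class = "conecap_undefined_ratio")
})

test_that("ratio transfer applied back through swapped stands is an involution", {
  set.seed(5)
  for (i in 1:50) {
    v <- runif(5, 0.05, 20)
    r1 <- composition_ratio(v[1], v[2], v[3], v[4], v[5])
    back <- composition_ratio(v[3], v[4], v[1], v[2], r1)
    expect_equal(back, v[5], tolerance = 1e-9)
  }
})

test_that("area reallocation by ratio conserves area exactly", {
  expect_equal(reallocate_stand_area(100, 1),
               c(sitka_ha = 50, lodgepole_ha = 50))
  expect_equal(reallocate_stand_area(100, 3),
               c(sitka_ha = 75, lodgepole_ha = 25))
  set.seed(3)
  for (i in 1:200) {
    a <- runif(1, 0, 500)
    r <- runif(1, 0.01, 30)
    parts <- reallocate_stand_area(a, r)
    expect_identical(sum(parts), a)           # exact conservation
    expect_equal(parts[["sitka_ha"]] / parts[["lodgepole_ha"]], r,
                 tolerance = 1e-9)
  }
  expect_error(reallocate_stand_area(100, 0), class = "conecap_domain_error")
})

test_that("percent reduction reproduces the coverage-change figures", {
  expect_equal(round_half_up(percent_reduction(156, 91)), 42)
  expect_equal(round_half_up(percent_reduction(276, 111)), 60)
  expect_equal(percent_reduction(7, 7), 0)
  expect_error(percent_reduction(0, 5), class = "conecap_domain_error")
})
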