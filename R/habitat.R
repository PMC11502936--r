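#' Classify a stand snapshot into a habitat category
#'
#' A conifer stand is `mature` once its age (snapshot year minus planting
#' year, whole years) reaches the maturity threshold, inclusive; younger
#' conifers are `immature`. Felled, bare or burned stands are `unsuitable`
#' regardless of age, broadleaf reserve stands are `broadleaf`, and species
#' outside the conifer vocabulary are `unsuitable` habitat for squirrels.
#' A conifer with neither a planting year nor an explicit mature/immature
#' status cannot be classified and raises an error.
#'
#' @param stand A one-row data frame (or list) with fields `species`,
#'   `status`, `year`, `planting_year`.
#' @param cfg An [analysis_config()]; `maturity_age_years` sets the
#'   threshold.
#' @return One of `"mature"`, `"immature"`, `"unsuitable"`, `"broadleaf"`.
#' @export
#' @examples
#' classify_stand(list(species = "sitka_spruce", status = "mature",
#'                     year = 2005, planting_year = 1965))
classify_stand <- function(stand, cfg = analysis_config()) {
  classify_stands(as_tibble(as.list(stand)[c("species", "status", "year",
                                             "planting_year")]), cfg)
}

#' @param stands A validated stand tibble (several rows).
#' @rdname classify_stand
#' @export
classify_stands <- function(stands, cfg = analysis_config()) {
  df <- as_tibble(stands)
  if (!"planting_year" %in% names(df)) df$planting_year <- NA_integer_
  out <- character(nrow(df))
  overriding <- df$status %in% c("bare_or_felled", "burned")
  out[overriding] <- "unsuitable"
  broad <- !overriding & (df$status == "broadleaf_reserve" |
                            df$species == "broadleaf")
  out[broad] <- "broadleaf"
  other <- !overriding & !broad & df$species == "other"
  out[other] <- "unsuitable"
  conifer <- !overriding & !broad & !other
  has_py <- conifer & !is.na(df$planting_year)
  age <- df$year - df$planting_year
  out[has_py & age >= cfg$maturity_age_years] <- "mature"
  out[has_py & age < cfg$maturity_age_years] <- "immature"
  fallback <- conifer & is.na(df$planting_year)
  ok_status <- fallback & df$status %in% c("mature", "immature")
  out[ok_status] <- df$status[ok_status]
  unclassifiable <- which(fallback & !df$status %in% c("mature", "immature"))
  if (length(unclassifiable) > 0) {
    cc_abort(sprintf(
      "Conifer stand(s) without planting year or mature/immature status (rows %s).",
      paste(unclassifiable, collapse = ", ")),
      class = "conecap_classification_error")
  }
  out
}

#' Tabulate stand areas for one snapshot
#'
#' Aggregates a single year's (and label's) stand snapshots into the area
#' ledger categories: broadleaf reserve, mature Sitka spruce, mature
#' lodgepole pine, their sum (mature conifers) and everything unsuitable
#' (immature, bare, felled, burned, other). Values are exact internally;
#' round for display.
#'
#' @param stands Stand snapshots for exactly one (year, label).
#' @param cfg An [analysis_config()].
#' @return A one-row tibble: `year`, `label`, `broadleaf_ha`, `sitka_ha`,
#'   `lodgepole_ha`, `mature_conifer_ha`, `unsuitable_ha`, `total_ha`.
#' @export
tabulate_areas <- function(stands, cfg = analysis_config()) {
  df <- validate_stands(stands)
  if (nrow(df) == 0) {
    cc_abort("No stand snapshots supplied.", class = "conecap_validation_error")
  }
  key <- unique(df[, c("year", "label")])
  if (nrow(key) != 1) {
    cc_abort("`tabulate_areas()` expects a single (year, label) snapshot; use `build_area_ledger()` for several.",
             class = "conecap_validation_error")
  }
  cls <- classify_stands(df, cfg)
  mature <- cls == "mature"
  tibble(
    year = key$year,
    label = key$label,
    broadleaf_ha = sum(df$area_ha[cls == "broadleaf"]),
    sitka_ha = sum(df$area_ha[mature & df$species == "sitka_spruce"]),
    lodgepole_ha = sum(df$area_ha[mature & df$species == "lodgepole_pine"]),
    mature_conifer_ha = sum(df$area_ha[mature]),
    unsuitable_ha = sum(df$area_ha[cls %in% c("unsuitable", "immature")]),
    total_ha = sum(df$area_ha)
  )
}

#' Build the multi-year area ledger
#'
#' @param stands Stand snapshots spanning several years/labels.
#' @param cfg An [analysis_config()].
#' @return A tibble with one [tabulate_areas()] row per (year, label),
#'   ordered by year then label.
#' @export
build_area_ledger <- function(stands, cfg = analysis_config()) {
  df <- validate_stands(stands)
  keys <- unique(df[, c("year", "label")])
  keys <- keys[order(keys$year, keys$label), ]
  bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$year == keys$year[i] & df$label == keys$label[i], ]
    tabulate_areas(sub, cfg)
  }))
}

#' Transfer a known species ratio between stands via cone densities
#'
#' Estimates the (unknown) Sitka spruce : lodgepole pine tree ratio of stand
#' 1 from the known ratio of a reference stand 2, by assuming cone
#' production per m2 scales with species share the same way in both stands:
#'
#' \deqn{R_{SS1} = \frac{C_{SS1} \times C_{LP2} \times R_{SS2}}{C_{LP1}
#'   \times C_{SS2}}}
#'
#' where \eqn{C_{SS}} and \eqn{C_{LP}} are Sitka and lodgepole cone
#' densities (cones/m2). A stand where either species produced no cones
#' cannot be corrected and raises an error.
#'
#' @param c_ss1,c_lp1 Cone densities in stand 1 (ratio unknown), > 0.
#' @param c_ss2,c_lp2 Cone densities in stand 2 (ratio known), > 0.
#' @param r_ss2 Known Sitka:lodgepole ratio in stand 2, > 0.
#' @return The estimated ratio in stand 1 (positive real).
#' @export
#' @examples
#' composition_ratio(2, 1, 1, 1, 1)
composition_ratio <- function(c_ss1, c_lp1, c_ss2, c_lp2, r_ss2) {
  for (v in list(c_ss1 = c_ss1, c_lp1 = c_lp1, c_ss2 = c_ss2,
                 c_lp2 = c_lp2, r_ss2 = r_ss2)) {
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      cc_abort("All cone densities and the reference ratio must be positive; a stand with no cones of one species cannot be corrected.",
               class = "conecap_undefined_ratio")
    }
  }
  (c_ss1 * c_lp2 * r_ss2) / (c_lp1 * c_ss2)
}

#' Split a stand area by a species ratio
#'
#' @param area_ha Stand area, ha (>= 0).
#' @param r_ss Sitka:lodgepole ratio (> 0).
#' @return A named numeric vector `c(sitka_ha, lodgepole_ha)`; the parts sum
#'   to `area_ha` exactly.
#' @export
#' @examples
#' reallocate_stand_area(100, 3)
reallocate_stand_area <- function(area_ha, r_ss) {
  assert_non_negative(area_ha, "area_ha")
  assert_positive(r_ss, "r_ss")
  lp <- area_ha / (1 + r_ss)
  c(sitka_ha = area_ha - lp, lodgepole_ha = lp)
}

#' Percent reduction between two values
#'
#' @param before Baseline value (> 0).
#' @param after Later value.
#' @return `100 * (before - after) / before`, unrounded; round with
#'   [round_half_up()] for display.
#' @export
#' @examples
#' round_half_up(percent_reduction(432, 202))
percent_reduction <- function(before, after) {
  assert_positive(before, "before")
  if (!is.numeric(after) || any(!is.finite(after))) {
    cc_abort("`after` must be finite.", class = "conecap_domain_error")
  }
  100 * (before - after) / before
}
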