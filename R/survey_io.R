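#' Read and validate transect survey records
#'
#' Reads a comma-separated table of per-species cone counts on surveyed
#' strips. Required columns: `transect_id`, `year`, `stand_id`, `species`,
#' `cones_total`, `cones_consumed`; optional `length_m` (default 50) and
#' `width_m` (default 1). Every row is validated: counts must be
#' non-negative integers with `cones_consumed <= cones_total`, dimensions
#' strictly positive, species drawn from the conifer vocabulary.
#'
#' @param path Path to a CSV file (UTF-8, header row mandatory).
#' @return A tibble of validated transect records.
#' @export
read_transects <- function(path) {
  df <- read_csv_checked(path, c("transect_id", "year", "stand_id", "species",
                                 "cones_total", "cones_consumed"))
  if (!"length_m" %in% names(df)) df$length_m <- 50
  if (!"width_m" %in% names(df)) df$width_m <- 1
  validate_transects(df)
}

#' @param transects A data frame shaped like the `transects.csv` schema.
#' @rdname read_transects
#' @export
validate_transects <- function(transects) {
  df <- as_tibble(transects)
  df$year <- as.integer(df$year)
  df$cones_total <- as.numeric(df$cones_total)
  df$cones_consumed <- as.numeric(df$cones_consumed)
  assert_species(df$species)
  bad_count <- which(df$cones_total < 0 | df$cones_consumed < 0 |
                       df$cones_total != floor(df$cones_total) |
                       df$cones_consumed != floor(df$cones_consumed))
  if (length(bad_count) > 0) {
    cc_abort(sprintf("Cone counts must be non-negative integers (rows %s).",
                     paste(bad_count, collapse = ", ")),
             class = "conecap_validation_error")
  }
  bad_cons <- which(df$cones_consumed > df$cones_total)
  if (length(bad_cons) > 0) {
    cc_abort(sprintf("cones_consumed exceeds cones_total (rows %s).",
                     paste(bad_cons, collapse = ", ")),
             class = "conecap_validation_error")
  }
  bad_dim <- which(!(df$length_m > 0) | !(df$width_m > 0))
  if (length(bad_dim) > 0) {
    cc_abort(sprintf("Transect dimensions must be positive (rows %s).",
                     paste(bad_dim, collapse = ", ")),
             class = "conecap_validation_error")
  }
  df
}

#' Read and validate cone measurements
#'
#' Reads single-cone observations: `species`, `length_mm`, optional
#' `scale_count` (blank where not counted) and logical `consumed`. Lengths
#' must lie in (5, 200) mm; scale counts, where present, are non-negative
#' integers.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated cone measurements.
#' @export
read_cone_measurements <- function(path) {
  df <- read_csv_checked(path, c("species", "length_mm"))
  if (!"scale_count" %in% names(df)) df$scale_count <- NA_real_
  if (!"consumed" %in% names(df)) df$consumed <- FALSE
  validate_cone_measurements(df)
}

#' @param cones A data frame shaped like the `cones.csv` schema.
#' @rdname read_cone_measurements
#' @export
validate_cone_measurements <- function(cones) {
  df <- as_tibble(cones)
  assert_species(df$species)
  df$length_mm <- as.numeric(df$length_mm)
  df$scale_count <- as.numeric(df$scale_count)
  df$consumed <- as.logical(df$consumed)
  bad_len <- which(!is.finite(df$length_mm) | df$length_mm <= 5 | df$length_mm >= 200)
  if (length(bad_len) > 0) {
    cc_abort(sprintf("Cone lengths must lie in (5, 200) mm (rows %s).",
                     paste(bad_len, collapse = ", ")),
             class = "conecap_validation_error")
  }
  sc <- df$scale_count
  bad_sc <- which(!is.na(sc) & (sc < 0 | sc != floor(sc)))
  if (length(bad_sc) > 0) {
    cc_abort(sprintf("Scale counts must be non-negative integers (rows %s).",
                     paste(bad_sc, collapse = ", ")),
             class = "conecap_validation_error")
  }
  df
}

#' Read and validate the stand ledger
#'
#' Reads per-stand, per-snapshot-year composition rows: `stand_id`, `year`,
#' `species` (conifers, `broadleaf` or `other`), optional `planting_year`,
#' `status` (`mature`, `immature`, `bare_or_felled`, `burned`,
#' `broadleaf_reserve`), `area_ha` and logical `occupied`. An optional
#' `label` column distinguishes multiple snapshots within one calendar year
#' (e.g. pre- and post-disturbance); it defaults to `""`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated stand snapshots.
#' @export
read_stand_ledger <- function(path) {
  df <- read_csv_checked(path, c("stand_id", "year", "species", "status", "area_ha"))
  if (!"planting_year" %in% names(df)) df$planting_year <- NA_integer_
  if (!"occupied" %in% names(df)) df$occupied <- FALSE
  if (!"label" %in% names(df)) df$label <- ""
  validate_stands(df)
}

#' @param stands A data frame shaped like the `stands.csv` schema.
#' @rdname read_stand_ledger
#' @export
validate_stands <- function(stands) {
  df <- as_tibble(stands)
  df$year <- as.integer(df$year)
  df$planting_year <- as.integer(df$planting_year)
  df$area_ha <- as.numeric(df$area_ha)
  df$occupied <- as.logical(df$occupied)
  if (!"label" %in% names(df)) df$label <- ""
  df$label[is.na(df$label)] <- ""
  assert_species(df$species, allowed = STAND_SPECIES)
  bad_status <- setdiff(unique(df$status), STAND_STATUS)
  if (length(bad_status) > 0) {
    cc_abort(sprintf("Unknown stand status: %s.", paste(bad_status, collapse = ", ")),
             class = "conecap_validation_error")
  }
  bad_area <- which(!is.finite(df$area_ha) | df$area_ha < 0)
  if (length(bad_area) > 0) {
    cc_abort(sprintf("Stand areas must be non-negative (rows %s).",
                     paste(bad_area, collapse = ", ")),
             class = "conecap_validation_error")
  }
  df
}

#' Write and re-read the capacity report
#'
#' Writes the per-year capacity table (the machine twin of the headline
#' results table) to CSV at fixed display precision: whole hectares and
#' whole squirrels, whole kJ for energy totals, two decimals for any density
#' columns. A report written by `write_report()` and re-read with
#' [read_report()] round-trips byte-identically.
#'
#' @param results A non-empty data frame of per-year capacity estimates, as
#'   produced by [capacity_table()] or [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results) || nrow(as_tibble(results)) == 0) {
    cc_abort("Cannot write an empty report.", class = "conecap_validation_error")
  }
  df <- as_tibble(results)
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) {
    digits <- if (grepl("per_m2|density|percent|_pct", nm)) 2 else 0
    df[[nm]] <- round_half_up(df[[nm]], digits)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read_csv_checked(path, character(0))
}

#' @param x A tibble of transect, cone or stand records.
#' @param path Output file path.
#' @describeIn read_transects Write transect records back to the same CSV schema.
#' @export
write_transects <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @describeIn read_cone_measurements Write cone measurements back to CSV.
#' @param x,path Tibble and output file path.
#' @export
write_cone_measurements <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @describeIn read_stand_ledger Write stand snapshots back to CSV.
#' @param x,path Tibble and output file path.
#' @export
write_stands <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

# internal: read a CSV and fail loudly when required columns are absent
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    cc_abort(sprintf("File not found: %s", path), class = "conecap_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    cc_abort(sprintf("%s is missing required column(s): %s.",
                     basename(path), paste(missing, collapse = ", ")),
             class = "conecap_schema_error")
  }
  as_tibble(df)
}
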