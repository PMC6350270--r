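#' Read and validate an explant staining table
#'
#' Expects a UTF-8 CSV with header columns `patient`, `group`, `explant_id`,
#' `marker`, `positive_count`, `tumor_area_mm2`. Validation errors name the
#' offending data row (1-based, excluding the header).
#'
#' @param path CSV file path.
#' @return A tibble of staining records.
#' @export
read_explant_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("patient", "group", "explant_id", "marker",
                      "positive_count", "tumor_area_mm2"),
                sprintf("'%s'", path))
  fail_row <- function(cond, what) {
    if (any(cond)) {
      abort(sprintf("%s: %s in row %d.", path, what, which(cond)[1]))
    }
  }
  fail_row(!df$marker %in% c("Ki67", "TUNEL"),
           "marker must be 'Ki67' or 'TUNEL'")
  fail_row(!is.finite(df$positive_count) | df$positive_count < 0,
           "non-numeric or negative positive_count")
  fail_row(!is.finite(df$tumor_area_mm2) | df$tumor_area_mm2 <= 0,
           "tumor_area_mm2 must be positive")
  df
}

#' Write an explant staining table
#'
#' @param records Tibble of staining records.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_explant_table <- function(records, path) {
  check_columns(records, c("patient", "group", "explant_id", "marker",
                           "positive_count", "tumor_area_mm2"), "`records`")
  readr::write_csv(records, path)
  invisible(path)
}

#' Read and validate a caliper measurement table
#'
#' Expects a UTF-8 CSV with header columns `patient`, `group`, `mouse_id`,
#' `day`, `d1_mm`, `d2_mm`; the two diameters carry no ordering assumption.
#' Duplicate (mouse, day) rows and non-positive diameters are errors naming
#' the offending row.
#'
#' @param path CSV file path.
#' @return A tibble of caliper records.
#' @export
read_caliper_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("patient", "group", "mouse_id", "day", "d1_mm", "d2_mm"),
                sprintf("'%s'", path))
  fail_row <- function(cond, what) {
    if (any(cond)) {
      abort(sprintf("%s: %s in row %d.", path, what, which(cond)[1]))
    }
  }
  fail_row(!is.finite(df$day) | df$day < 0, "day must be a non-negative number")
  fail_row(!is.finite(df$d1_mm) | df$d1_mm <= 0, "d1_mm must be positive")
  fail_row(!is.finite(df$d2_mm) | df$d2_mm <= 0, "d2_mm must be positive")
  dup <- duplicated(df[, c("mouse_id", "day")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("%s: duplicate measurement for mouse '%s' on day %s (row %d).",
                  path, df$mouse_id[i], format(df$day[i]), i))
  }
  df
}

#' Write a caliper measurement table
#'
#' @param calipers Tibble of caliper records.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_caliper_table <- function(calipers, path) {
  check_columns(calipers, c("patient", "group", "mouse_id", "day",
                            "d1_mm", "d2_mm"), "`calipers`")
  readr::write_csv(calipers, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' The YAML mirrors the arguments of [scenario_config()]; `drug_effects` is
#' a list of mappings with keys `drug`, `prolif_multiplier`,
#' `apoptosis_multiplier`, `growth_inhibition`.
#'
#' @param path YAML file path.
#' @return A `teva_scenario` object.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$drug_effects)) abort(sprintf("%s: missing `drug_effects`.", path))
  effects <- purrr::map_dfr(raw$drug_effects, function(e) {
    drug_effect(e$drug, e$prolif_multiplier, e$apoptosis_multiplier,
                e$growth_inhibition)
  })
  raw$drug_effects <- effects
  if (!is.null(raw$measurement_days)) {
    raw$measurement_days <- as.numeric(unlist(raw$measurement_days))
  }
  do.call(scenario_config, raw)
}

#' Write a scenario configuration to YAML
#'
#' @param config A `teva_scenario` object.
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "teva_scenario"))
  x <- unclass(config)
  x$drug_effects <- purrr::transpose(as.list(config$drug_effects)) |>
    purrr::map(~ purrr::map(.x, identity))
  # precision 17 makes doubles round-trip exactly
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}
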