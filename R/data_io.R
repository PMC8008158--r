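# Reading, validating and completing the survey / population / divisions inputs.

SURVEY_COLUMNS <- c(
  "division_numeric_code", "start_date", "end_date", "is_in_union",
  "age_range", "data_series_type", "sample_mismatch",
  "contraceptive_use_modern", "contraceptive_use_traditional",
  "unmet_need_any", "se_modern", "se_traditional", "se_unmet_need"
)

PROP_COLUMNS <- c(
  modern = "contraceptive_use_modern",
  traditional = "contraceptive_use_traditional",
  unmet = "unmet_need_any"
)

SE_COLUMNS <- c(
  modern = "se_modern",
  traditional = "se_traditional",
  unmet = "se_unmet_need"
)

#' Read a contraceptive-use survey dataset
#'
#' Reads a CSV of aggregated survey estimates, one row per survey, with the
#' observed proportions of women using modern methods, using traditional
#' methods, and with unmet need for family planning, plus sampling errors
#' where available. Empty numeric cells become `NA` (missing), never zero.
#'
#' Validation is strict: unknown source-type labels, proportions outside
#' \[0, 1\], reversed survey dates, negative sampling errors, and rows in
#' which all three proportions are missing are rejected with an error naming
#' the offending row.
#'
#' @param path Path to a CSV file with header columns
#'   `division_numeric_code, start_date, end_date, is_in_union, age_range,
#'   data_series_type, sample_mismatch, contraceptive_use_modern,
#'   contraceptive_use_traditional, unmet_need_any, se_modern, se_traditional,
#'   se_unmet_need`.
#' @return A tibble with one row per survey observation, in file order.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(example_survey_data(), path)
#' read_survey_data(path)
read_survey_data <- function(path) {
  if (!file.exists(path)) {
    stop("survey data file not found: ", path, call. = FALSE)
  }
  obs <- readr::read_csv(
    path,
    col_types = readr::cols(
      division_numeric_code = readr::col_integer(),
      start_date = readr::col_double(),
      end_date = readr::col_double(),
      is_in_union = readr::col_character(),
      age_range = readr::col_character(),
      data_series_type = readr::col_character(),
      sample_mismatch = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(SURVEY_COLUMNS, names(obs))
  if (length(missing_cols) > 0) {
    stop("survey data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs <- obs[SURVEY_COLUMNS]
  validate_survey_data(obs)
  obs
}

validate_survey_data <- function(obs) {
  row_fail <- function(rows, msg) {
    if (any(rows)) {
      stop("survey data row ", which(rows)[1], ": ", msg, call. = FALSE)
    }
  }
  bad_source <- !(obs$data_series_type %in% FP_SOURCE_TYPES)
  row_fail(bad_source, paste0(
    "unknown data_series_type ",
    if (any(bad_source)) dQuote(obs$data_series_type[which(bad_source)[1]]) else "",
    " (expected one of ", paste(FP_SOURCE_TYPES, collapse = ", "), ")"
  ))
  row_fail(!(obs$is_in_union %in% c("Y", "N")), "is_in_union must be \"Y\" or \"N\"")
  row_fail(is.na(obs$start_date) | is.na(obs$end_date), "missing survey dates")
  row_fail(obs$start_date > obs$end_date, "start_date > end_date")
  for (k in names(PROP_COLUMNS)) {
    p <- obs[[PROP_COLUMNS[k]]]
    row_fail(!is.na(p) & (p < 0 | p > 1),
             paste0(PROP_COLUMNS[k], " outside [0, 1]"))
    s <- obs[[SE_COLUMNS[k]]]
    row_fail(!is.na(s) & s < 0, paste0(SE_COLUMNS[k], " is negative"))
  }
  all_missing <- is.na(obs$contraceptive_use_modern) &
    is.na(obs$contraceptive_use_traditional) & is.na(obs$unmet_need_any)
  row_fail(all_missing, "all three observed proportions are missing")
  both <- !is.na(obs$contraceptive_use_modern) &
    !is.na(obs$contraceptive_use_traditional)
  row_fail(
    both & (obs$contraceptive_use_modern + obs$contraceptive_use_traditional > 1),
    "modern + traditional use exceeds 1"
  )
  all3 <- both & !is.na(obs$unmet_need_any)
  row_fail(
    all3 & (obs$contraceptive_use_modern + obs$contraceptive_use_traditional +
              obs$unmet_need_any > 1),
    "modern + traditional + unmet need exceeds 1"
  )
  invisible(obs)
}

#' Filter survey observations to one population
#'
#' Keeps exactly the observations for one division and union status, in their
#' original order. An empty result is legal: the model fit then returns prior
#' samples.
#'
#' @param obs Survey data tibble, as from [read_survey_data()].
#' @param division_code Integer division (country or subnational area) code.
#' @param is_in_union `"Y"` (in-union women) or `"N"` (not-in-union women).
#' @return The matching rows of `obs`.
#' @export
filter_observations <- function(obs, division_code, is_in_union) {
  stopifnot(is_in_union %in% c("Y", "N"))
  dplyr::filter(
    obs,
    .data$division_numeric_code == division_code,
    .data$is_in_union == !!is_in_union
  )
}

#' Impute missing survey sampling errors
#'
#' Completes missing sampling errors before model fitting. For each component
#' (modern use, traditional use, unmet need), a missing standard error is set
#' to the largest observed standard error for that component among the
#' supplied observations; if none is observed, to `default_se`. All standard
#' errors are then floored at `se_floor`. Observed values above the floor are
#' never changed, so the operation is idempotent.
#'
#' @param obs Survey observations already filtered to one population.
#' @param default_se Fallback proportion-scale standard error used when a
#'   component has no observed SE at all (default 0.025).
#' @param se_floor Minimum admissible standard error (default 0.005).
#' @return `obs` with all SE columns complete and `>= se_floor`.
#' @export
impute_sampling_errors <- function(obs, default_se = 0.025, se_floor = 0.005) {
  for (col in SE_COLUMNS) {
    s <- obs[[col]]
    fill <- if (all(is.na(s))) default_se else max(s, na.rm = TRUE)
    s[is.na(s)] <- fill
    obs[[col]] <- pmax(s, se_floor)
  }
  obs
}

#' Read a divisions (hierarchical groupings) table
#'
#' @param path CSV with columns `division_numeric_code, name_country,
#'   division_numeric_code_sub_region, division_numeric_code_region`.
#' @return A tibble, one row per division.
#' @export
read_divisions <- function(path) {
  if (!file.exists(path)) {
    stop("divisions file not found: ", path, call. = FALSE)
  }
  div <- readr::read_csv(
    path,
    col_types = readr::cols(
      division_numeric_code = readr::col_integer(),
      name_country = readr::col_character(),
      division_numeric_code_sub_region = readr::col_integer(),
      division_numeric_code_region = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (anyDuplicated(div$division_numeric_code)) {
    stop("duplicate division_numeric_code in divisions table", call. = FALSE)
  }
  if (anyNA(div$division_numeric_code_sub_region) ||
      anyNA(div$division_numeric_code_region)) {
    stop("every division must map to a sub-region and a region", call. = FALSE)
  }
  div
}

#' Resolve the prior level for a division
#'
#' The global-parameter fixture stores prior blocks keyed by sub-region (the
#' level at which the global model shares information). A national fit uses
#' the division's sub-region key. In subnational mode each subnation is
#' treated as a "country" within the "subregion" of its parent nation, so the
#' divisions table lists the parent country's code in the sub-region column
#' and that country code is the prior-level key.
#'
#' @param divisions Divisions tibble, as from [read_divisions()].
#' @param division_code Division whose prior level is wanted.
#' @param subnational Logical; `TRUE` when `division_code` is a subnational
#'   area nested in a parent country.
#' @return The integer prior-level key.
#' @export
resolve_prior_level <- function(divisions, division_code, subnational = FALSE) {
  i <- match(division_code, divisions$division_numeric_code)
  if (is.na(i)) {
    stop("unknown division_numeric_code: ", division_code, call. = FALSE)
  }
  key <- divisions$division_numeric_code_sub_region[i]
  if (subnational && is.na(key)) {
    stop("division ", division_code, " has no parent country recorded",
         call. = FALSE)
  }
  key
}

#' Read a population-count dataset
#'
#' @param path CSV with columns `division_numeric_code, mid_year, is_in_union,
#'   population_count` (number of women aged 15-49).
#' @return A tibble, one row per (division, year, union status).
#' @export
read_population_counts <- function(path) {
  if (!file.exists(path)) {
    stop("population data file not found: ", path, call. = FALSE)
  }
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      division_numeric_code = readr::col_integer(),
      mid_year = readr::col_integer(),
      is_in_union = readr::col_character(),
      population_count = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_population_counts(counts)
  counts
}

validate_population_counts <- function(counts) {
  bad <- is.na(counts$population_count) | counts$population_count < 0
  if (any(bad)) {
    stop("population data row ", which(bad)[1],
         ": population_count must be a non-negative number", call. = FALSE)
  }
  if (!all(counts$is_in_union %in% c("Y", "N"))) {
    stop("population data: is_in_union must be \"Y\" or \"N\"", call. = FALSE)
  }
  key <- paste(counts$division_numeric_code, counts$mid_year, counts$is_in_union)
  if (anyDuplicated(key)) {
    stop("population data: duplicate (division, year, union) key: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  invisible(counts)
}

#' A tiny example survey dataset
#'
#' Three synthetic survey observations for one division, used in examples.
#'
#' @return A survey-data tibble.
#' @export
example_survey_data <- function() {
  tibble::tibble(
    division_numeric_code = 4L,
    start_date = c(2004.5, 2010.0, 2015.0),
    end_date = c(2005.5, 2011.0, 2015.5),
    is_in_union = "Y",
    age_range = "15-49",
    data_series_type = c("DHS", "MICS", "NATIONAL"),
    sample_mismatch = FALSE,
    contraceptive_use_modern = c(0.21, 0.27, 0.33),
    contraceptive_use_traditional = c(0.06, 0.05, 0.05),
    unmet_need_any = c(0.24, 0.22, 0.20),
    se_modern = c(0.015, 0.02, NA),
    se_traditional = c(0.01, NA, NA),
    se_unmet_need = c(0.02, 0.02, 0.025)
  )
}
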