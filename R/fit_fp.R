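# End-to-end wrapper: read/filter/impute the survey data, resolve the prior
# level, and fit one or both union statuses.

#' Fit the family-planning model for a population of interest
#'
#' High-level entry point mirroring the fitting workflow: filter the survey
#' data to the division and union status, impute missing sampling errors,
#' resolve the prior level from the divisions table, and sample the
#' posterior. With `is_in_union = "ALL"` the model is fit separately to
#' in-union and not-in-union women and a named list of the two fits is
#' returned; all-women estimates then come from [calc_fp()] with population
#' counts.
#'
#' @param survey_data A survey tibble or a path to a survey CSV.
#' @param divisions A divisions tibble or path.
#' @param global_parameters An `fp_global_parameters` object or path to the
#'   JSON fixture.
#' @param division_code Integer division code of the population of interest.
#' @param is_in_union `"Y"`, `"N"`, or `"ALL"` (default `"Y"`).
#' @param first_year,last_year Estimate window (defaults 1970 and 2030).
#' @param subnational Logical; treat the division as a subnational area whose
#'   prior level is its parent country.
#' @param default_se Fallback sampling error for [impute_sampling_errors()].
#' @param ... Further arguments passed to [fit_config()] (`chains`,
#'   `warmup_iterations`, `kept_iterations`, `seed`, `quantile_probs`).
#' @return An `fp_fit`, or for `"ALL"` a list of class `fp_fit_list` with
#'   elements `in_union` and `not_in_union`.
#' @export
fit_fp <- function(survey_data, divisions, global_parameters,
                   division_code, is_in_union = "Y",
                   first_year = 1970L, last_year = 2030L,
                   subnational = FALSE, default_se = 0.025, ...) {
  if (is.character(survey_data)) survey_data <- read_survey_data(survey_data)
  if (is.character(divisions)) divisions <- read_divisions(divisions)
  if (is.character(global_parameters)) {
    global_parameters <- read_global_parameters(global_parameters)
  }
  stopifnot(is_in_union %in% c("Y", "N", "ALL"))
  level_key <- resolve_prior_level(divisions, division_code, subnational)
  config <- fit_config(first_year = first_year, last_year = last_year,
                       subnational = subnational, ...)
  fit_one <- function(union) {
    obs <- filter_observations(survey_data, division_code, union)
    obs <- impute_sampling_errors(obs, default_se = default_se)
    fit_model(obs, global_parameters, level_key, config,
              division_code = division_code, is_in_union = union)
  }
  if (is_in_union == "ALL") {
    structure(list(in_union = fit_one("Y"), not_in_union = fit_one("N")),
              class = "fp_fit_list")
  } else {
    fit_one(is_in_union)
  }
}

#' @export
print.fp_fit_list <- function(x, ...) {
  cat("<fp_fit_list> named list of fits:\n")
  for (nm in names(x)) {
    cat("$", nm, "\n", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}
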