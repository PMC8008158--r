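# Derived family-planning indicators from posterior trajectory draws.

#' Names of the derived indicators
#'
#' Proportion indicators are shares of all women in the population; count
#' indicators (`users_*`, `women_with_unmet_need`) scale proportions by the
#' number of women and require population counts.
#'
#' @return Character vector of indicator names.
#' @export
indicator_names <- function() {
  c(PROPORTION_INDICATORS, COUNT_INDICATORS)
}

PROPORTION_INDICATORS <- c(
  "modern", "traditional", "total_use", "unmet_need", "non_use",
  "total_demand", "demand_satisfied", "demand_satisfied_modern",
  "unmet_need_modern"
)
COUNT_INDICATORS <- c(
  "users_modern", "users_traditional", "users_total", "women_with_unmet_need"
)
# indicators aggregated as count-weighted means; everything else is derived
BASE_INDICATORS <- c("modern", "traditional", "unmet_need")

# Per-draw indicator matrices (draws x years) from base trajectory matrices.
derive_indicator_matrices <- function(M, T, Z, n_women = NULL) {
  total_use <- M + T
  total_demand <- total_use + Z
  out <- list(
    modern = M,
    traditional = T,
    total_use = total_use,
    unmet_need = Z,
    non_use = 1 - total_use,
    total_demand = total_demand,
    demand_satisfied = total_use / total_demand,
    demand_satisfied_modern = M / total_demand,
    unmet_need_modern = Z + T
  )
  if (!is.null(n_women)) {
    scale <- function(p) sweep(p, 2, n_women, `*`)
    out$users_modern <- scale(M)
    out$users_traditional <- scale(T)
    # exact per-draw identity with the two user counts
    out$users_total <- out$users_modern + out$users_traditional
    out$women_with_unmet_need <- scale(Z)
  }
  out
}

# Resolve the n_women vector for the fit's division and union status over
# `years`; errors name any missing year.
counts_for_years <- function(counts, years, division_code, is_in_union) {
  if (!is.na(division_code)) {
    counts <- dplyr::filter(counts, .data$division_numeric_code == division_code)
  }
  if (!is.na(is_in_union)) {
    counts <- dplyr::filter(counts, .data$is_in_union == !!is_in_union)
  }
  i <- match(years, counts$mid_year)
  if (anyNA(i)) {
    stop("population counts missing for year(s) ",
         paste(years[is.na(i)], collapse = ", "),
         " (division ", division_code, ", is_in_union ", is_in_union, ")",
         call. = FALSE)
  }
  counts$population_count[i]
}

#' Per-draw indicator values
#'
#' Computes every derived indicator for each posterior draw and year:
#' `total_use = M + T`, `non_use = 1 - total_use`, `total_demand = total_use +
#' unmet_need`, `demand_satisfied = total_use / total_demand`,
#' `demand_satisfied_modern = modern / total_demand`, `unmet_need_modern =
#' unmet_need + traditional`, and user counts as proportion x number of women.
#' Ratio indicators are computed per draw, never as ratios of summaries.
#'
#' @param fit An `fp_fit`.
#' @param counts Optional population-count tibble
#'   ([read_population_counts()]); required for the count indicators. The
#'   count for an estimate's calendar year is used as-is (no interpolation);
#'   a missing year is an error.
#' @param years Years to report (default: the configured estimate window).
#' @return A tibble with columns `draw, year, indicator, value`.
#' @export
indicator_draws <- function(fit, counts = NULL, years = NULL) {
  cd <- fit$core_data
  if (is.null(years)) {
    years <- seq.int(cd$config$first_year, cd$config$last_year)
  }
  years <- as.integer(years)
  if (!all(years %in% cd$grid)) {
    stop("requested years outside the model grid", call. = FALSE)
  }
  cols <- match(years, cd$grid)
  n_women <- if (!is.null(counts)) {
    counts_for_years(counts, years, cd$division_numeric_code, cd$is_in_union)
  }
  mats <- derive_indicator_matrices(
    fit$trajectories$M[, cols, drop = FALSE],
    fit$trajectories$T[, cols, drop = FALSE],
    fit$trajectories$Z[, cols, drop = FALSE],
    n_women
  )
  indicator_matrices_to_tibble(mats, years)
}

indicator_matrices_to_tibble <- function(mats, years) {
  n_draws <- nrow(mats[[1]])
  dplyr::bind_rows(lapply(names(mats), function(ind) {
    tibble::tibble(
      draw = rep(seq_len(n_draws), times = length(years)),
      year = rep(years, each = n_draws),
      indicator = ind,
      value = as.vector(mats[[ind]])
    )
  }))
}

#' Summarize per-draw values into quantile estimates
#'
#' Empirical quantiles with linear interpolation between closest order
#' statistics (the type-7 convention), computed per indicator and year. The
#' default probabilities give the median and the 80% and 95% credible bands.
#'
#' @param draw_values Tibble with columns `draw, year, indicator, value`
#'   (from [indicator_draws()], [combine_union_fits()] or
#'   [aggregate_populations()]).
#' @param probs Strictly increasing probabilities in (0, 1).
#' @return An `fp_estimates` tibble: `indicator, year, percentile, value`,
#'   with a `units` column (`"proportion"` or `"women"`).
#' @export
summarize_quantiles <- function(draw_values,
                                probs = c(0.025, 0.10, 0.50, 0.90, 0.975)) {
  stopifnot(nrow(draw_values) > 0, all(probs > 0), all(probs < 1),
            !is.unsorted(probs, strictly = TRUE))
  out <- dplyr::reframe(
    dplyr::group_by(draw_values, .data$indicator, .data$year),
    percentile = probs,
    value = as.numeric(stats::quantile(.data$value, probs = probs, type = 7,
                                       names = FALSE))
  )
  out$units <- ifelse(out$indicator %in% COUNT_INDICATORS, "women",
                      "proportion")
  class(out) <- c("fp_estimates", class(out))
  out
}

#' Indicator estimates from a fit
#'
#' Convenience wrapper: [indicator_draws()] followed by
#' [summarize_quantiles()]. For a named list of union-status fits (from
#' [fit_fp()] with `is_in_union = "ALL"`) it returns estimates for in-union
#' women, not-in-union women, and the population-weighted all-women
#' combination.
#'
#' @param fit An `fp_fit`, or a named list with elements `in_union` and
#'   `not_in_union`.
#' @param counts Population counts; required for count indicators and for
#'   the all-women combination.
#' @param years Years to report (default: the configured window).
#' @param probs Quantile probabilities (default: the fit's configuration).
#' @return An `fp_estimates` tibble, or a named list of them (`in_union`,
#'   `not_in_union`, `all_women`).
#' @export
calc_fp <- function(fit, counts = NULL, years = NULL, probs = NULL) {
  if (inherits(fit, "fp_fit")) {
    probs <- probs %||% fit$core_data$config$quantile_probs
    est <- summarize_quantiles(indicator_draws(fit, counts, years), probs)
    attr(est, "division_numeric_code") <- fit$core_data$division_numeric_code
    attr(est, "is_in_union") <- fit$core_data$is_in_union
    return(est)
  }
  stopifnot(all(c("in_union", "not_in_union") %in% names(fit)))
  if (is.null(counts)) {
    stop("population counts are required to combine union-status fits into ",
         "all-women estimates", call. = FALSE)
  }
  probs <- probs %||% fit$in_union$core_data$config$quantile_probs
  all_draws <- combine_union_fits(fit$in_union, fit$not_in_union, counts,
                                  years)
  out <- list(
    in_union = calc_fp(fit$in_union, counts, years, probs),
    not_in_union = calc_fp(fit$not_in_union, counts, years, probs),
    all_women = summarize_quantiles(all_draws, probs)
  )
  attr(out$all_women, "division_numeric_code") <-
    fit$in_union$core_data$division_numeric_code
  attr(out$all_women, "is_in_union") <- "ALL"
  out
}

#' Write estimates to the long-format CSV
#'
#' Columns: `division_numeric_code, is_in_union, indicator, year, percentile,
#' value`.
#'
#' @param estimates An `fp_estimates` tibble (attributes carry the division
#'   and union status) or a named list of them.
#' @param path Output CSV path.
#' @param division_code,is_in_union Overrides for the metadata columns (used
#'   for aggregates, where the division is a user-supplied label).
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, division_code = NULL,
                            is_in_union = NULL) {
  flatten <- function(est, union_label) {
    tibble::tibble(
      division_numeric_code = division_code %||%
        attr(est, "division_numeric_code") %||% NA,
      is_in_union = union_label,
      indicator = est$indicator,
      year = est$year,
      percentile = est$percentile,
      value = est$value
    )
  }
  if (inherits(estimates, "fp_estimates")) {
    out <- flatten(estimates,
                   is_in_union %||% attr(estimates, "is_in_union") %||% NA)
  } else {
    out <- dplyr::bind_rows(lapply(names(estimates), function(nm) {
      flatten(estimates[[nm]],
              c(in_union = "Y", not_in_union = "N", all_women = "ALL")[[nm]])
    }))
  }
  readr::write_csv(out, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
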