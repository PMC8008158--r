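# Combining union-status fits into all-women estimates and aggregating fits
# across populations. Both are count-weighted means of the base proportions
# per posterior draw, with draws paired by (chain, iteration) index; user
# counts sum, and ratio indicators are recomputed from the aggregated bases.

check_fits_compatible <- function(fits) {
  grid <- fits[[1]]$core_data$grid
  n_draws <- nrow(fits[[1]]$params)
  for (f in fits[-1]) {
    if (!identical(f$core_data$grid, grid)) {
      stop("fits have mismatched year grids and cannot be combined",
           call. = FALSE)
    }
    if (nrow(f$params) != n_draws) {
      stop("fits have different draw counts; refusing to pair draws",
           call. = FALSE)
    }
  }
  invisible(grid)
}

# Weighted combination shared by both aggregation operations.
# fits: list of fp_fit; weights: list of n_women vectors over `years`.
aggregate_draws <- function(fits, weights, years) {
  w_total <- Reduce(`+`, weights)
  if (any(w_total <= 0)) {
    stop("total number of women is zero for some year; cannot form weights",
         call. = FALSE)
  }
  base <- list(M = 0, T = 0, Z = 0)
  for (i in seq_along(fits)) {
    cols <- match(years, fits[[i]]$core_data$grid)
    for (b in names(base)) {
      base[[b]] <- base[[b]] +
        sweep(fits[[i]]$trajectories[[b]][, cols, drop = FALSE], 2,
              weights[[i]], `*`)
    }
  }
  M <- sweep(base$M, 2, w_total, `/`)
  T <- sweep(base$T, 2, w_total, `/`)
  Z <- sweep(base$Z, 2, w_total, `/`)
  mats <- derive_indicator_matrices(M, T, Z, n_women = w_total)
  indicator_matrices_to_tibble(mats, years)
}

#' Combine in-union and not-in-union fits into all-women values
#'
#' For each posterior draw `d` (paired by chain and iteration across the two
#' fits) and year `t`, every base proportion is the count-weighted mean
#' `p_all = (W_in p_in + W_not p_not) / (W_in + W_not)` with weights given by
#' the number of in-union and not-in-union women in year `t`; user counts
#' sum, and ratio indicators (demand satisfied and variants) are recomputed
#' from the aggregated base proportions.
#'
#' @param fit_in,fit_not `fp_fit` objects for in-union and not-in-union women
#'   of the same division, sharing grid and draw count.
#' @param counts Population counts covering both union statuses for all
#'   requested years.
#' @param years Years to report (default: the configured window of `fit_in`).
#' @return A per-draw tibble `draw, year, indicator, value` for all women.
#' @export
combine_union_fits <- function(fit_in, fit_not, counts, years = NULL) {
  check_fits_compatible(list(fit_in, fit_not))
  cd <- fit_in$core_data
  if (is.null(years)) {
    years <- seq.int(cd$config$first_year, cd$config$last_year)
  }
  years <- as.integer(years)
  if (!all(years %in% cd$grid)) {
    stop("requested years outside the model grid", call. = FALSE)
  }
  w_in <- counts_for_years(counts, years, cd$division_numeric_code, "Y")
  w_not <- counts_for_years(counts, years,
                            fit_not$core_data$division_numeric_code, "N")
  aggregate_draws(list(fit_in, fit_not), list(w_in, w_not), years)
}

#' Aggregate fits across populations
#'
#' Aggregate estimates of the family-planning proportions are the weighted
#' average of the population-specific values, with weights given by the
#' number of women in each population (for in-union fits, the number of
#' in-union women, and so on); user counts sum. Ratio indicators are
#' recomputed from the aggregated base proportions, and the "no need"
#' category is available as `non_use - unmet_need` of the aggregate.
#'
#' @param fits List of `fp_fit` objects for distinct divisions, sharing union
#'   status, grid and draw count.
#' @param counts Population counts covering every fit's division for all
#'   requested years.
#' @param years Years to report (default: the configured window of the first
#'   fit).
#' @return A per-draw tibble `draw, year, indicator, value` for the combined
#'   population.
#' @export
aggregate_populations <- function(fits, counts, years = NULL) {
  stopifnot(length(fits) >= 1)
  check_fits_compatible(fits)
  divs <- vapply(fits, function(f) f$core_data$division_numeric_code,
                 numeric(1))
  if (anyDuplicated(divs)) {
    stop("duplicate divisions among the fits to aggregate: ",
         divs[duplicated(divs)][1], call. = FALSE)
  }
  unions <- vapply(fits, function(f) f$core_data$is_in_union, character(1))
  if (length(unique(unions)) > 1) {
    stop("fits to aggregate must share union status", call. = FALSE)
  }
  cd <- fits[[1]]$core_data
  if (is.null(years)) {
    years <- seq.int(cd$config$first_year, cd$config$last_year)
  }
  years <- as.integer(years)
  if (!all(years %in% cd$grid)) {
    stop("requested years outside the model grid", call. = FALSE)
  }
  weights <- lapply(fits, function(f) {
    counts_for_years(counts, years, f$core_data$division_numeric_code,
                     f$core_data$is_in_union)
  })
  aggregate_draws(fits, weights, years)
}
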