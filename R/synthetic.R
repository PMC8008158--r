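# Synthetic global-parameter fixtures and fully synthetic populations
# (truth + surveys + counts), generated from the model's own statistical
# structure so every operation is testable without external data.

#' Generate a global-parameter fixture
#'
#' Produces a valid fixture with documented defaults: an asymptote prior for
#' total use centred at `inv_logit(0.5) ~ 0.62` with unit logit-scale SD,
#' log-pace priors centred near 0.1/year (total use) and 0.08/year (modern
#' share), timing priors centred at 1995-2000 with 10-year SDs, AR(1)
#' autocorrelations drawn in \[0.8, 0.95\] with stationary SDs in
#' \[0.08, 0.15\], zero bias for the DHS reference source, small random
#' biases and non-sampling SDs for the other source types, and a fixed
#' unmet-need slope `beta = 1`. Deterministic under `seed`. The numeric
#' values are package constants chosen to resemble typical national survey
#' series; they are not estimates from any published model run.
#'
#' @param seed Integer seed.
#' @param level_keys Prior-level keys (sub-region or country codes) to
#'   generate blocks for.
#' @return A validated `fp_global_parameters` object.
#' @export
generate_global_parameters <- function(seed = 1L, level_keys = c(34L)) {
  set.seed(seed)
  levels <- lapply(stats::setNames(nm = as.character(level_keys)), function(k) {
    list(
      mu_logit_Ptilde = 0.5 + stats::rnorm(1, 0, 0.2), sd_logit_Ptilde = 1.0,
      mu_log_pace_P = log(0.10) + stats::rnorm(1, 0, 0.1), sd_log_pace_P = 0.5,
      mu_Omega_P = 2000 + stats::rnorm(1, 0, 2), sd_Omega_P = 10,
      mu_logit_Rtilde = 1.0 + stats::rnorm(1, 0, 0.2), sd_logit_Rtilde = 1.0,
      mu_log_pace_R = log(0.08) + stats::rnorm(1, 0, 0.1), sd_log_pace_R = 0.5,
      mu_Omega_R = 1995 + stats::rnorm(1, 0, 2), sd_Omega_R = 10,
      mu_alpha = -1.0 + stats::rnorm(1, 0, 0.1), sd_alpha = 0.5
    )
  })
  small_bias <- function() stats::rnorm(1, 0, 0.05)
  small_tau <- function() abs(stats::rnorm(1, 0, 0.05)) + 0.02
  bias <- list(DHS = c(modern = 0, traditional = 0, unmet = 0))
  tau <- list(DHS = c(modern = small_tau(), traditional = small_tau(),
                      unmet = small_tau()))
  for (s in setdiff(FP_SOURCE_TYPES, "DHS")) {
    bias[[s]] <- c(modern = small_bias(), traditional = small_bias(),
                   unmet = small_bias())
    tau[[s]] <- c(modern = small_tau(), traditional = small_tau(),
                  unmet = small_tau())
  }
  gp <- structure(
    list(
      levels = levels,
      ar = list(
        rho_P = stats::runif(1, 0.8, 0.95), sigma_P = stats::runif(1, 0.08, 0.15),
        rho_R = stats::runif(1, 0.8, 0.95), sigma_R = stats::runif(1, 0.08, 0.15),
        rho_Z = stats::runif(1, 0.8, 0.95), sigma_Z = stats::runif(1, 0.08, 0.15)
      ),
      beta = 1.0,
      bias = bias,
      tau = tau,
      tau_mismatch = 0.1
    ),
    class = "fp_global_parameters"
  )
  validate_global_parameters(gp)
  gp
}

#' Draw population parameters from the fixture priors
#'
#' @param gp Global parameters.
#' @param level_key Prior-level key.
#' @param grid Integer year grid (sets the distortion series length).
#' @return An `fp_parameters` object drawn from the prior.
#' @export
draw_population_parameters <- function(gp, level_key, grid) {
  b <- prior_level_block(gp, level_key)
  draw_ar1 <- function(rho, sigma, n) {
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, sigma)
    innov <- sigma * sqrt(1 - rho^2)
    for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, innov)
    e
  }
  n <- length(grid)
  population_parameters(
    Ptilde = inv_logit(stats::rnorm(1, b$mu_logit_Ptilde, b$sd_logit_Ptilde)),
    Omega_P = stats::rnorm(1, b$mu_Omega_P, b$sd_Omega_P),
    pace_P = exp(stats::rnorm(1, b$mu_log_pace_P, b$sd_log_pace_P)),
    Rtilde = inv_logit(stats::rnorm(1, b$mu_logit_Rtilde, b$sd_logit_Rtilde)),
    Omega_R = stats::rnorm(1, b$mu_Omega_R, b$sd_Omega_R),
    pace_R = exp(stats::rnorm(1, b$mu_log_pace_R, b$sd_log_pace_R)),
    alpha = stats::rnorm(1, b$mu_alpha, b$sd_alpha),
    eps_P = draw_ar1(gp$ar$rho_P, gp$ar$sigma_P, n),
    eps_R = draw_ar1(gp$ar$rho_R, gp$ar$sigma_R, n),
    eps_Z = draw_ar1(gp$ar$rho_Z, gp$ar$sigma_Z, n)
  )
}

#' Simulate one synthetic population
#'
#' Draws population parameters from the fixture priors, builds the latent
#' trajectories, and simulates survey observations from the exact observation
#' model: `logit(y) ~ Normal(logit(latent) + bias[source, component],
#' se_logit^2 + tau[source, component]^2)`, where the logit-scale sampling SD
#' is the delta-method transform of the supplied proportion-scale `se`.
#' Population counts grow smoothly over the grid. When `dir` is given, the
#' survey, population and divisions CSVs, the fixture, the truth table and a
#' JSON manifest (seed, file names) are written in the package's input
#' dialects.
#'
#' @param gp Global parameters.
#' @param level_key Prior-level key to draw from.
#' @param seed Integer seed (the simulation is deterministic under it).
#' @param grid_years Integer year grid of the truth (default 1991-2015).
#' @param survey_years Calendar years of the simulated surveys (default 5
#'   surveys spread over the grid).
#' @param source_types Source type per survey (recycled).
#' @param se Proportion-scale sampling SD per survey component (default
#'   0.02).
#' @param division_code,is_in_union Population labels written to the CSVs.
#' @param n_women_start Women aged 15-49 in the first grid year (default
#'   1e6); counts grow at 0.5%/year, both union statuses written.
#' @param params Optional `fp_parameters` truth; when supplied it is used
#'   instead of a fresh prior draw (useful for controlled experiments).
#' @param dir Optional output directory.
#' @return A list: `truth` (tibble year, P, R, Z, M, T), `params`, `surveys`,
#'   `counts`, `divisions`, `gp`, and the file paths when written.
#' @export
simulate_population <- function(gp, level_key = 34L, seed = 1L,
                                grid_years = 1991:2015,
                                survey_years = NULL,
                                source_types = c("DHS", "MICS", "DHS",
                                                 "NATIONAL", "OTHER"),
                                se = 0.02,
                                division_code = 4L, is_in_union = "Y",
                                n_women_start = 1e6, params = NULL,
                                dir = NULL) {
  set.seed(seed)
  if (is.null(survey_years)) {
    survey_years <- round(seq(min(grid_years) + 1, max(grid_years) - 3,
                              length.out = 5))
  }
  stopifnot(all(survey_years %in% grid_years))
  if (is.null(params)) {
    params <- draw_population_parameters(gp, level_key, grid_years)
  }
  truth <- latent_trajectories(params, grid_years, gp$beta)
  source_types <- rep_len(source_types, length(survey_years))
  se <- rep_len(se, length(survey_years))

  rows <- lapply(seq_along(survey_years), function(i) {
    yr <- survey_years[i]
    src <- source_types[i]
    row <- match(yr, truth$year)
    # Noise is drawn on the logit scale with a fixed logit-scale sampling SD
    # (the design input `se` transformed at the latent value); the CSV then
    # carries the proportion-scale SE implied by the realized observation, so
    # that the delta-method transform applied at fitting time recovers the
    # exact logit-scale SD the data were generated with. Rows violating the
    # deterministic sum constraints (modern + traditional <= 1, plus unmet
    # <= 1) are redrawn, so written datasets always pass input validation.
    for (try in 1:1000) {
      drawn <- lapply(names(FP_COMPONENTS), function(k) {
        latent <- truth[[FP_COMPONENTS[k]]][row]
        se_logit <- logit_scale_se(se[i], latent)
        sd_tot <- sqrt(se_logit^2 + gp$tau[[src]][[k]]^2)
        y <- inv_logit(logit(latent) + gp$bias[[src]][[k]] +
                         stats::rnorm(1, 0, sd_tot))
        list(y = y,
             se = se_logit * clamp_proportion(y) * (1 - clamp_proportion(y)))
      })
      names(drawn) <- names(FP_COMPONENTS)
      obs_y <- vapply(drawn, `[[`, numeric(1), "y")
      obs_se <- vapply(drawn, `[[`, numeric(1), "se")
      if (obs_y[["modern"]] + obs_y[["traditional"]] <= 1 &&
          sum(obs_y) <= 1) break
    }
    tibble::tibble(
      division_numeric_code = as.integer(division_code),
      start_date = yr - 0.25, end_date = yr + 0.25,
      is_in_union = is_in_union, age_range = "15-49",
      data_series_type = src, sample_mismatch = FALSE,
      contraceptive_use_modern = obs_y[["modern"]],
      contraceptive_use_traditional = obs_y[["traditional"]],
      unmet_need_any = obs_y[["unmet"]],
      se_modern = obs_se[["modern"]],
      se_traditional = obs_se[["traditional"]],
      se_unmet_need = obs_se[["unmet"]]
    )
  })
  surveys <- dplyr::bind_rows(rows)

  counts <- tidyr::expand_grid(
    division_numeric_code = as.integer(division_code),
    mid_year = as.integer(grid_years),
    is_in_union = c("Y", "N")
  )
  counts$population_count <- ifelse(counts$is_in_union == "Y", 1, 0.6) *
    n_women_start * exp(0.005 * (counts$mid_year - min(grid_years)))

  divisions <- tibble::tibble(
    division_numeric_code = as.integer(division_code),
    name_country = paste0("Synthetic-", division_code),
    division_numeric_code_sub_region = as.integer(level_key),
    division_numeric_code_region = 900L
  )

  out <- list(truth = truth, params = params, surveys = surveys,
              counts = counts, divisions = divisions, gp = gp,
              level_key = level_key, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      surveys = file.path(dir, "survey_data.csv"),
      counts = file.path(dir, "population_counts.csv"),
      divisions = file.path(dir, "divisions.csv"),
      gp = file.path(dir, "global_parameters.json"),
      truth = file.path(dir, "truth.csv")
    )
    readr::write_csv(surveys, paths$surveys)
    readr::write_csv(counts, paths$counts)
    readr::write_csv(divisions, paths$divisions)
    write_global_parameters(gp, paths$gp)
    readr::write_csv(truth, paths$truth)
    jsonlite::write_json(
      list(seed = seed, level_key = level_key,
           division_numeric_code = division_code, is_in_union = is_in_union,
           files = lapply(paths, basename)),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
    )
    out$paths <- paths
  }
  out
}
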