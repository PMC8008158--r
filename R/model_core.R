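# The single-population probability model: logistic systematic trends with
# stationary AR(1) distortions for total use, the modern share of use, and
# unmet need, plus a logit-scale survey likelihood with source-type biases
# and non-sampling error variances fixed by the global-parameter fixture.

#' Logit and inverse-logit transforms
#'
#' `logit()` maps a proportion in (0, 1) to the real line; `inv_logit()` is
#' its inverse. Proportions are clamped to `[0.001, 0.999]` before the
#' transform so that boundary survey values remain finite on the logit scale.
#'
#' @param p A proportion (vectorised).
#' @param x A real number (vectorised).
#' @param clamp Logical; clamp `p` into `[0.001, 0.999]` first (default TRUE).
#' @param lower,upper Clamping bounds used by `clamp_proportion()`.
#' @return `logit()`: real values; `inv_logit()`: proportions in (0, 1).
#' @export
logit <- function(p, clamp = TRUE) {
  if (clamp) p <- clamp_proportion(p)
  stats::qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' @rdname logit
#' @export
clamp_proportion <- function(p, lower = 0.001, upper = 0.999) {
  pmin(pmax(p, lower), upper)
}

#' Systematic logistic growth curve
#'
#' The systematic (distortion-free) trend of a prevalence indicator: a
#' logistic curve rising from 0 towards `asymptote`, reaching half the
#' asymptote at `timing`, with growth rate `pace` per year.
#'
#' @param t Decimal calendar year (vectorised).
#' @param asymptote Upper limit of the curve, in (0, 1).
#' @param timing Decimal year at which the curve reaches `asymptote / 2`.
#' @param pace Logistic growth rate per year, > 0.
#' @return `asymptote / (1 + exp(-pace * (t - timing)))`.
#' @export
systematic_curve <- function(t, asymptote, timing, pace) {
  stopifnot(asymptote > 0, asymptote < 1, pace > 0)
  asymptote * stats::plogis(pace * (t - timing))
}

#' Log-density of a zero-mean stationary AR(1) series
#'
#' Joint log-density of the distortion series: the first element is
#' `Normal(0, sigma^2)` (the stationary law) and each subsequent element is
#' `Normal(rho * previous, sigma^2 * (1 - rho^2))`.
#'
#' @param series Real vector of distortions on the model's transformed scale.
#' @param rho Autocorrelation, `|rho| < 1`.
#' @param sigma Stationary standard deviation, > 0.
#' @return The joint log-density (a scalar).
#' @export
ar1_log_density <- function(series, rho, sigma) {
  stopifnot(abs(rho) < 1, sigma > 0, length(series) >= 1)
  n <- length(series)
  lp <- stats::dnorm(series[1], 0, sigma, log = TRUE)
  if (n > 1) {
    innov_sd <- sigma * sqrt(1 - rho^2)
    lp <- lp + sum(stats::dnorm(series[-1], rho * series[-n], innov_sd,
                                log = TRUE))
  }
  lp
}

#' Survey reference time
#'
#' The reference time of a survey is the midpoint of its field period,
#' carried as a decimal year.
#'
#' @param start_date,end_date Decimal calendar years.
#' @return `(start_date + end_date) / 2`.
#' @export
survey_reference_time <- function(start_date, end_date) {
  (start_date + end_date) / 2
}

# Nearest integer grid year; exact .5 ties round down (determinism).
grid_year_of <- function(t) as.integer(ceiling(t - 0.5))

#' Estimation grid of calendar years
#'
#' Consecutive integer years spanning the requested estimate window widened
#' to include every survey reference time, so the model is always fit to all
#' data, including dates outside the requested window.
#'
#' @param first_year,last_year Integer bounds of the requested estimates.
#' @param obs_times Decimal survey reference times (may be empty).
#' @return An integer vector of consecutive years.
#' @export
make_year_grid <- function(first_year, last_year, obs_times = numeric(0)) {
  stopifnot(first_year <= last_year)
  lo <- min(first_year, if (length(obs_times)) floor(min(obs_times)) else first_year)
  hi <- max(last_year, if (length(obs_times)) ceiling(max(obs_times)) else last_year)
  seq.int(as.integer(lo), as.integer(hi))
}

#' Population-specific parameters
#'
#' Bundles the unknowns of a single-population fit: the logistic-trend
#' parameters of total use (`Ptilde`, `Omega_P`, `pace_P`) and of the modern
#' share of use (`Rtilde`, `Omega_R`, `pace_R`), the unmet-need level `alpha`
#' (logit scale), and the three AR(1) distortion series, one value per grid
#' year.
#'
#' @param Ptilde,Rtilde Asymptotes in (0, 1).
#' @param Omega_P,Omega_R Timing parameters (decimal years).
#' @param pace_P,pace_R Growth rates per year, > 0.
#' @param alpha Unmet-need level on the logit scale.
#' @param eps_P,eps_R,eps_Z Distortion series (same length as the grid).
#' @return A list of class `fp_parameters`.
#' @export
population_parameters <- function(Ptilde, Omega_P, pace_P,
                                  Rtilde, Omega_R, pace_R,
                                  alpha, eps_P, eps_R, eps_Z) {
  stopifnot(
    Ptilde > 0, Ptilde < 1, Rtilde > 0, Rtilde < 1,
    pace_P > 0, pace_R > 0,
    length(eps_P) == length(eps_R), length(eps_R) == length(eps_Z)
  )
  structure(
    list(Ptilde = Ptilde, Omega_P = Omega_P, pace_P = pace_P,
         Rtilde = Rtilde, Omega_R = Omega_R, pace_R = pace_R,
         alpha = alpha, eps_P = eps_P, eps_R = eps_R, eps_Z = eps_Z),
    class = "fp_parameters"
  )
}

#' Latent indicator trajectories
#'
#' Builds the per-year latent proportions from population parameters on an
#' integer year grid:
#' total use `P_t = Ptilde * inv_logit(pace_P * (t - Omega_P) + eps_P[t])`,
#' modern share `R_t = Rtilde * inv_logit(pace_R * (t - Omega_R) + eps_R[t])`,
#' unmet need `Z_t = (1 - P_t) * inv_logit(alpha + beta * P_t + eps_Z[t])`,
#' modern use `M_t = P_t * R_t`, traditional use `T_t = P_t * (1 - R_t)`.
#'
#' @param params An `fp_parameters` object (distortion series lengths must
#'   equal the grid length).
#' @param grid Integer year grid.
#' @param beta Fixed slope of unmet need in total use (from the fixture).
#' @return A tibble with columns `year, P, R, Z, M, T`.
#' @export
latent_trajectories <- function(params, grid, beta) {
  stopifnot(length(grid) >= 1, length(params$eps_P) == length(grid))
  P <- params$Ptilde *
    stats::plogis(params$pace_P * (grid - params$Omega_P) + params$eps_P)
  R <- params$Rtilde *
    stats::plogis(params$pace_R * (grid - params$Omega_R) + params$eps_R)
  Z <- (1 - P) * stats::plogis(params$alpha + beta * P + params$eps_Z)
  tibble::tibble(year = as.integer(grid), P = P, R = R, Z = Z,
                 M = P * R, T = P * (1 - R))
}

# Delta-method SE on the logit scale for an observed proportion y.
logit_scale_se <- function(se, y) {
  y <- clamp_proportion(y)
  se / (y * (1 - y))
}

#' Log-likelihood of one survey observation
#'
#' Sums, over the non-missing components (modern use, traditional use, unmet
#' need), Normal log-densities on the logit scale:
#' `logit(y) ~ Normal(logit(latent) + bias[source, component], se_logit^2 +
#' tau[source, component]^2 + tau_mismatch^2 * [sample_mismatch])`, where
#' `se_logit = se / (y (1 - y))` is the delta-method sampling SD. Missing
#' components contribute zero.
#'
#' @param ob A one-row survey tibble (SE-complete).
#' @param traj Latent trajectories from [latent_trajectories()].
#' @param gp Global parameters (bias, tau, tau_mismatch tables).
#' @return The scalar log-likelihood contribution.
#' @export
observation_log_likelihood <- function(ob, traj, gp) {
  t_i <- survey_reference_time(ob$start_date, ob$end_date)
  yr <- grid_year_of(t_i)
  row <- match(yr, traj$year)
  if (is.na(row)) {
    stop("observation reference year ", yr, " lies outside the model grid",
         call. = FALSE)
  }
  src <- ob$data_series_type
  lp <- 0
  for (k in names(FP_COMPONENTS)) {
    y <- ob[[PROP_COLUMNS[k]]]
    if (is.na(y)) next
    se <- ob[[SE_COLUMNS[k]]]
    if (is.na(se)) {
      stop("missing sampling error for component ", k,
           "; run impute_sampling_errors() first", call. = FALSE)
    }
    latent <- traj[[FP_COMPONENTS[k]]][row]
    sd_tot <- sqrt(logit_scale_se(se, y)^2 + gp$tau[[src]][[k]]^2 +
                     if (isTRUE(ob$sample_mismatch)) gp$tau_mismatch^2 else 0)
    lp <- lp + stats::dnorm(logit(y), logit(latent) + gp$bias[[src]][[k]],
                            sd_tot, log = TRUE)
  }
  lp
}

#' Exact log-posterior of the single-population model
#'
#' The sum of (a) Normal priors on `logit(Ptilde)`, `log(pace_P)`, `Omega_P`,
#' `logit(Rtilde)`, `log(pace_R)`, `Omega_R` and `alpha` at the fixture's
#' means and SDs for `level_key`; (b) the stationary AR(1) log-density of
#' each distortion series; and (c) the survey log-likelihood summed over
#' observations. With zero observations the posterior is the prior.
#'
#' @param params An `fp_parameters` object.
#' @param obs SE-complete survey observations for this population (possibly
#'   zero rows).
#' @param gp Global parameters.
#' @param level_key Prior-level key (must exist in the fixture).
#' @param grid Integer year grid matching the distortion series length.
#' @return The scalar log-posterior density (up to a constant).
#' @export
log_posterior <- function(params, obs, gp, level_key, grid) {
  b <- prior_level_block(gp, level_key)
  lp <-
    stats::dnorm(logit(params$Ptilde, clamp = FALSE), b$mu_logit_Ptilde,
                 b$sd_logit_Ptilde, log = TRUE) +
    stats::dnorm(log(params$pace_P), b$mu_log_pace_P, b$sd_log_pace_P,
                 log = TRUE) +
    stats::dnorm(params$Omega_P, b$mu_Omega_P, b$sd_Omega_P, log = TRUE) +
    stats::dnorm(logit(params$Rtilde, clamp = FALSE), b$mu_logit_Rtilde,
                 b$sd_logit_Rtilde, log = TRUE) +
    stats::dnorm(log(params$pace_R), b$mu_log_pace_R, b$sd_log_pace_R,
                 log = TRUE) +
    stats::dnorm(params$Omega_R, b$mu_Omega_R, b$sd_Omega_R, log = TRUE) +
    stats::dnorm(params$alpha, b$mu_alpha, b$sd_alpha, log = TRUE) +
    ar1_log_density(params$eps_P, gp$ar$rho_P, gp$ar$sigma_P) +
    ar1_log_density(params$eps_R, gp$ar$rho_R, gp$ar$sigma_R) +
    ar1_log_density(params$eps_Z, gp$ar$rho_Z, gp$ar$sigma_Z)
  if (nrow(obs) > 0) {
    traj <- latent_trajectories(params, grid, gp$beta)
    for (i in seq_len(nrow(obs))) {
      lp <- lp + observation_log_likelihood(obs[i, ], traj, gp)
    }
  }
  lp
}
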