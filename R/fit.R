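# Posterior sampling for one population and the fitted-model container.

#' Fit configuration
#'
#' @param first_year,last_year Integer bounds of the returned estimates. The
#'   model is always fit to all data, including survey dates outside this
#'   window.
#' @param chains Number of MCMC chains (default 4).
#' @param warmup_iterations,kept_iterations Iterations discarded / retained
#'   per chain (defaults 1000 and 1000).
#' @param seed Integer RNG seed; identical inputs and seed give identical
#'   draws.
#' @param subnational Logical; `TRUE` when the division is a subnational area
#'   whose prior level is its parent country.
#' @param quantile_probs Strictly increasing probabilities used for posterior
#'   summaries; the defaults give the median and the 80% and 95% bands.
#' @return A list of class `fp_config`.
#' @export
fit_config <- function(first_year = 1970L, last_year = 2030L,
                       chains = 4L, warmup_iterations = 1000L,
                       kept_iterations = 1000L, seed = 1L,
                       subnational = FALSE,
                       quantile_probs = c(0.025, 0.10, 0.50, 0.90, 0.975)) {
  stopifnot(
    first_year <= last_year,
    chains >= 1, warmup_iterations >= 1, kept_iterations >= 1,
    all(quantile_probs > 0), all(quantile_probs < 1),
    !is.unsorted(quantile_probs, strictly = TRUE)
  )
  structure(
    list(first_year = as.integer(first_year), last_year = as.integer(last_year),
         chains = as.integer(chains),
         warmup_iterations = as.integer(warmup_iterations),
         kept_iterations = as.integer(kept_iterations),
         seed = as.integer(seed), subnational = isTRUE(subnational),
         quantile_probs = quantile_probs),
    class = "fp_config"
  )
}

THETA_NAMES <- c("logit_Ptilde", "log_pace_P", "Omega_P",
                 "logit_Rtilde", "log_pace_R", "Omega_R", "alpha")
PARAM_NAMES <- c("Ptilde", "pace_P", "Omega_P",
                 "Rtilde", "pace_R", "Omega_R", "alpha")

# Flatten SE-complete observations into per-component records aligned to the
# grid, with the source bias already subtracted from logit(y) and the total
# observation SD assembled (sampling + non-sampling + mismatch).
process_observations <- function(obs, gp, grid) {
  ref_time <- survey_reference_time(obs$start_date, obs$end_date)
  year <- grid_year_of(ref_time)
  out <- vector("list", length(FP_COMPONENTS))
  for (k in names(FP_COMPONENTS)) {
    y <- obs[[PROP_COLUMNS[k]]]
    keep <- !is.na(y)
    if (!any(keep)) next
    se <- obs[[SE_COLUMNS[k]]][keep]
    if (anyNA(se)) {
      stop("missing sampling errors for component ", k,
           "; run impute_sampling_errors() first", call. = FALSE)
    }
    src <- obs$data_series_type[keep]
    bias <- vapply(src, function(s) gp$bias[[s]][[k]], numeric(1))
    tau <- vapply(src, function(s) gp$tau[[s]][[k]], numeric(1))
    mism <- ifelse(obs$sample_mismatch[keep] %in% TRUE, gp$tau_mismatch, 0)
    yk <- y[keep]
    out[[k]] <- tibble::tibble(
      obs_index = which(keep),
      component = k,
      ref_time = ref_time[keep],
      year = year[keep],
      data_series_type = src,
      y = yk,
      y_clamped = clamp_proportion(yk) != yk,
      se = se,
      se_logit = logit_scale_se(se, yk),
      bias = bias,
      sd_total = sqrt(logit_scale_se(se, yk)^2 + tau^2 + mism^2),
      y_logit = logit(yk),
      y_bias_adjusted = inv_logit(logit(yk) - bias)
    )
  }
  comps <- dplyr::bind_rows(out)
  if (nrow(comps) == 0) {
    comps <- tibble::tibble(
      obs_index = integer(0), component = character(0),
      ref_time = numeric(0), year = integer(0),
      data_series_type = character(0), y = numeric(0),
      y_clamped = logical(0), se = numeric(0), se_logit = numeric(0),
      bias = numeric(0), sd_total = numeric(0), y_logit = numeric(0),
      y_bias_adjusted = numeric(0)
    )
  }
  if (nrow(comps) > 0 && !all(comps$year %in% grid)) {
    stop("observation reference years outside the model grid", call. = FALSE)
  }
  comps
}

#' Fit the single-population model by MCMC
#'
#' Samples the exact posterior defined by [log_posterior()] with an adaptive
#' Metropolis-within-Gibbs sampler (non-centered in the AR(1) innovations).
#' Zero observations is legal and yields samples from the prior.
#'
#' @param obs SE-complete survey observations already filtered to one
#'   population (see [filter_observations()], [impute_sampling_errors()]).
#' @param gp Global parameters ([read_global_parameters()]).
#' @param level_key Prior-level key ([resolve_prior_level()]).
#' @param config An [fit_config()] object.
#' @param division_code,is_in_union Optional population labels stored with
#'   the fit and used when joining population counts later.
#' @return An object of class `fp_fit`: posterior draws of the top-level
#'   parameters and the latent trajectories, plus `core_data` (processed and
#'   bias-adjusted observations, configuration, prior level, grid).
#' @export
fit_model <- function(obs, gp, level_key, config = fit_config(),
                      division_code = NA_integer_,
                      is_in_union = NA_character_) {
  validate_global_parameters(gp)
  b <- prior_level_block(gp, level_key)
  ref_time <- if (nrow(obs) > 0) {
    survey_reference_time(obs$start_date, obs$end_date)
  } else numeric(0)
  grid <- make_year_grid(config$first_year, config$last_year, ref_time)
  Tn <- length(grid)
  comps <- process_observations(obs, gp, grid)

  prior_mean <- c(b$mu_logit_Ptilde, b$mu_log_pace_P, b$mu_Omega_P,
                  b$mu_logit_Rtilde, b$mu_log_pace_R, b$mu_Omega_R, b$mu_alpha)
  prior_sd <- c(b$sd_logit_Ptilde, b$sd_log_pace_P, b$sd_Omega_P,
                b$sd_logit_Rtilde, b$sd_log_pace_R, b$sd_Omega_R, b$sd_alpha)
  rho <- c(gp$ar$rho_P, gp$ar$rho_R, gp$ar$rho_Z)
  sigma <- c(gp$ar$sigma_P, gp$ar$sigma_R, gp$ar$sigma_Z)
  comp_code <- c(modern = 0L, traditional = 1L, unmet = 2L)

  kept <- config$kept_iterations
  theta_arr <- array(NA_real_, c(kept, config$chains, 7),
                     dimnames = list(NULL, NULL, THETA_NAMES))
  z_all <- vector("list", config$chains)
  lp_arr <- matrix(NA_real_, kept, config$chains)

  for (chain in seq_len(config$chains)) {
    set.seed(config$seed + chain - 1L)
    res <- NULL
    for (attempt in 1:11) {
      init <- c(prior_mean + 0.1 * prior_sd * stats::rnorm(7),
                0.1 * stats::rnorm(3 * Tn))
      res <- tryCatch(
        .fp_run_chain(as.numeric(grid), prior_mean, prior_sd, rho, sigma,
                      gp$beta,
                      match(comps$year, grid) - 1L, comp_code[comps$component],
                      comps$y_logit - comps$bias, comps$sd_total,
                      init, config$warmup_iterations, kept),
        error = function(e) if (attempt <= 10) NULL else stop(e)
      )
      if (!is.null(res)) break
    }
    theta_arr[, chain, ] <- res$theta
    z_all[[chain]] <- res$z
    lp_arr[, chain] <- res$lp
  }

  # reconstruct constrained parameters and latent trajectories per draw
  theta_flat <- do.call(rbind, lapply(seq_len(config$chains),
                                      function(c) theta_arr[, c, ]))
  z_flat <- do.call(rbind, z_all)
  n_draws <- nrow(theta_flat)
  params <- tibble::tibble(
    chain = rep(seq_len(config$chains), each = kept),
    iteration = rep(seq_len(kept), config$chains),
    Ptilde = inv_logit(theta_flat[, 1]),
    pace_P = exp(theta_flat[, 2]),
    Omega_P = theta_flat[, 3],
    Rtilde = inv_logit(theta_flat[, 4]),
    pace_R = exp(theta_flat[, 5]),
    Omega_R = theta_flat[, 6],
    alpha = theta_flat[, 7],
    lp = as.vector(lp_arr)
  )

  eps <- lapply(1:3, function(s) {
    z <- z_flat[, (s - 1) * Tn + seq_len(Tn), drop = FALSE]
    e <- matrix(NA_real_, n_draws, Tn)
    innov <- sigma[s] * sqrt(1 - rho[s]^2)
    e[, 1] <- sigma[s] * z[, 1]
    for (t in seq_len(Tn)[-1]) e[, t] <- rho[s] * e[, t - 1] + innov * z[, t]
    e
  })
  yr_center <- function(pace, Omega) outer(pace, as.numeric(grid)) - pace * Omega
  P <- params$Ptilde * stats::plogis(yr_center(params$pace_P, params$Omega_P) +
                                       eps[[1]])
  R <- params$Rtilde * stats::plogis(yr_center(params$pace_R, params$Omega_R) +
                                       eps[[2]])
  Z <- (1 - P) * stats::plogis(params$alpha + gp$beta * P + eps[[3]])

  structure(
    list(
      params = params,
      trajectories = list(P = P, R = R, Z = Z, M = P * R, T = P * (1 - R)),
      theta_array = theta_arr,
      lp_array = lp_arr,
      core_data = list(
        observations = obs,
        processed_observations = comps,
        bias_adjusted = if (nrow(comps) > 0) {
          dplyr::select(comps, "obs_index", "component", "ref_time", "year",
                        "data_series_type", "y", "se", "y_bias_adjusted")
        } else comps,
        config = config,
        level_key = level_key,
        grid = grid,
        division_numeric_code = division_code,
        is_in_union = is_in_union
      )
    ),
    class = "fp_fit"
  )
}

#' @export
print.fp_fit <- function(x, ...) {
  cfg <- x$core_data$config
  cat("<fp_fit>\n")
  cat(sprintf("  population: division %s, is_in_union = %s\n",
              x$core_data$division_numeric_code, x$core_data$is_in_union))
  cat(sprintf("  grid: %d-%d (%d years), prior level %s\n",
              min(x$core_data$grid), max(x$core_data$grid),
              length(x$core_data$grid), x$core_data$level_key))
  cat(sprintf("  draws: %d chains x %d kept (%d warmup)\n",
              cfg$chains, cfg$kept_iterations, cfg$warmup_iterations))
  cat(sprintf("  observations: %d\n", nrow(x$core_data$observations)))
  invisible(x)
}

#' Tidy posterior summaries of the top-level parameters
#'
#' @param x An `fp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per top-level parameter: posterior mean, SD
#'   and the configured quantiles.
#' @export
tidy.fp_fit <- function(x, ...) {
  probs <- x$core_data$config$quantile_probs
  long <- tidyr::pivot_longer(
    dplyr::select(x$params, dplyr::all_of(PARAM_NAMES)),
    dplyr::everything(), names_to = "term", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$term),
    estimate = stats::median(.data$value),
    mean = mean(.data$value),
    std.error = stats::sd(.data$value),
    .groups = "drop"
  )
  qs <- dplyr::reframe(
    dplyr::group_by(long, .data$term),
    percentile = probs,
    value = as.numeric(stats::quantile(.data$value, probs, type = 7))
  )
  dplyr::left_join(
    out,
    tidyr::pivot_wider(qs, names_from = "percentile", values_from = "value",
                       names_prefix = "q"),
    by = "term"
  )
}

#' One-row fit summary
#'
#' @param x An `fp_fit`.
#' @param ... Unused.
#' @return A tibble with draw counts, observation count and the worst
#'   split-chain R-hat across top-level parameters.
#' @export
glance.fp_fit <- function(x, ...) {
  d <- convergence_diagnostics(x)
  tibble::tibble(
    chains = x$core_data$config$chains,
    kept_iterations = x$core_data$config$kept_iterations,
    n_obs = nrow(x$core_data$observations),
    max_rhat = suppressWarnings(max(d$rhat, na.rm = TRUE)),
    converged = attr(d, "converged")
  )
}

#' Serialize a fit to a directory
#'
#' Writes the draws as columnar CSV (one row per chain x iteration for the
#' top-level parameters; one row per chain x iteration x year for the latent
#' trajectories), the processed and bias-adjusted observations, and a JSON
#' manifest with the configuration, seed, prior level and grid.
#'
#' @param fit An `fp_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fit$params, file.path(dir, "parameters.csv"))
  cd <- fit$core_data
  traj <- tibble::tibble(
    chain = rep(fit$params$chain, each = length(cd$grid)),
    iteration = rep(fit$params$iteration, each = length(cd$grid)),
    year = rep(cd$grid, nrow(fit$params)),
    P = as.vector(t(fit$trajectories$P)),
    R = as.vector(t(fit$trajectories$R)),
    Z = as.vector(t(fit$trajectories$Z)),
    M = as.vector(t(fit$trajectories$M)),
    T = as.vector(t(fit$trajectories$T))
  )
  readr::write_csv(traj, file.path(dir, "trajectories.csv"))
  readr::write_csv(cd$observations, file.path(dir, "observations.csv"))
  readr::write_csv(cd$processed_observations,
                   file.path(dir, "processed_observations.csv"))
  jsonlite::write_json(
    list(
      config = unclass(cd$config), level_key = cd$level_key,
      grid = cd$grid,
      division_numeric_code = cd$division_numeric_code,
      is_in_union = cd$is_in_union
    ),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a serialized fit back from a directory
#'
#' @param dir Directory written by [write_fit()].
#' @return An `fp_fit` (without the raw unconstrained draw arrays; all
#'   indicator and aggregation operations work on the reloaded object).
#' @export
read_fit <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  config <- do.call(fit_config, man$config)
  params <- readr::read_csv(file.path(dir, "parameters.csv"),
                            show_col_types = FALSE, progress = FALSE)
  traj_long <- readr::read_csv(file.path(dir, "trajectories.csv"),
                               show_col_types = FALSE, progress = FALSE)
  grid <- as.integer(man$grid)
  n_draws <- nrow(params)
  as_mat <- function(v) matrix(v, nrow = n_draws, ncol = length(grid),
                               byrow = TRUE)
  obs <- readr::read_csv(file.path(dir, "observations.csv"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           is_in_union = readr::col_character(),
                           age_range = readr::col_character(),
                           data_series_type = readr::col_character()
                         ))
  processed <- readr::read_csv(file.path(dir, "processed_observations.csv"),
                               show_col_types = FALSE, progress = FALSE)
  theta_arr <- array(NA_real_,
                     c(config$kept_iterations, config$chains, 7),
                     dimnames = list(NULL, NULL, THETA_NAMES))
  for (ch in seq_len(config$chains)) {
    rows <- params$chain == ch
    theta_arr[, ch, ] <- cbind(
      logit(params$Ptilde[rows], clamp = FALSE), log(params$pace_P[rows]),
      params$Omega_P[rows],
      logit(params$Rtilde[rows], clamp = FALSE), log(params$pace_R[rows]),
      params$Omega_R[rows], params$alpha[rows]
    )
  }
  structure(
    list(
      params = params,
      trajectories = list(P = as_mat(traj_long$P), R = as_mat(traj_long$R),
                          Z = as_mat(traj_long$Z), M = as_mat(traj_long$M),
                          T = as_mat(traj_long$T)),
      theta_array = theta_arr,
      lp_array = matrix(params$lp, config$kept_iterations, config$chains),
      core_data = list(
        observations = obs,
        processed_observations = processed,
        bias_adjusted = if (nrow(processed) > 0 && "y_bias_adjusted" %in% names(processed)) {
          dplyr::select(processed, "obs_index", "component", "ref_time", "year",
                        "data_series_type", "y", "se", "y_bias_adjusted")
        } else processed,
        config = config, level_key = man$level_key, grid = grid,
        division_numeric_code = man$division_numeric_code,
        is_in_union = man$is_in_union
      )
    ),
    class = "fp_fit"
  )
}
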