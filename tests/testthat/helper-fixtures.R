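# Shared fixtures: a deterministic global-parameter set, small fitted models,
# hand-built fit objects with known trajectories, and a cache so expensive
# simulation experiments run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_gp <- function() cached("gp", generate_global_parameters(seed = 42L))

# a fixture with zero biases / non-sampling error, handy for exact checks
test_gp_clean <- function() {
  gp <- test_gp()
  for (s in names(gp$bias)) {
    gp$bias[[s]][] <- 0
    gp$tau[[s]][] <- 0
  }
  gp$tau_mismatch <- 0
  gp
}

test_grid <- 1991:2015

# one small but converged fit to real simulated data, reused across tests
test_fit <- function() {
  cached("fit", {
    sim <- test_sim()
    obs <- impute_sampling_errors(sim$surveys)
    fit_model(obs, test_gp(), 34L,
              fit_config(first_year = 1991, last_year = 2015, chains = 2,
                         warmup_iterations = 500, kept_iterations = 500,
                         seed = 99L),
              division_code = 4L, is_in_union = "Y")
  })
}

test_sim <- function() {
  cached("sim", simulate_population(test_gp(), seed = 7L,
                                    grid_years = test_grid))
}

# the full simulation-based calibration experiment (expensive; run once)
test_sbc <- function() cached("sbc", sbc_experiment(n_rep = 100, seed = 1L))

# Hand-built fit object with fully controlled trajectories, for exercising
# the indicator and aggregation contracts without MCMC.
make_fake_fit <- function(M, T, Z, grid = 2000:2002, division = 4L,
                          union = "Y", chains = 2L) {
  n_draws <- nrow(M)
  kept <- n_draws / chains
  config <- fit_config(first_year = min(grid), last_year = max(grid),
                       chains = chains, warmup_iterations = 1,
                       kept_iterations = kept, seed = 1)
  P <- M + T
  R <- M / P
  structure(
    list(
      params = tibble::tibble(
        chain = rep(seq_len(chains), each = kept),
        iteration = rep(seq_len(kept), chains),
        Ptilde = 0.5, pace_P = 0.1, Omega_P = 2000,
        Rtilde = 0.5, pace_R = 0.1, Omega_R = 2000, alpha = -1, lp = 0
      ),
      trajectories = list(P = P, R = R, Z = Z, M = M, T = T),
      theta_array = array(0, c(kept, chains, 7)),
      lp_array = matrix(0, kept, chains),
      core_data = list(
        observations = example_survey_data()[0, ],
        processed_observations = NULL, bias_adjusted = NULL,
        config = config, level_key = 34L, grid = as.integer(grid),
        division_numeric_code = division, is_in_union = union
      )
    ),
    class = "fp_fit"
  )
}

# constant-count population table covering a grid for given divisions
make_counts <- function(grid, divisions = 4L, n_women_y = 1e6,
                        n_women_n = 4e5) {
  out <- tidyr::expand_grid(division_numeric_code = as.integer(divisions),
                            mid_year = as.integer(grid),
                            is_in_union = c("Y", "N"))
  out$population_count <- ifelse(out$is_in_union == "Y",
                                 n_women_y, n_women_n)
  out
}

# dense multivariate-normal log-density with AR(1) covariance, used as the
# independent oracle for ar1_log_density
dense_ar1_oracle <- function(series, rho, sigma) {
  n <- length(series)
  Sigma <- sigma^2 * rho^abs(outer(seq_len(n), seq_len(n), `-`))
  -0.5 * (n * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus[1] +
            drop(series %*% solve(Sigma, series)))
}
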