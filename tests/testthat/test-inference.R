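# MCMC sampling: determinism, prior recovery, parameter recovery,
# convergence diagnostics.

test_that("identical inputs and seed give bit-identical draws", {
  gp <- test_gp()
  sim <- test_sim()
  obs <- impute_sampling_errors(sim$surveys)
  cfg <- fit_config(first_year = 1995, last_year = 2014, chains = 2,
                    warmup_iterations = 100, kept_iterations = 100, seed = 5)
  f1 <- fit_model(obs, gp, 34L, cfg)
  f2 <- fit_model(obs, gp, 34L, cfg)
  expect_identical(f1$theta_array, f2$theta_array)
  expect_identical(f1$trajectories, f2$trajectories)
  # a different seed moves the draws
  f3 <- fit_model(obs, gp, 34L,
                  fit_config(first_year = 1995, last_year = 2014, chains = 2,
                             warmup_iterations = 100, kept_iterations = 100,
                             seed = 6))
  expect_false(identical(f1$theta_array, f3$theta_array))
})

test_that("the fit carries core data: processed and bias-adjusted observations", {
  fit <- test_fit()
  cd <- fit$core_data
  expect_s3_class(cd$observations, "tbl_df")
  expect_equal(cd$level_key, 34L)
  expect_true(all(c("y_bias_adjusted", "component") %in%
                    names(cd$bias_adjusted)))
  # bias adjustment is observed logit minus source bias, back-transformed
  gp <- test_gp()
  po <- cd$processed_observations
  expect_equal(po$y_bias_adjusted,
               plogis(qlogis(pmin(pmax(po$y, 0.001), 0.999)) - po$bias),
               tolerance = 1e-12)
  # every draw satisfies the trajectory invariants
  tr <- fit$trajectories
  expect_true(all(tr$P > 0 & tr$P < 1))
  expect_true(all(abs(tr$M + tr$T - tr$P) < 1e-12))
  expect_true(all(tr$M + tr$T + tr$Z < 1))
  expect_true(all(tr$Z > 0 & tr$Z < 1 - tr$P))
})

test_that("with no data the sampler reproduces the prior", {
  gp <- test_gp()
  b <- prior_level_block(gp, 34)
  fit <- cached("prior_fit", {
    fit_model(example_survey_data()[0, ], gp, 34L,
              fit_config(first_year = 1991, last_year = 2015, chains = 2,
                         warmup_iterations = 500, kept_iterations = 1000,
                         seed = 12))
  })
  d <- convergence_diagnostics(fit)
  mu <- c(b$mu_logit_Ptilde, b$mu_log_pace_P, b$mu_Omega_P,
          b$mu_logit_Rtilde, b$mu_log_pace_R, b$mu_Omega_R, b$mu_alpha)
  sdp <- c(b$sd_logit_Ptilde, b$sd_log_pace_P, b$sd_Omega_P,
           b$sd_logit_Rtilde, b$sd_log_pace_R, b$sd_Omega_R, b$sd_alpha)
  for (j in 1:7) {
    draws <- fit$theta_array[, , j]
    mcse <- sdp[j] / sqrt(d$ess[j])
    expect_lt(abs(mean(draws) - mu[j]), 3 * mcse)
  }
})

test_that("precise synthetic surveys pin the latent modern prevalence", {
  gp <- test_gp()
  rec <- cached("recovery", {
    sim <- simulate_population(
      gp, seed = 11,
      survey_years = rep(1993:2012, length.out = 20),
      source_types = "DHS", se = 0.005
    )
    obs <- impute_sampling_errors(sim$surveys)
    fit <- fit_model(obs, gp, 34L,
                     fit_config(first_year = 1991, last_year = 2015,
                                chains = 2, warmup_iterations = 1000,
                                kept_iterations = 1000, seed = 77))
    list(sim = sim, fit = fit)
  })
  grid <- rec$fit$core_data$grid
  for (yr in unique(rec$sim$surveys$start_date + 0.25)) {
    med <- median(rec$fit$trajectories$M[, match(yr, grid)])
    truth <- rec$sim$truth$M[rec$sim$truth$year == yr]
    expect_lt(abs(med - truth), 0.02)
  }
})

test_that("posterior SD of modern prevalence contracts as data accumulate", {
  gp <- test_gp()
  sds <- cached("contraction", {
    vapply(c(1, 5, 20), function(k) {
      sim <- simulate_population(gp, seed = 21,
                                 survey_years = rep(2003, k),
                                 source_types = "DHS", se = 0.005)
      obs <- impute_sampling_errors(sim$surveys)
      fit <- fit_model(obs, gp, 34L,
                       fit_config(first_year = 1991, last_year = 2015,
                                  chains = 2, warmup_iterations = 1000,
                                  kept_iterations = 1000, seed = 33))
      sd(fit$trajectories$M[, match(2003, fit$core_data$grid)])
    }, numeric(1))
  })
  expect_true(all(diff(sds) < 0))
})

test_that("split-chain R-hat and ESS behave under known chain regimes", {
  make_diag_fit <- function(theta_chains, lp = NULL) {
    kept <- nrow(theta_chains)
    chains <- ncol(theta_chains)
    arr <- array(rep(theta_chains, 7), c(kept, chains, 7))
    structure(list(theta_array = arr,
                   lp_array = lp %||% theta_chains),
              class = "fp_fit")
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x

  # iid normal chains: R-hat close to 1, large ESS
  set.seed(41)
  d <- convergence_diagnostics(make_diag_fit(matrix(rnorm(4000), 1000, 4)))
  # split R-hat has a deterministic floor of sqrt((n-1)/n) per half-chain
  expect_true(all(d$rhat >= sqrt(499 / 500) - 1e-8))
  expect_true(all(d$rhat < 1.02))
  expect_true(all(d$ess <= 4000 + 1e-6))
  expect_true(all(d$ess > 1000))
  expect_true(attr(d, "converged"))

  # grossly separated chains
  d2 <- convergence_diagnostics(
    make_diag_fit(cbind(rnorm(500), rnorm(500, 100)))
  )
  expect_true(all(d2$rhat > 1.1))
  expect_false(attr(d2, "converged"))

  # constant chains report degenerate variance rather than crashing
  d3 <- convergence_diagnostics(make_diag_fit(matrix(1, 200, 2)))
  expect_true(all(is.na(d3$rhat)))

  # single chain is an error
  expect_error(convergence_diagnostics(make_diag_fit(matrix(rnorm(200), 200, 1))),
               "2 chains")
})

test_that("posterior ranks from self-simulated data are uniform", {
  sbc <- test_sbc()
  # chi-square goodness of fit on decile bins of the truth's rank
  bins <- table(cut(sbc$rank, breaks = seq(0, 1, by = 0.1),
                    include.lowest = TRUE))
  p <- suppressWarnings(chisq.test(as.vector(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("zero-observation fits and serialization round-trip the fit contract", {
  fit <- test_fit()
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(file.exists(file.path(dir, "parameters.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_fit(dir)
  expect_equal(back$trajectories$M, fit$trajectories$M, tolerance = 1e-12)
  expect_equal(back$params$Ptilde, fit$params$Ptilde, tolerance = 1e-12)
  expect_equal(back$core_data$grid, fit$core_data$grid)
  expect_equal(back$core_data$config$seed, fit$core_data$config$seed)
  # indicator pipeline works identically on the reloaded fit
  counts <- make_counts(fit$core_data$grid)
  e1 <- calc_fp(fit, counts, years = 2000:2005)
  e2 <- calc_fp(back, counts, years = 2000:2005)
  expect_equal(e1$value, e2$value, tolerance = 1e-12)
})

test_that("tidy and glance summarise a fit", {
  fit <- test_fit()
  td <- tidy(fit)
  expect_setequal(td$term, c("Ptilde", "pace_P", "Omega_P", "Rtilde",
                             "pace_R", "Omega_R", "alpha"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$chains, 2L)
  expect_true(is.finite(gl$max_rhat))
})
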