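# The probability model: transforms, systematic curves, AR(1) prior,
# trajectories, observation likelihood and log-posterior.

test_that("systematic curve matches its closed form and is monotone", {
  # logistic midpoint
  expect_equal(systematic_curve(2000, 0.8, 2000, 0.1), 0.4)
  # direct closed-form evaluation
  expect_equal(systematic_curve(2010, 0.8, 2000, 0.1), 0.8 / (1 + exp(-1)),
               tolerance = 1e-12)
  t <- seq(1900, 2100, by = 1)
  v <- systematic_curve(t, 0.8, 2000, 0.1)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 0.8))
  # left tail goes to zero
  expect_lt(systematic_curve(1700, 0.8, 2000, 0.1), 1e-10)
  expect_error(systematic_curve(2000, 1.2, 2000, 0.1))
})

test_that("logit transform round-trips and clamps boundary values", {
  expect_equal(logit(0.5), 0)
  expect_equal(inv_logit(logit(0.3)), 0.3, tolerance = 1e-12)
  p <- runif(50, 0.01, 0.99)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-12)
  # boundary input is clamped before the transform
  expect_equal(logit(1.0), logit(0.999))
  expect_equal(logit(0.0), logit(0.001))
})

test_that("AR(1) log-density agrees with the dense-covariance oracle", {
  # degenerate chain is the stationary normal
  expect_equal(ar1_log_density(0.3, 0.9, 0.2), dnorm(0.3, 0, 0.2, log = TRUE))
  # independence limit
  x <- c(-0.5, 0.2, 0.1, -0.3)
  expect_equal(ar1_log_density(x, 0, 0.15),
               sum(dnorm(x, 0, 0.15, log = TRUE)), tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    rho <- runif(1, -0.95, 0.95)
    sigma <- runif(1, 0.05, 2)
    x <- rnorm(n, 0, sigma)
    expect_equal(ar1_log_density(x, rho, sigma),
                 dense_ar1_oracle(x, rho, sigma), tolerance = 1e-8)
  }
  expect_error(ar1_log_density(x, 1.0, 0.2))
})

test_that("latent trajectories reduce to the systematic curves at zero distortion", {
  grid <- 1990:2020
  params <- population_parameters(
    Ptilde = 0.8, Omega_P = 2000, pace_P = 0.1,
    Rtilde = 0.9, Omega_R = 1995, pace_R = 0.08, alpha = -1,
    eps_P = rep(0, length(grid)), eps_R = rep(0, length(grid)),
    eps_Z = rep(0, length(grid))
  )
  traj <- latent_trajectories(params, grid, beta = 0)
  # logit(P/Ptilde) is exactly the linear systematic trend
  expect_equal(qlogis(traj$P / 0.8), 0.1 * (grid - 2000), tolerance = 1e-10)
  # hand evaluation of the stated formulas at t = 2010
  i <- match(2010, grid)
  expect_equal(traj$P[i], 0.8 * plogis(0.1 * 10), tolerance = 1e-12)
  expect_equal(traj$R[i], 0.9 * plogis(0.08 * 15), tolerance = 1e-12)
  expect_equal(traj$M[i], traj$P[i] * traj$R[i], tolerance = 1e-12)
  expect_equal(traj$Z[i], (1 - traj$P[i]) * plogis(-1), tolerance = 1e-12)
})

test_that("trajectory bounds and identities hold over random parameter draws", {
  gp <- test_gp()
  grid <- 1995:2005
  set.seed(11)
  viol <- 0L
  for (rep in 1:10000) {
    params <- population_parameters(
      Ptilde = runif(1, 0.01, 0.99), Omega_P = runif(1, 1960, 2040),
      pace_P = exp(runif(1, -4, 0)),
      Rtilde = runif(1, 0.01, 0.99), Omega_R = runif(1, 1960, 2040),
      pace_R = exp(runif(1, -4, 0)), alpha = rnorm(1, -1, 2),
      eps_P = rnorm(11, 0, 0.3), eps_R = rnorm(11, 0, 0.3),
      eps_Z = rnorm(11, 0, 0.3)
    )
    traj <- latent_trajectories(params, grid, beta = gp$beta)
    ok <- all(traj$P > 0 & traj$P < 1) && all(traj$R > 0 & traj$R < 1) &&
      all(traj$Z > 0 & traj$Z < 1 - traj$P) &&
      all(abs(traj$M + traj$T - traj$P) < 1e-14) &&
      all(traj$M + traj$T + traj$Z < 1)
    if (!ok) viol <- viol + 1L
  }
  expect_identical(viol, 0L)
})

test_that("observation likelihood matches a direct normal-density oracle", {
  gp <- test_gp()
  grid <- 2000:2010
  params <- population_parameters(
    Ptilde = 0.7, Omega_P = 2003, pace_P = 0.12,
    Rtilde = 0.8, Omega_R = 2001, pace_R = 0.1, alpha = -1,
    eps_P = rep(0, 11), eps_R = rep(0, 11), eps_Z = rep(0, 11)
  )
  traj <- latent_trajectories(params, grid, gp$beta)

  ob <- example_survey_data()[1, ]
  ob$start_date <- 2004.5
  ob$end_date <- 2005.5
  ob$data_series_type <- "MICS"
  ob$contraceptive_use_modern <- 0.30
  ob$contraceptive_use_traditional <- NA
  ob$unmet_need_any <- NA
  ob$se_modern <- 0.02

  # independent density evaluation with the stated mean and variance
  latent <- traj$M[match(2005, grid)]
  se_logit <- 0.02 / (0.30 * 0.70)
  want <- dnorm(qlogis(0.30),
                qlogis(latent) + gp$bias$MICS[["modern"]],
                sqrt(se_logit^2 + gp$tau$MICS[["modern"]]^2), log = TRUE)
  expect_equal(observation_log_likelihood(ob, traj, gp), want,
               tolerance = 1e-10)

  # all components missing contribute zero (empty product)
  ob0 <- ob
  ob0$contraceptive_use_modern <- NA
  expect_identical(observation_log_likelihood(ob0, traj, gp), 0)

  # centered single component with zero bias / tau: density at the mode
  gp0 <- test_gp_clean()
  ob1 <- ob
  ob1$data_series_type <- "DHS"
  ob1$contraceptive_use_modern <- latent
  se_logit1 <- 0.02 / (latent * (1 - latent))
  expect_equal(observation_log_likelihood(ob1, traj, gp0),
               -0.5 * log(2 * pi * se_logit1^2), tolerance = 1e-10)

  # sample mismatch inflates the variance by tau_mismatch^2
  ob2 <- ob
  ob2$sample_mismatch <- TRUE
  want2 <- dnorm(qlogis(0.30),
                 qlogis(latent) + gp$bias$MICS[["modern"]],
                 sqrt(se_logit^2 + gp$tau$MICS[["modern"]]^2 +
                        gp$tau_mismatch^2), log = TRUE)
  expect_equal(observation_log_likelihood(ob2, traj, gp), want2,
               tolerance = 1e-10)
})

test_that("log-posterior equals the hand-summed prior, AR(1) and likelihood terms", {
  gp <- test_gp()
  b <- prior_level_block(gp, 34)
  grid <- 2000:2009
  n <- length(grid)
  params <- population_parameters(
    Ptilde = plogis(b$mu_logit_Ptilde), Omega_P = b$mu_Omega_P,
    pace_P = exp(b$mu_log_pace_P),
    Rtilde = plogis(b$mu_logit_Rtilde), Omega_R = b$mu_Omega_R,
    pace_R = exp(b$mu_log_pace_R), alpha = b$mu_alpha,
    eps_P = rep(0, n), eps_R = rep(0, n), eps_Z = rep(0, n)
  )
  obs0 <- example_survey_data()[0, ]

  # term-by-term oracle at the prior modes with zero distortions
  want <- dnorm(b$mu_logit_Ptilde, b$mu_logit_Ptilde, b$sd_logit_Ptilde, log = TRUE) +
    dnorm(b$mu_log_pace_P, b$mu_log_pace_P, b$sd_log_pace_P, log = TRUE) +
    dnorm(b$mu_Omega_P, b$mu_Omega_P, b$sd_Omega_P, log = TRUE) +
    dnorm(b$mu_logit_Rtilde, b$mu_logit_Rtilde, b$sd_logit_Rtilde, log = TRUE) +
    dnorm(b$mu_log_pace_R, b$mu_log_pace_R, b$sd_log_pace_R, log = TRUE) +
    dnorm(b$mu_Omega_R, b$mu_Omega_R, b$sd_Omega_R, log = TRUE) +
    dnorm(b$mu_alpha, b$mu_alpha, b$sd_alpha, log = TRUE) +
    dense_ar1_oracle(rep(0, n), gp$ar$rho_P, gp$ar$sigma_P) +
    dense_ar1_oracle(rep(0, n), gp$ar$rho_R, gp$ar$sigma_R) +
    dense_ar1_oracle(rep(0, n), gp$ar$rho_Z, gp$ar$sigma_Z)
  expect_equal(log_posterior(params, obs0, gp, 34, grid), want,
               tolerance = 1e-10)

  # additivity: adding observations adds exactly their likelihood terms
  obs <- example_survey_data()
  obs$start_date <- c(2002, 2005, 2008) - 0.25
  obs$end_date <- c(2002, 2005, 2008) + 0.25
  obs <- impute_sampling_errors(obs)
  traj <- latent_trajectories(params, grid, gp$beta)
  lik <- sum(vapply(1:3, function(i) {
    observation_log_likelihood(obs[i, ], traj, gp)
  }, numeric(1)))
  expect_equal(log_posterior(params, obs, gp, 34, grid),
               log_posterior(params, obs0, gp, 34, grid) + lik,
               tolerance = 1e-10)

  # duplicating a row adds exactly its own term (difference oracle)
  expect_equal(log_posterior(params, obs[c(1, 1), ], gp, 34, grid) -
                 log_posterior(params, obs[1, , drop = FALSE], gp, 34, grid),
               observation_log_likelihood(obs[1, ], traj, gp),
               tolerance = 1e-10)

  expect_error(log_posterior(params, obs0, gp, 999, grid), "no prior block")
})

test_that("log-posterior decreases as an observation moves from its prediction", {
  gp <- test_gp_clean()
  b <- prior_level_block(gp, 34)
  grid <- 2000:2009
  n <- length(grid)
  params <- population_parameters(
    Ptilde = plogis(b$mu_logit_Ptilde), Omega_P = b$mu_Omega_P,
    pace_P = exp(b$mu_log_pace_P),
    Rtilde = plogis(b$mu_logit_Rtilde), Omega_R = b$mu_Omega_R,
    pace_R = exp(b$mu_log_pace_R), alpha = b$mu_alpha,
    eps_P = rep(0, n), eps_R = rep(0, n), eps_Z = rep(0, n)
  )
  traj <- latent_trajectories(params, grid, gp$beta)
  latent <- traj$M[match(2005, grid)]
  ob <- example_survey_data()[1, ]
  ob$start_date <- 2005
  ob$end_date <- 2005
  ob$contraceptive_use_traditional <- NA
  ob$unmet_need_any <- NA
  ob$se_modern <- 0.02
  # move the observed value away from the predicted mean on the logit scale
  offsets <- c(0, 0.5, 1, 2, 3)
  lp <- vapply(offsets, function(d) {
    ob$contraceptive_use_modern <- plogis(qlogis(latent) + d)
    # keep the logit-scale SE fixed so only the distance changes
    y <- ob$contraceptive_use_modern
    ob$se_modern <- 0.3 * y * (1 - y)
    log_posterior(params, ob, gp, 34, grid)
  }, numeric(1))
  expect_true(all(is.finite(lp)))
  expect_true(all(diff(lp) < 0))
})
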