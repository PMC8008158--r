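# Convergence diagnostics: split-chain potential scale reduction (R-hat) and
# effective sample size, computed per scalar top-level parameter.

# Split each chain in half; draws is an iterations x chains matrix.
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[seq.int(n - half + 1, n), , drop = FALSE])
}

rhat_scalar <- function(draws) {
  sp <- split_chains(draws)
  n <- nrow(sp)
  m <- ncol(sp)
  chain_means <- colMeans(sp)
  chain_vars <- apply(sp, 2, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(chain_means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_scalar <- function(draws) {
  sp <- split_chains(draws)
  n <- nrow(sp)
  m <- ncol(sp)
  chain_vars <- apply(sp, 2, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(colMeans(sp))
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  # multi-chain autocorrelation estimate with Geyer's initial positive
  # sequence truncation
  acov <- sapply(seq_len(ncol(sp)), function(j) {
    x <- sp[, j] - mean(sp[, j])
    stats::acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # sum consecutive pairs while positive
  tau <- 0
  t <- 1
  while (t + 1 < length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + pair
    t <- t + 2
  }
  ess <- n * m / (1 + 2 * tau)
  min(ess, n * m)
}

#' MCMC convergence diagnostics
#'
#' Computes the split-chain potential scale reduction factor (R-hat) and an
#' effective sample size for every top-level parameter (on the sampler's
#' unconstrained scale) and for the log-posterior. The overall convergence
#' flag is `TRUE` when every finite R-hat is below 1.1. Parameters with
#' degenerate (zero) within-chain variance get `NA` diagnostics rather than
#' an error.
#'
#' @param fit An `fp_fit` with at least two chains.
#' @return A tibble with columns `parameter, rhat, ess`, with the overall
#'   flag in attribute `"converged"`.
#' @export
convergence_diagnostics <- function(fit) {
  if (dim(fit$theta_array)[2] < 2) {
    stop("convergence diagnostics require at least 2 chains", call. = FALSE)
  }
  mats <- c(
    stats::setNames(
      lapply(seq_along(THETA_NAMES), function(j) fit$theta_array[, , j]),
      THETA_NAMES
    ),
    list(lp = fit$lp_array)
  )
  out <- tibble::tibble(
    parameter = names(mats),
    rhat = vapply(mats, rhat_scalar, numeric(1)),
    ess = vapply(mats, ess_scalar, numeric(1))
  )
  finite <- is.finite(out$rhat)
  attr(out, "converged") <- all(out$rhat[finite] < 1.1)
  out
}

#' Trace plots of the top-level parameters
#'
#' One trace plot per top-level parameter; written as image files when `dir`
#' is supplied, otherwise returned as a named list of ggplot objects.
#'
#' @param fit An `fp_fit`.
#' @param dir Optional output directory for PNG files.
#' @return Named list of ggplot objects (invisibly when written to `dir`).
#' @export
plot_traces <- function(fit, dir = NULL) {
  plots <- lapply(stats::setNames(nm = THETA_NAMES), function(p) {
    j <- match(p, THETA_NAMES)
    df <- tibble::tibble(
      iteration = rep(seq_len(dim(fit$theta_array)[1]),
                      dim(fit$theta_array)[2]),
      chain = factor(rep(seq_len(dim(fit$theta_array)[2]),
                         each = dim(fit$theta_array)[1])),
      value = as.vector(fit$theta_array[, , j])
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
      ggplot2::geom_line(alpha = 0.8, linewidth = 0.3) +
      ggplot2::labs(title = p, x = "iteration", y = p) +
      ggplot2::theme_minimal()
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in names(plots)) {
      ggplot2::ggsave(file.path(dir, paste0("trace_", p, ".png")), plots[[p]],
                      width = 7, height = 4, dpi = 120)
    }
    return(invisible(plots))
  }
  plots
}
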