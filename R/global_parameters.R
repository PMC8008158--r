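# The global-parameter fixture: every non-population-specific quantity the
# single-population model conditions on. In a full hierarchical run these would
# be estimated jointly across countries; here they are fixed inputs.

#' Read a global-parameter fixture
#'
#' The fixture is a JSON file with one prior block per prior-level key
#' (sub-region code, or country code for subnational runs) plus shared
#' blocks: AR(1) autocorrelations and stationary SDs for the three distortion
#' series, the fixed unmet-need slope `beta`, additive logit-scale biases and
#' non-sampling SDs by source type and component, and the extra SD applied to
#' observations whose sample population differs from the target group.
#'
#' @param path Path to the JSON fixture.
#' @return A validated `fp_global_parameters` list.
#' @export
read_global_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("global-parameter fixture not found: ", path, call. = FALSE)
  }
  gp <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  gp$levels <- lapply(gp$levels, function(b) lapply(b, as.numeric))
  gp$bias <- lapply(gp$bias, function(b) vapply(b, as.numeric, numeric(1)))
  gp$tau <- lapply(gp$tau, function(b) vapply(b, as.numeric, numeric(1)))
  class(gp) <- "fp_global_parameters"
  validate_global_parameters(gp)
  gp
}

#' Write a global-parameter fixture to JSON
#'
#' @param gp An `fp_global_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_global_parameters <- function(gp, path) {
  validate_global_parameters(gp)
  out <- unclass(gp)
  # bias/tau rows are named vectors; write them as JSON objects, not arrays
  out$bias <- lapply(out$bias, as.list)
  out$tau <- lapply(out$tau, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

LEVEL_FIELDS <- c(
  "mu_logit_Ptilde", "sd_logit_Ptilde",
  "mu_log_pace_P", "sd_log_pace_P",
  "mu_Omega_P", "sd_Omega_P",
  "mu_logit_Rtilde", "sd_logit_Rtilde",
  "mu_log_pace_R", "sd_log_pace_R",
  "mu_Omega_R", "sd_Omega_R",
  "mu_alpha", "sd_alpha"
)

#' Validate a global-parameter fixture
#'
#' Checks the structural invariants: all prior SDs positive, AR(1)
#' autocorrelations strictly inside (-1, 1) with positive stationary SDs,
#' non-sampling SDs non-negative, and zero bias for the DHS reference source.
#'
#' @param gp An `fp_global_parameters` list.
#' @return `gp`, invisibly; errors describe the first violated invariant.
#' @export
validate_global_parameters <- function(gp) {
  stopifnot(is.list(gp$levels), length(gp$levels) > 0)
  for (key in names(gp$levels)) {
    b <- gp$levels[[key]]
    missing_f <- setdiff(LEVEL_FIELDS, names(b))
    if (length(missing_f) > 0) {
      stop("prior block ", key, " is missing fields: ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    }
    sds <- unlist(b[grep("^sd_", LEVEL_FIELDS, value = TRUE)])
    if (any(sds <= 0)) stop("prior block ", key, ": all SDs must be > 0",
                            call. = FALSE)
  }
  ar <- gp$ar
  for (s in c("P", "R", "Z")) {
    rho <- ar[[paste0("rho_", s)]]
    sig <- ar[[paste0("sigma_", s)]]
    if (is.null(rho) || abs(rho) >= 1) {
      stop("AR(1) autocorrelation rho_", s, " must lie in (-1, 1)", call. = FALSE)
    }
    if (is.null(sig) || sig <= 0) {
      stop("AR(1) stationary SD sigma_", s, " must be > 0", call. = FALSE)
    }
  }
  if (is.null(gp$beta) || !is.finite(gp$beta)) {
    stop("fixed unmet-need slope beta is missing", call. = FALSE)
  }
  for (tbl in c("bias", "tau")) {
    missing_s <- setdiff(FP_SOURCE_TYPES, names(gp[[tbl]]))
    if (length(missing_s) > 0) {
      stop(tbl, " table is missing source types: ",
           paste(missing_s, collapse = ", "), call. = FALSE)
    }
    for (s in FP_SOURCE_TYPES) {
      missing_k <- setdiff(names(FP_COMPONENTS), names(gp[[tbl]][[s]]))
      if (length(missing_k) > 0) {
        stop(tbl, "[", s, "] is missing components: ",
             paste(missing_k, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (any(gp$bias$DHS != 0)) {
    stop("bias[DHS, ] must be 0 (DHS is the reference source type)",
         call. = FALSE)
  }
  if (any(unlist(gp$tau) < 0) || gp$tau_mismatch < 0) {
    stop("non-sampling SDs (tau, tau_mismatch) must be >= 0", call. = FALSE)
  }
  invisible(gp)
}

#' Fetch one prior-level block from a fixture
#'
#' @param gp An `fp_global_parameters` object.
#' @param level_key Prior-level key (sub-region or parent-country code).
#' @return The named list of prior means and SDs for that level.
#' @export
prior_level_block <- function(gp, level_key) {
  b <- gp$levels[[as.character(level_key)]]
  if (is.null(b)) {
    stop("global-parameter fixture has no prior block for level key ",
         level_key, " (available: ",
         paste(names(gp$levels), collapse = ", "), ")", call. = FALSE)
  }
  b
}

#' @export
print.fp_global_parameters <- function(x, ...) {
  cat("<fp_global_parameters>\n")
  cat("  prior levels:", paste(names(x$levels), collapse = ", "), "\n")
  cat(sprintf("  AR(1): rho_P=%.3f rho_R=%.3f rho_Z=%.3f; sigma_P=%.3f sigma_R=%.3f sigma_Z=%.3f\n",
              x$ar$rho_P, x$ar$rho_R, x$ar$rho_Z,
              x$ar$sigma_P, x$ar$sigma_R, x$ar$sigma_Z))
  cat(sprintf("  beta=%.3f, tau_mismatch=%.3f\n", x$beta, x$tau_mismatch))
  invisible(x)
}
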