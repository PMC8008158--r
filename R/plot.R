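# Plotting indicator estimates over time, with survey data overlaid.

# observed value of an indicator implied directly by the survey columns
observed_indicator_values <- function(obs, indicator) {
  y <- switch(
    indicator,
    modern = obs$contraceptive_use_modern,
    traditional = obs$contraceptive_use_traditional,
    unmet_need = obs$unmet_need_any,
    total_use = obs$contraceptive_use_modern + obs$contraceptive_use_traditional,
    return(NULL)
  )
  se <- switch(
    indicator,
    modern = obs$se_modern,
    traditional = obs$se_traditional,
    unmet_need = obs$se_unmet_need,
    total_use = sqrt(obs$se_modern^2 + obs$se_traditional^2),
    NULL
  )
  tibble::tibble(
    time = survey_reference_time(obs$start_date, obs$end_date),
    y = y, se = se, source = obs$data_series_type
  )
}

#' Plot indicator estimates over time
#'
#' One plot per requested indicator: the posterior median line, a dark
#' shaded band for the 80% credible interval and a lighter band for the 95%
#' credible interval, with survey observations (markers with +/- 2 SE bars)
#' overlaid where the indicator is directly observed. Proportion indicators
#' use a \[0, 1\] y-axis.
#'
#' @param estimates An `fp_estimates` tibble containing percentiles 0.025,
#'   0.10, 0.50, 0.90 and 0.975.
#' @param obs Optional survey observations to overlay.
#' @param indicators Indicator names to plot (default: all present in
#'   `estimates`). Unknown names are an error listing what is available.
#' @return A named list of ggplot objects.
#' @export
plot_estimates <- function(estimates, obs = NULL, indicators = NULL) {
  available <- unique(estimates$indicator)
  indicators <- indicators %||% available
  unknown <- setdiff(indicators, available)
  if (length(unknown) > 0) {
    stop("indicator(s) not present in the estimates: ",
         paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "), call. = FALSE)
  }
  lapply(stats::setNames(nm = indicators), function(ind) {
    wide <- tidyr::pivot_wider(
      dplyr::filter(estimates, .data$indicator == ind),
      id_cols = "year", names_from = "percentile", values_from = "value",
      names_prefix = "q"
    )
    p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$year)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$q0.025, ymax = .data$q0.975),
        fill = "#c5b8d9"
      ) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$q0.1, ymax = .data$q0.9),
        fill = "#8f6bb0"
      ) +
      ggplot2::geom_line(ggplot2::aes(y = .data$q0.5), colour = "#3d2a57",
                         linewidth = 0.7) +
      ggplot2::scale_x_continuous(limits = range(wide$year),
                                  expand = c(0, 0)) +
      ggplot2::labs(x = "year", y = ind, title = ind) +
      ggplot2::theme_minimal()
    is_prop <- !(ind %in% COUNT_INDICATORS)
    if (is_prop) {
      p <- p + ggplot2::coord_cartesian(ylim = c(0, 1))
    }
    if (!is.null(obs) && nrow(obs) > 0) {
      pts <- observed_indicator_values(obs, ind)
      if (!is.null(pts) && any(!is.na(pts$y))) {
        pts <- dplyr::filter(pts, !is.na(.data$y))
        p <- p +
          ggplot2::geom_pointrange(
            data = pts,
            ggplot2::aes(x = .data$time, y = .data$y,
                         ymin = pmax(.data$y - 2 * .data$se, 0),
                         ymax = pmin(.data$y + 2 * .data$se, 1),
                         shape = .data$source),
            inherit.aes = FALSE, colour = "black", size = 0.3
          )
      }
    }
    p
  })
}

#' Autoplot method for indicator estimates
#'
#' @param object An `fp_estimates` tibble.
#' @param indicator Single indicator to plot (default `"modern"` when
#'   present, else the first available).
#' @param obs Optional survey observations to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_estimates <- function(object, indicator = NULL, obs = NULL, ...) {
  available <- unique(object$indicator)
  indicator <- indicator %||%
    (if ("modern" %in% available) "modern" else available[1])
  plot_estimates(object, obs = obs, indicators = indicator)[[1]]
}
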