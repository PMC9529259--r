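#' @import ggplot2
#' @importFrom rlang .data
NULL

#' Plot a simulated response
#'
#' Stacked panels of applied force, dynamic threshold (in the signed input
#' frame) and discharge rate against time.
#'
#' @param object A `cs_response`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cs_response <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time_s", "force_mN", "threshold_mN", "rate_hz")],
    -"time_s", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel,
                         levels = c("force_mN", "threshold_mN", "rate_hz"),
                         labels = c("force (mN)", "threshold x (mN)",
                                    "discharge (Hz)"))
  ggplot(long, aes(.data$time_s, .data$value)) +
    geom_line(linewidth = 0.4) +
    facet_grid(rows = vars(.data$channel), scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot an experiment's summary metrics
#'
#' Offset series: antagonist off-response vs offset with an OLS line.
#' Duration series: off-response peak and |threshold creep| vs hold
#' duration. Rate series: peak discharge vs ramp rate on log-log axes.
#' Staircase: per-epoch mean discharge vs time for both subgroups.
#'
#' @param object A `cs_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cs_experiment <- function(object, ...) {
  m <- object$metrics
  switch(
    object$name,
    offset_series = {
      ant <- m[m$subgroup == "antagonist", ]
      ggplot(ant, aes(.data$offset_mN, .data$off_mean_hz)) +
        geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                    colour = "grey60", linewidth = 0.5) +
        geom_point() +
        labs(x = "offset load (mN)",
             y = "mean off-response (Hz)",
             title = "Offset suppression of unloading responses") +
        theme_minimal()
    },
    duration_series = {
      ant <- m[m$subgroup == "antagonist", ]
      long <- tidyr::pivot_longer(
        dplyr::transmute(ant, hold_s = .data$hold_s,
                         `off-response peak (Hz)` = .data$off_peak_hz,
                         `|threshold creep| (mN)` =
                           abs(.data$dx_creep_mN)),
        -"hold_s", names_to = "quantity", values_to = "value")
      ggplot(long, aes(.data$hold_s, .data$value)) +
        geom_line() + geom_point() +
        facet_wrap(vars(.data$quantity), scales = "free_y") +
        labs(x = "hold duration (s)", y = NULL,
             title = "Duration-dependent creep amplification") +
        theme_minimal()
    },
    rate_series = {
      cur <- object$rate_curves %||%
        abort("rate_series experiment has no rate curves",
              class = "campaniform_input_error")
      ggplot(cur, aes(.data$rate_mN_s, .data$peak_hz,
                      colour = .data$subgroup)) +
        geom_line() + geom_point() +
        scale_x_log10() + scale_y_log10() +
        labs(x = "ramp rate (mN/s)", y = "peak discharge (Hz)",
             title = "Emergent power-law rate sensitivity") +
        theme_minimal()
    },
    staircase = {
      ggplot(m, aes(.data$t_start, .data$mean_hz,
                    fill = .data$epoch)) +
        geom_col(width = 0.3) +
        facet_grid(rows = vars(.data$subgroup)) +
        labs(x = "epoch start (s)", y = "mean discharge (Hz)",
             title = "Staircase loading and unloading") +
        theme_minimal()
    },
    abort(paste0("no plot defined for experiment ", object$name),
          class = "campaniform_input_error")
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
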