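#' Simulated offset-series experiment
#'
#' Ramp-and-hold stimuli of identical amplitude and rate applied on top of
#' a series of sustained offset loads, simulated for both receptor
#' subgroups. The receptor starts fully adapted to the offset. The
#' antagonist off-response declines approximately linearly with offset
#' (offset suppression of unloading responses).
#'
#' @param offsets Offset loads, mN.
#' @param amplitude Test-ramp amplitude, mN.
#' @param rate Rise and fall rate, mN/s.
#' @param hold_s Hold duration, s.
#' @param params Named list of [cs_params()] for the `agonist` and
#'   `antagonist` subgroups.
#' @param dt,pre_s,post_s Trace sampling and padding, s.
#' @param keep_traces Keep the stimulus/response traces in the result.
#' @return A list of class `cs_experiment` with elements `name`, `metrics`
#'   (one row per subgroup x offset) and, optionally, `stimuli` and
#'   `responses`.
#' @examples
#' ex <- experiment_offset_series(offsets = c(0, 0.425, 0.85))
#' ex$metrics
#' @export
experiment_offset_series <- function(offsets = seq(0, 0.85, length.out = 5),
                                     amplitude = 0.85, rate = 8.5,
                                     hold_s = 1,
                                     params = default_subgroups(),
                                     dt = 0.001, pre_s = 1, post_s = 1,
                                     keep_traces = FALSE) {
  stims <- purrr::map(offsets, function(off) {
    stim_ramp_hold(amplitude = amplitude, rise_rate = rate,
                   fall_rate = rate, hold_s = hold_s, baseline = off,
                   pre_s = pre_s, post_s = post_s, dt = dt)
  })
  run_battery("offset_series", stims, params,
              trial_id = tibble(offset_mN = as.numeric(offsets)),
              keep_traces = keep_traces)
}

#' Simulated duration-series experiment
#'
#' Ramp-and-hold stimuli identical except for the hold duration. The
#' threshold "creep" accumulated during the hold, and with it the
#' off-response, grow with duration and saturate — the model analog of
#' viscoelastic creep in the cuticle.
#'
#' @param durations Strictly increasing hold durations, s.
#' @inheritParams experiment_offset_series
#' @return A `cs_experiment`; metric rows carry `hold_s` and
#'   `dx_creep_mN`.
#' @export
experiment_duration_series <- function(durations = c(0.25, 0.5, 1, 2, 4),
                                       amplitude = 2, rate = 10,
                                       params = default_subgroups(),
                                       dt = 0.001, pre_s = 0.5,
                                       post_s = 0.5,
                                       keep_traces = FALSE) {
  stims <- stim_duration_series(durations = durations,
                                amplitude = amplitude, rate = rate,
                                pre_s = pre_s, post_s = post_s, dt = dt)
  run_battery("duration_series", stims, params,
              trial_id = tibble(hold_s = as.numeric(durations)),
              keep_traces = keep_traces)
}

#' Simulated rate-series experiment
#'
#' Fixed-amplitude ramps over a sweep of rates; the peak discharge during
#' the encoding epoch follows an approximate power law in the ramp rate.
#'
#' @param rates Ramp rates, mN/s.
#' @inheritParams experiment_offset_series
#' @param hold_s Hold duration between rise and fall, s.
#' @return A `cs_experiment`.
#' @export
experiment_rate_series <- function(rates = 10^seq(-0.5, 1, by = 0.25),
                                   amplitude = 5, hold_s = 3,
                                   params = default_subgroups(),
                                   dt = 0.001, pre_s = 0.5, post_s = 0.5,
                                   keep_traces = FALSE) {
  stims <- stim_rate_series(rates = rates, amplitude = amplitude,
                            hold_s = hold_s, pre_s = pre_s,
                            post_s = post_s, dt = dt)
  ex <- run_battery("rate_series", stims, params,
                    trial_id = tibble(ramp_rate_mN_s = as.numeric(rates)),
                    keep_traces = TRUE)
  # attach the subgroup-appropriate peak-vs-rate curve
  ex$rate_curves <- purrr::imap_dfr(ex$responses, function(resps, sg) {
    dplyr::mutate(rate_sensitivity_curve(resps), subgroup = sg,
                  .before = 1)
  })
  if (!keep_traces) {
    ex$stimuli <- NULL
    ex$responses <- NULL
  }
  ex
}

#' Simulated staircase experiment
#'
#' Force climbs and descends in equal steps. The agonist subgroup fires on
#' up-steps with a tonic level that grows with load; the antagonist fires
#' only on down-steps, maximally at the final return to zero.
#'
#' @param step_mN,n_steps,rate,plateau_s Staircase geometry, see
#'   [stim_staircase()].
#' @inheritParams experiment_offset_series
#' @return A `cs_experiment`; `metrics` has one row per subgroup x epoch
#'   (columns `epoch`, `level_mN`, `mean_hz`, `peak_hz`).
#' @export
experiment_staircase <- function(step_mN = 1, n_steps = 5, rate = 10,
                                 plateau_s = 1,
                                 params = default_subgroups(),
                                 dt = 0.001, pre_s = 0.5, post_s = 0.5,
                                 keep_traces = FALSE) {
  stim <- stim_staircase(step_mN = step_mN, n_steps = n_steps, rate = rate,
                         plateau_s = plateau_s, pre_s = pre_s,
                         post_s = post_s, dt = dt)
  responses <- purrr::map(params, function(p) {
    simulate_response(stim, p, x0 = "adapted")
  })
  metrics <- purrr::imap_dfr(responses, function(resp, sg) {
    epochs <- segment_epochs(resp)
    purrr::pmap_dfr(epochs, function(epoch, start, end, t_start, t_end,
                                     duration_s) {
      y <- resp$rate_hz[start:end]
      tibble(subgroup = sg, epoch = epoch,
             t_start = t_start,
             level_mN = resp$force_mN[end],
             mean_hz = mean(y), peak_hz = max(y))
    })
  })
  out <- list(name = "staircase", metrics = metrics)
  if (keep_traces) {
    out$stimuli <- list(stim)
    out$responses <- responses
  }
  structure(out, class = "cs_experiment")
}

#' Default parameter sets for the two subgroups
#'
#' The demonstration tuning for the agonist (loading-excited) subgroup and
#' the same constants with negated input sign for the antagonist
#' (unloading-excited) subgroup.
#'
#' @return A named list with elements `agonist` and `antagonist`.
#' @export
default_subgroups <- function() {
  list(agonist = cs_params(subgroup = "agonist"),
       antagonist = cs_params(subgroup = "antagonist"))
}

# Simulate a battery of stimuli for each subgroup and collect per-trial
# epoch metrics; trial_id labels the swept protocol variable.
run_battery <- function(name, stims, params, trial_id, keep_traces) {
  stims <- unname(stims)
  responses <- purrr::map(params, function(p) {
    purrr::map(stims, function(s) simulate_response(s, p, x0 = "adapted"))
  })
  metrics <- purrr::imap_dfr(responses, function(resps, sg) {
    rows <- purrr::map_dfr(resps, epoch_metrics)
    dplyr::bind_cols(tibble(subgroup = sg), trial_id,
                     dplyr::select(rows, -"subgroup", -"offset_mN",
                                   -"hold_s"))
  })
  # restore protocol descriptors that epoch_metrics would also carry
  proto <- purrr::map_dfr(stims, function(s) {
    p <- attr(s, "protocol")
    tibble(offset_mN = p$baseline %||% NA_real_,
           hold_s = p$hold_s %||% NA_real_)
  })
  extra <- proto[rep(seq_len(nrow(proto)), times = length(params)),
                 setdiff(names(proto), names(metrics)), drop = FALSE]
  metrics <- dplyr::bind_cols(metrics, extra)
  out <- list(name = name, metrics = metrics)
  if (keep_traces) {
    out$stimuli <- stims
    out$responses <- responses
  }
  structure(out, class = "cs_experiment")
}

#' Run a named simulated experiment
#'
#' Dispatches to the corresponding `experiment_*()` function.
#'
#' @param name One of `"offset_series"`, `"duration_series"`,
#'   `"rate_series"`, `"staircase"`.
#' @param ... Passed to the experiment function.
#' @return A `cs_experiment`.
#' @export
run_experiment <- function(name, ...) {
  fn <- switch(name,
               offset_series = experiment_offset_series,
               duration_series = experiment_duration_series,
               rate_series = experiment_rate_series,
               staircase = experiment_staircase,
               abort(paste0("unknown experiment: ", name),
                     class = "campaniform_input_error"))
  fn(...)
}

#' @export
print.cs_experiment <- function(x, ...) {
  cat("<cs_experiment> ", x$name, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}
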