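#' Construct a stimulus trace
#'
#' A stimulus trace is a tibble with columns `time_s` (uniformly spaced,
#' strictly increasing) and `force_mN`, carrying the generating protocol as
#' an attribute. All stimulus generators in the package return this class.
#'
#' @param time_s Sample times in seconds (uniform step).
#' @param force_mN Applied bending force in mN, same length as `time_s`.
#' @param protocol Optional named list describing the generating protocol.
#' @return A tibble of class `cs_stimulus`.
#' @export
new_stimulus <- function(time_s, force_mN, protocol = list()) {
  out <- tibble(time_s = as.numeric(time_s), force_mN = as.numeric(force_mN))
  out <- structure(out, protocol = protocol,
                   class = c("cs_stimulus", class(out)))
  validate_stimulus(out)
}

validate_stimulus <- function(x) {
  if (!all(c("time_s", "force_mN") %in% names(x))) {
    abort("a stimulus needs `time_s` and `force_mN` columns",
          class = "campaniform_input_error")
  }
  tt <- x$time_s
  if (nrow(x) < 2L) {
    abort("a stimulus needs at least two samples",
          class = "campaniform_input_error")
  }
  if (anyNA(tt) || anyNA(x$force_mN) || !all(is.finite(x$force_mN))) {
    abort("stimulus samples must be finite", class = "campaniform_input_error")
  }
  dts <- diff(tt)
  if (any(dts <= 0)) {
    abort("`time_s` must be strictly increasing",
          class = "campaniform_input_error")
  }
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    abort("`time_s` must be uniformly spaced",
          class = "campaniform_input_error")
  }
  x
}

#' @export
print.cs_stimulus <- function(x, ...) {
  p <- attr(x, "protocol")
  if (!is.null(p$kind)) {
    cat("<cs_stimulus> ", p$kind, ", dt = ", format(stim_dt(x)),
        " s, ", nrow(x), " samples\n", sep = "")
  }
  NextMethod()
}

#' Sampling interval of a trace
#' @param x A stimulus or response trace.
#' @return The time step in seconds.
#' @export
stim_dt <- function(x) {
  stats::median(diff(x$time_s))
}

#' Protocol metadata of a generated trace
#' @param x A stimulus generated by one of the `stim_*()` builders.
#' @return The protocol descriptor list (kind, generator arguments, and the
#'   true epoch table `epochs` with columns `epoch`, `t_start`, `t_end`).
#' @export
stim_protocol <- function(x) {
  attr(x, "protocol")
}

# Sample a piecewise-linear force polyline onto a uniform grid. Knot times
# need not land on the grid: samples at or beyond a plateau corner take the
# plateau value exactly, so only the final partial ramp sample is adjusted.
sample_polyline <- function(knot_t, knot_u, dt, protocol = list()) {
  stopifnot(length(knot_t) == length(knot_u), dt > 0)
  n <- floor(knot_t[length(knot_t)] / dt + 1e-9)
  tt <- (0:n) * dt
  u <- approx(knot_t, knot_u, xout = tt, rule = 2)$y
  new_stimulus(tt, u, protocol = protocol)
}

# True epoch table from ramp/plateau knots: label each inter-knot segment.
knot_epochs <- function(knot_t, knot_u) {
  n <- length(knot_t) - 1L
  lab <- character(n)
  for (i in seq_len(n)) {
    dU <- knot_u[i + 1L] - knot_u[i]
    lab[i] <- if (dU > 0) "rise" else if (dU < 0) "fall" else "hold"
  }
  tibble(epoch = lab, t_start = knot_t[-length(knot_t)], t_end = knot_t[-1L])
}

#' Constant-force stimulus
#'
#' @param level Force level in mN.
#' @param duration_s Trace duration in seconds.
#' @param dt Sample interval in seconds.
#' @return A `cs_stimulus`.
#' @export
stim_constant <- function(level = 0, duration_s = 1, dt = 0.001) {
  kt <- c(0, duration_s)
  ku <- c(level, level)
  sample_polyline(kt, ku, dt,
                  protocol = list(kind = "constant", level = level,
                                  duration_s = duration_s, dt = dt,
                                  epochs = knot_epochs(kt, ku)))
}

#' Ramp-and-hold (trapezoidal) stimulus
#'
#' Force rises linearly from `baseline` to `baseline + amplitude` at
#' `rise_rate`, is held for `hold_s`, and returns to `baseline` at
#' `fall_rate`. Ramps are specified by rate (mN/s); their durations are
#' derived. Flat lead-in and lead-out segments at `baseline` bracket the
#' trapezoid.
#'
#' @param amplitude Ramp amplitude above baseline, mN (>= 0).
#' @param rise_rate,fall_rate Ramp rates, mN/s (> 0).
#' @param hold_s Hold-phase duration in seconds (>= 0).
#' @param baseline Sustained offset load, mN.
#' @param pre_s,post_s Baseline durations before and after the trapezoid, s.
#' @param dt Sample interval, s.
#' @return A `cs_stimulus`.
#' @examples
#' stim_ramp_hold(amplitude = 0.85, rise_rate = 8.5, hold_s = 1)
#' @export
stim_ramp_hold <- function(amplitude, rise_rate = 8.5, fall_rate = rise_rate,
                           hold_s = 1, baseline = 0, pre_s = 0.5,
                           post_s = 0.5, dt = 0.001) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    abort("`amplitude` must be a single number >= 0",
          class = "campaniform_input_error")
  }
  if (rise_rate <= 0 || fall_rate <= 0 || hold_s < 0 || dt <= 0) {
    abort("rates must be > 0 and durations >= 0",
          class = "campaniform_input_error")
  }
  pre_s <- max(pre_s, dt)
  post_s <- max(post_s, dt)
  if (amplitude == 0) {
    kt <- c(0, pre_s + hold_s + post_s)
    ku <- c(baseline, baseline)
  } else {
    t_rise <- amplitude / rise_rate
    t_fall <- amplitude / fall_rate
    kt <- cumsum(c(0, pre_s, t_rise, hold_s, t_fall, post_s))
    ku <- baseline + c(0, 0, amplitude, amplitude, 0, 0)
  }
  sample_polyline(
    kt, ku, dt,
    protocol = list(kind = "ramp_hold", amplitude = amplitude,
                    rise_rate = rise_rate, fall_rate = fall_rate,
                    hold_s = hold_s, baseline = baseline,
                    pre_s = pre_s, post_s = post_s, dt = dt,
                    epochs = knot_epochs(kt, ku))
  )
}

#' Staircase stimulus
#'
#' Force climbs to a maximum in `n_steps` equal ramp steps with plateaus,
#' then declines in equivalent steps, emulating the protocol used to probe
#' discharges at progressively increasing and decreasing load levels.
#'
#' @param step_mN Amplitude of each step, mN (> 0).
#' @param n_steps Number of steps up (and down); default 5.
#' @param rate Ramp rate of each step, mN/s.
#' @param plateau_s Plateau duration between steps, s.
#' @inheritParams stim_ramp_hold
#' @return A `cs_stimulus`; the peak force is `baseline + n_steps * step_mN`.
#' @export
stim_staircase <- function(step_mN = 1, n_steps = 5, rate = 10,
                           plateau_s = 1, baseline = 0, pre_s = 0.5,
                           post_s = 0.5, dt = 0.001) {
  if (step_mN <= 0 || n_steps < 1 || rate <= 0 || plateau_s < 0 || dt <= 0) {
    abort("invalid staircase specification",
          class = "campaniform_input_error")
  }
  n_steps <- as.integer(n_steps)
  t_step <- step_mN / rate
  kt <- 0
  ku <- baseline
  add <- function(dtm, lvl) {
    kt <<- c(kt, kt[length(kt)] + dtm)
    ku <<- c(ku, lvl)
  }
  add(max(pre_s, dt), baseline)
  for (i in seq_len(n_steps)) {
    add(t_step, baseline + i * step_mN)
    add(plateau_s, baseline + i * step_mN)
  }
  for (i in rev(seq_len(n_steps) - 1L)) {
    add(t_step, baseline + i * step_mN)
    if (i > 0L) add(plateau_s, baseline + i * step_mN)
  }
  add(max(post_s, dt), baseline)
  sample_polyline(
    kt, ku, dt,
    protocol = list(kind = "staircase", step_mN = step_mN,
                    n_steps = n_steps, rate = rate, plateau_s = plateau_s,
                    baseline = baseline, pre_s = pre_s, post_s = post_s,
                    dt = dt, epochs = knot_epochs(kt, ku))
  )
}

#' Duration-series protocol
#'
#' A sequence of ramp-and-hold stimuli identical except for the length of
#' the hold phase, used to probe duration-dependent ("creep") amplification
#' of off-responses.
#'
#' @param durations Strictly increasing hold durations, s.
#' @inheritParams stim_ramp_hold
#' @param rate Common rise and fall rate, mN/s.
#' @return A named list of `cs_stimulus` traces (one per duration).
#' @export
stim_duration_series <- function(durations = c(0.25, 0.5, 1, 2, 4),
                                 amplitude = 2, rate = 10, baseline = 0,
                                 pre_s = 0.5, post_s = 0.5, dt = 0.001) {
  if (length(durations) < 1L || any(durations < 0) ||
      is.unsorted(durations, strictly = TRUE)) {
    abort("`durations` must be strictly increasing and non-negative",
          class = "campaniform_input_error")
  }
  out <- purrr::map(durations, function(hold) {
    stim_ramp_hold(amplitude = amplitude, rise_rate = rate,
                   fall_rate = rate, hold_s = hold, baseline = baseline,
                   pre_s = pre_s, post_s = post_s, dt = dt)
  })
  names(out) <- paste0("hold_", durations, "s")
  out
}

#' Rate-series protocol
#'
#' Fixed-amplitude ramp-and-hold stimuli whose rise and fall rates sweep a
#' list of values, used to measure rate sensitivity (discharge vs dF/dt).
#'
#' @param rates Ramp rates, mN/s (all > 0).
#' @inheritParams stim_ramp_hold
#' @return A named list of `cs_stimulus` traces (one per rate).
#' @export
stim_rate_series <- function(rates = 10^seq(-0.5, 1, by = 0.25),
                             amplitude = 5, hold_s = 3, baseline = 0,
                             pre_s = 0.5, post_s = 0.5, dt = 0.001) {
  if (length(rates) < 1L || any(rates <= 0)) {
    abort("`rates` must all be positive", class = "campaniform_input_error")
  }
  out <- purrr::map(rates, function(r) {
    stim_ramp_hold(amplitude = amplitude, rise_rate = r, fall_rate = r,
                   hold_s = hold_s, baseline = baseline,
                   pre_s = pre_s, post_s = post_s, dt = dt)
  })
  names(out) <- paste0("rate_", signif(rates, 4))
  out
}
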