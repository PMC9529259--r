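#' Closed-form threshold relaxation under constant force
#'
#' Analytic solution of the dynamic-threshold equation
#' `tau * dx/dt = sign(u - x) * |u - x|^b` for constant input `u_const`.
#' Writing `w(t) = |u_const - x(t)|` and `w0 = |u_const - x0|`:
#' for `b = 1`, `w(t) = w0 * exp(-t/tau)`; otherwise
#' `w(t)^(1-b) = w0^(1-b) - (1-b) * t / tau` while positive, with `w = 0`
#' afterwards (finite-time convergence when `b < 1`). This is the oracle the
#' numerical integrator is verified against.
#'
#' @param u_const Constant applied force, mN.
#' @param x0 Initial threshold, mN.
#' @param params A [cs_params()] object (only `b` and `tau` are used).
#' @param t Times at which to evaluate, s (>= 0); vectorized.
#' @return Threshold values `x(t)` in mN.
#' @examples
#' p <- cs_params(b = 1, tau = 0.2)
#' threshold_step(2, 0, p, 0.2)  # 2 * (1 - exp(-1))
#' @export
threshold_step <- function(u_const, x0, params, t) {
  params <- as_cs_params(params)
  if (any(t < 0)) {
    abort("`t` must be >= 0", class = "campaniform_input_error")
  }
  w0 <- abs(u_const - x0)
  if (w0 == 0) return(rep(x0, length(t)))
  s <- sign(u_const - x0)
  b <- params$b
  tau <- params$tau
  if (b == 1) {
    w <- w0 * exp(-t / tau)
  } else {
    base <- w0^(1 - b) - (1 - b) * t / tau
    if (b < 1) {
      w <- ifelse(base <= 0, 0, base^(1 / (1 - b)))
    } else {
      w <- base^(1 / (1 - b))
    }
  }
  u_const - s * w
}

#' Integrator control settings
#'
#' @param max_frac Bound on the fractional threshold change (and on the
#'   linearized contraction `lambda * h`) per sub-step.
#' @param absorb_tol Gap below which the threshold is clamped onto the
#'   force (`sign(0)*|0|^b` is taken as 0), mN.
#' @param max_substeps Sub-stepping budget per stimulus sample.
#' @return A list of control settings.
#' @export
integrator_control <- function(max_frac = 0.1, absorb_tol = 1e-9,
                               max_substeps = 20000L) {
  list(max_frac = max_frac, absorb_tol = absorb_tol,
       max_substeps = as.integer(max_substeps))
}

#' Integrate the dynamic-threshold equation along a stimulus
#'
#' Numerically solves `tau * dx/dt = sign(u - x) * |u - x|^b` at the
#' stimulus sample times, treating the force as linear between samples.
#' For piecewise-constant forces the result agrees with the closed form
#' [threshold_step()] applied piecewise, and the threshold never overshoots
#' the force within a constant segment.
#'
#' @param stim A [new_stimulus()] trace. The force column is used as-is;
#'   any sign convention is applied by the caller (see
#'   [simulate_response()]).
#' @param params A [cs_params()] object (only `b` and `tau` are used).
#' @param x0 Initial threshold, mN.
#' @param control See [integrator_control()].
#' @return Numeric vector of threshold values, one per stimulus sample.
#' @export
integrate_threshold <- function(stim, params, x0 = 0,
                                control = integrator_control()) {
  stim <- validate_stimulus(stim)
  params <- as_cs_params(params)
  if (!is.finite(x0)) {
    abort("`x0` must be finite", class = "campaniform_input_error")
  }
  integrate_threshold_cpp(stim$time_s, stim$force_mN,
                          params$b, params$tau, x0,
                          control$max_frac, control$absorb_tol,
                          control$max_substeps)
}

#' Rectified discharge function
#'
#' Pointwise discharge frequency `y = max(0, a*(u - x) + c*u + d)`: an
#' adaptive (phasic) term driven by force minus dynamic threshold, a tonic
#' term proportional to force, and a constant offset, rectified at zero.
#'
#' @param u Force, mN (after any sign convention).
#' @param x Dynamic threshold, mN.
#' @param params A [cs_params()] object.
#' @return Discharge frequency in impulses s^-1 (>= 0), vectorized.
#' @export
discharge <- function(u, x, params) {
  params <- as_cs_params(params)
  pmax(0, params$a * (u - x) + params$c * u + params$d)
}

#' Simulate the receptor response to a stimulus
#'
#' Applies the subgroup's input sign to the force, integrates the dynamic
#' threshold, and evaluates the rectified discharge. Under a sustained
#' force `u` the discharge settles to `max(0, c*u + d)`.
#'
#' @param stim A [new_stimulus()] trace (applied bending force).
#' @param params A [cs_params()] object.
#' @param x0 Initial threshold in the signed input frame, mN. Use
#'   `x0 = "adapted"` to start fully adapted to the first force sample.
#' @param control See [integrator_control()].
#' @return A tibble of class `cs_response` with columns `time_s`,
#'   `force_mN` (applied force), `drive_mN` (signed model input),
#'   `threshold_mN` and `rate_hz`, carrying `params` and the stimulus
#'   protocol as attributes.
#' @examples
#' stim <- stim_ramp_hold(amplitude = 2, rise_rate = 10, hold_s = 1)
#' resp <- simulate_response(stim, cs_params(subgroup = "antagonist"))
#' @export
simulate_response <- function(stim, params, x0 = 0,
                              control = integrator_control()) {
  stim <- validate_stimulus(stim)
  params <- as_cs_params(params)
  v <- params$input_sign * stim$force_mN
  if (identical(x0, "adapted")) x0 <- v[1L]
  vstim <- new_stimulus(stim$time_s, v)
  x <- integrate_threshold(vstim, params, x0 = x0, control = control)
  y <- discharge(v, x, params)
  out <- tibble(time_s = stim$time_s, force_mN = stim$force_mN,
                drive_mN = v, threshold_mN = x, rate_hz = y)
  structure(out, params = params, protocol = attr(stim, "protocol"),
            class = c("cs_response", class(out)))
}

#' @export
print.cs_response <- function(x, ...) {
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat("<cs_response> ", p$subgroup, ", ", nrow(x), " samples, peak ",
        sprintf("%.3g", max(x$rate_hz)), " Hz\n", sep = "")
  }
  NextMethod()
}

#' Model parameters attached to a response
#' @param resp A `cs_response`.
#' @return The [cs_params()] used for the simulation (or `NULL`).
#' @export
response_params <- function(resp) {
  attr(resp, "params")
}
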