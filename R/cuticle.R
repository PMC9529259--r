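#' Viscoelastic creep under constant force
#'
#' Displacement of a standard linear solid held at constant force `F0`:
#' `disp(t) = F0 * (1/k0 + (1/k1) * (1 - exp(-t/tau_c)))` — an
#' instantaneous elastic response `F0/k0` followed by bounded, saturating
#' creep toward the equilibrium compliance `F0 * (1/k0 + 1/k1)`.
#'
#' @param F0 Held force, mN.
#' @param params A [zener_params()] object.
#' @param t Times since force onset, s (>= 0); vectorized.
#' @return Displacement in length units.
#' @export
creep_displacement <- function(F0, params, t) {
  params <- as_zener_params(params)
  if (any(t < 0)) {
    abort("`t` must be >= 0", class = "campaniform_input_error")
  }
  F0 * (1 / params$k0 + (1 / params$k1) * (1 - exp(-t / params$tau_c)))
}

#' Stress relaxation under constant displacement
#'
#' Resisting force of a standard linear solid held at constant displacement
#' `d0`: `F(t) = d0 * (k_eq + (k0 - k_eq) * exp(-t/tau_r))`, declining
#' monotonically from the instantaneous stiffness `d0*k0` to the
#' equilibrium value `d0*k_eq`.
#'
#' @param d0 Held displacement, length units.
#' @param params A [zener_params()] object.
#' @param t Times since displacement onset, s (>= 0); vectorized.
#' @return Force in mN.
#' @export
stress_relaxation <- function(d0, params, t) {
  params <- as_zener_params(params)
  if (any(t < 0)) {
    abort("`t` must be >= 0", class = "campaniform_input_error")
  }
  d0 * (params$k_eq + (params$k0 - params$k_eq) * exp(-t / params$tau_r))
}

#' Creep accumulated over hold phases of different durations
#'
#' For each hold duration `T`, the creep is the displacement gained after
#' the instantaneous elastic response:
#' `creep(T) = disp(T) - disp(0+) = (F0/k1) * (1 - exp(-T/tau_c))`. It is
#' strictly increasing in `T` and saturates at `F0/k1`.
#'
#' @param F0 Held force, mN.
#' @param params A [zener_params()] object.
#' @param durations Hold durations, s (> 0).
#' @return A tibble with columns `duration_s` and `creep_units`.
#' @export
creep_vs_duration <- function(F0, params, durations) {
  params <- as_zener_params(params)
  if (any(durations <= 0)) {
    abort("`durations` must be positive", class = "campaniform_input_error")
  }
  tibble(duration_s = as.numeric(durations),
         creep_units = (F0 / params$k1) * (1 - exp(-durations / params$tau_c)))
}

#' Displacement response to an arbitrary force history
#'
#' Convolution path for protocol simulation: the creep compliance of the
#' standard linear solid applied to a sampled force trace,
#' `disp(t) = F(t)/k0 + (1/(k1*tau_c)) * int_0^t exp(-(t-s)/tau_c) F(s) ds`.
#' The convolution is evaluated with an exponential recursion that is exact
#' for forces linear between samples, so on step inputs it reproduces
#' [creep_displacement()] to floating-point accuracy. The material starts
#' at rest (no stored viscous strain) unless `initial = "equilibrium"`.
#'
#' @param stim A [new_stimulus()] force trace.
#' @param params A [zener_params()] object.
#' @param initial `"rest"` (no viscous memory at the first sample) or
#'   `"equilibrium"` (pre-equilibrated to the first force value).
#' @return A tibble with columns `time_s`, `force_mN`,
#'   `displacement_units`.
#' @export
zener_displacement <- function(stim, params,
                               initial = c("rest", "equilibrium")) {
  stim <- validate_stimulus(stim)
  params <- as_zener_params(params)
  initial <- match.arg(initial)
  tt <- stim$time_s
  f <- stim$force_mN
  n <- length(tt)
  tau <- params$tau_c
  z <- numeric(n)  # z(t) = int_0^t exp(-(t-s)/tau) F(s) ds
  z[1] <- if (initial == "equilibrium") tau * f[1] else 0
  for (i in seq_len(n - 1L)) {
    h <- tt[i + 1L] - tt[i]
    E <- exp(-h / tau)
    m <- (f[i + 1L] - f[i]) / h
    z[i + 1L] <- z[i] * E + tau * (f[i + 1L] - f[i] * E) -
      m * tau^2 * (1 - E)
  }
  tibble(time_s = tt, force_mN = f,
         displacement_units = f / params$k0 + z / (params$k1 * tau))
}
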