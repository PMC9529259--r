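# Independent closed-form oracle for the threshold gap w = |u - x| under
# constant force, written from the separable solution of
# tau * dw/dt = -w^b (kept independent of the package's implementation).
oracle_gap <- function(w0, b, tau, t) {
  if (b == 1) {
    return(w0 * exp(-t / tau))
  }
  base <- w0^(1 - b) - (1 - b) * t / tau
  if (b < 1) {
    ifelse(base <= 0, 0, base^(1 / (1 - b)))
  } else {
    base^(1 / (1 - b))
  }
}

oracle_step_x <- function(u, x0, b, tau, t) {
  if (u == x0) return(rep(x0, length(t)))
  u - sign(u - x0) * oracle_gap(abs(u - x0), b, tau, t)
}

# constant-force stimulus of given length
const_stim <- function(level, duration_s = 1, dt = 0.001) {
  n <- round(duration_s / dt)
  new_stimulus((0:n) * dt, rep(level, n + 1))
}

# worst-case error relative to the sample value, floored at 1% of the
# trace scale so zero crossings do not inflate the ratio
rel_err <- function(got, want, floor = NULL) {
  if (is.null(floor)) floor <- 0.01 * max(abs(want))
  max(abs(got - want) / pmax(abs(want), floor))
}

# random parameter sets and protocols for property sweeps
random_params <- function(subgroup = "agonist") {
  cs_params(a = runif(1, 10, 100), b = runif(1, 0.5, 2),
            c = runif(1, 0, 20), d = runif(1, -5, 5),
            tau = runif(1, 0.05, 1), subgroup = subgroup)
}

random_protocol <- function(dt = 0.005) {
  if (runif(1) < 0.5) {
    stim_ramp_hold(amplitude = runif(1, 0.2, 3), rise_rate = runif(1, 1, 20),
                   fall_rate = runif(1, 1, 20), hold_s = runif(1, 0.1, 1),
                   baseline = runif(1, 0, 1), pre_s = 0.1, post_s = 0.1,
                   dt = dt)
  } else {
    stim_staircase(step_mN = runif(1, 0.3, 1.5), n_steps = sample(2:3, 1),
                   rate = runif(1, 2, 20), plateau_s = runif(1, 0.1, 0.4),
                   pre_s = 0.1, post_s = 0.1, dt = dt)
  }
}
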