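#' Default parameter bounds for fitting
#'
#' Generous physical ranges for the five model constants.
#'
#' @return A list with `lower` and `upper` named vectors over
#'   `(a, b, c, d, tau)`.
#' @export
fit_bounds <- function() {
  list(lower = c(a = 0, b = 0.1, c = 0, d = -100, tau = 1e-3),
       upper = c(a = 1000, b = 5, c = 1000, d = 100, tau = 100))
}

# Pooled mean squared rate error over a battery of traces.
# Works on pre-extracted signed inputs for speed inside optim().
fit_objective_fun <- function(tlist, vlist, x0list, ylist, control) {
  n_tot <- sum(lengths(ylist))
  function(theta) {
    sse <- 0
    for (i in seq_along(tlist)) {
      x <- integrate_threshold_cpp(tlist[[i]], vlist[[i]],
                                   theta[2], theta[5], x0list[[i]],
                                   control$max_frac, control$absorb_tol,
                                   control$max_substeps)
      yhat <- pmax(0, theta[1] * (vlist[[i]] - x) +
                     theta[3] * vlist[[i]] + theta[4])
      sse <- sse + sum((yhat - ylist[[i]])^2)
    }
    mse <- sse / n_tot
    if (!is.finite(mse)) return(1e12)
    mse
  }
}

# Normalize fitting inputs into aligned lists of traces and observations.
fit_prepare <- function(stim, observed_rate, params, x0) {
  if (inherits(stim, "cs_stimulus")) stim <- list(stim)
  if (!is.list(observed_rate)) observed_rate <- list(observed_rate)
  if (length(stim) != length(observed_rate)) {
    abort("`stim` and `observed_rate` must have the same length",
          class = "campaniform_input_error")
  }
  if (length(x0) == 1L) x0 <- rep(list(x0), length(stim))
  vlist <- list()
  tlist <- list()
  x0list <- list()
  for (i in seq_along(stim)) {
    s <- validate_stimulus(stim[[i]])
    if (length(observed_rate[[i]]) != nrow(s)) {
      abort("observed rate length must match its stimulus",
            class = "campaniform_input_error")
    }
    v <- params$input_sign * s$force_mN
    x0i <- x0[[i]]
    if (identical(x0i, "adapted")) x0i <- v[1L]
    tlist[[i]] <- s$time_s
    vlist[[i]] <- v
    x0list[[i]] <- x0i
  }
  list(t = tlist, v = vlist, x0 = x0list,
       y = purrr::map(observed_rate, as.numeric))
}

#' Estimate model parameters from paired stimulus/rate traces
#'
#' Minimizes the mean squared error between the simulated and observed
#' discharge rate over `(a, b, c, d, tau)` within box bounds, using
#' box-constrained quasi-Newton local searches (`stats::optim`,
#' `"L-BFGS-B"`) started from `init` and from seeded random perturbations
#' of it (deterministic multi-start). The subgroup and input sign are taken
#' from `init` and are not fitted.
#'
#' @param stim A `cs_stimulus` or list of them (a protocol battery).
#' @param observed_rate Numeric vector (or list, aligned with `stim`) of
#'   observed discharge rates at the stimulus samples, Hz.
#' @param init A [cs_params()] starting point; must lie within `bounds`.
#' @param bounds See [fit_bounds()].
#' @param seed Integer seed for the restart perturbations.
#' @param restarts Number of local searches (>= 1); the first starts at
#'   `init`.
#' @param x0 Initial threshold per trace (scalar, list, or `"adapted"`).
#' @param control Integrator settings, see [integrator_control()].
#' @return An object of class `cs_fit` with the estimated [cs_params()],
#'   the objective value (Hz^2), convergence flag, per-restart log, and
#'   seed. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' stim <- stim_ramp_hold(amplitude = 2, rise_rate = 10, hold_s = 1,
#'                        dt = 0.005)
#' truth <- cs_params()
#' y <- simulate_response(stim, truth)$rate_hz
#' fit_params(stim, y, init = truth, restarts = 1)
#' @export
fit_params <- function(stim, observed_rate, init = cs_params(),
                       bounds = fit_bounds(), seed = 1, restarts = 8,
                       x0 = 0, control = integrator_control()) {
  init <- as_cs_params(init)
  th0 <- c(a = init$a, b = init$b, c = init$c, d = init$d, tau = init$tau)
  if (any(th0 < bounds$lower) || any(th0 > bounds$upper)) {
    abort("`init` must lie within `bounds`",
          class = "campaniform_parameter_error")
  }
  dat <- fit_prepare(stim, observed_rate, init, x0)
  obj <- fit_objective_fun(dat$t, dat$v, dat$x0, dat$y, control)
  f0 <- obj(th0)
  if (!is.finite(f0) || f0 >= 1e12) {
    abort(paste0("objective is not finite at the initial parameters: ",
                 paste(signif(th0, 4), collapse = ", ")),
          class = "campaniform_numerical_error")
  }
  starts <- list(th0)
  if (restarts > 1L) {
    withr::local_seed(seed)
    for (k in seq_len(restarts - 1L)) {
      s <- th0
      s[c("a", "c", "tau")] <- s[c("a", "c", "tau")] * exp(rnorm(3, 0, 0.3))
      s["b"] <- s["b"] * exp(rnorm(1, 0, 0.15))
      s["d"] <- s["d"] + rnorm(1, 0, 0.3 * max(1, abs(s["d"])))
      starts[[k + 1L]] <- pmin(pmax(s, bounds$lower), bounds$upper)
    }
  }
  runs <- purrr::imap(starts, function(s, k) {
    res <- optim(s, obj, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 300))
    tibble(restart = k, objective = res$value,
           convergence = res$convergence,
           par = list(res$par))
  })
  runs <- dplyr::bind_rows(runs)
  best <- runs[which.min(runs$objective), ]
  bp <- best$par[[1]]
  est <- cs_params(a = bp["a"], b = bp["b"], c = bp["c"], d = bp["d"],
                   tau = bp["tau"], subgroup = init$subgroup,
                   input_sign = init$input_sign)
  structure(
    list(params = est, objective = best$objective,
         convergence = best$convergence == 0,
         restarts = dplyr::select(runs, "restart", "objective",
                                  "convergence"),
         n_restarts = length(starts), seed = seed,
         n_obs = sum(lengths(dat$y))),
    class = "cs_fit"
  )
}

#' @export
print.cs_fit <- function(x, ...) {
  cat("<cs_fit> objective (MSE) =", signif(x$objective, 5), "Hz^2,",
      x$n_restarts, "restart(s),",
      if (x$convergence) "converged" else "not converged", "\n")
  print(x$params)
  invisible(x)
}

#' Tidy a fitted parameter set
#' @param x A `cs_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.cs_fit <- function(x, ...) {
  p <- x$params
  tibble(term = c("a", "b", "c", "d", "tau"),
         estimate = c(p$a, p$b, p$c, p$d, p$tau))
}

#' One-row summary of a fit
#' @param x A `cs_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the objective, convergence flag, restart
#'   count, number of observations, and seed.
#' @export
glance.cs_fit <- function(x, ...) {
  tibble(objective = x$objective, converged = x$convergence,
         n_restarts = x$n_restarts, n_obs = x$n_obs, seed = x$seed)
}

#' Serialize a fit to JSON
#' @param fit A `cs_fit` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cs_fit"))
  jsonlite::write_json(
    list(params = unclass(fit$params), objective = fit$objective,
         converged = fit$convergence, n_restarts = fit$n_restarts,
         seed = fit$seed, n_obs = fit$n_obs,
         restarts = fit$restarts),
    path, auto_unbox = TRUE, digits = I(17), dataframe = "rows")
  invisible(path)
}

#' One-dimensional objective profile
#'
#' Slice of the mean-squared-error objective along one parameter axis,
#' holding the other parameters fixed at `params`.
#'
#' @inheritParams fit_params
#' @param params The [cs_params()] around which to profile.
#' @param axis One of `"a"`, `"b"`, `"c"`, `"d"`, `"tau"`.
#' @param grid Values of the profiled parameter.
#' @return A tibble with columns `value` and `objective`.
#' @export
profile_objective <- function(stim, observed_rate, params, axis, grid,
                              x0 = 0, control = integrator_control()) {
  params <- as_cs_params(params)
  axis <- match.arg(axis, c("a", "b", "c", "d", "tau"))
  dat <- fit_prepare(stim, observed_rate, params, x0)
  obj <- fit_objective_fun(dat$t, dat$v, dat$x0, dat$y, control)
  th <- c(a = params$a, b = params$b, c = params$c, d = params$d,
          tau = params$tau)
  vals <- purrr::map_dbl(grid, function(g) {
    th[axis] <- g
    obj(th)
  })
  tibble(value = as.numeric(grid), objective = vals)
}

#' Joint protocol battery for parameter estimation
#'
#' A compact battery combining an offset series, a duration series and a
#' rate series. Jointly these resolve all five model constants: the offset
#' series separates the tonic gain `c` from the constant `d`, the duration
#' series pins the threshold dynamics (`b`, `tau`), and the rate series
#' constrains the phasic gain `a`. A single ramp, by contrast, leaves a
#' near-flat valley along the `c`/`d` trade-off.
#'
#' @param dt Sample interval, s.
#' @return A list of `cs_stimulus` traces.
#' @export
protocol_battery <- function(dt = 0.002) {
  c(
    purrr::map(c(0, 0.4, 0.8), function(off) {
      stim_ramp_hold(amplitude = 0.85, rise_rate = 8.5, hold_s = 2,
                     baseline = off, pre_s = 1, post_s = 1, dt = dt)
    }),
    stim_duration_series(durations = c(0.25, 1, 4), amplitude = 1,
                         rate = 10, pre_s = 0.3, post_s = 0.3, dt = dt),
    stim_rate_series(rates = c(1, 3, 10), amplitude = 1, hold_s = 1,
                     pre_s = 0.3, post_s = 0.3, dt = dt)
  )
}

#' Seeded parameter-recovery study
#'
#' Simulates the joint [protocol_battery()] under known parameters, adds
#' Gaussian rate noise scaled to the battery's peak rate, perturbs the
#' starting parameters, refits, and reports per-trial relative errors.
#'
#' @param truth The generating [cs_params()].
#' @param n_trials Number of seeded trials.
#' @param noise_frac Noise standard deviation as a fraction of the peak
#'   noiseless rate.
#' @param seed Master seed; per-trial seeds are derived from it.
#' @param restarts Local searches per fit (see [fit_params()]).
#' @param dt Battery sample interval, s.
#' @param init_jitter Log-scale s.d. of the multiplicative perturbation
#'   applied to the true parameters to form each trial's starting point
#'   (about +/-30% at the default 0.25).
#' @return A tibble with columns `trial`, `term`, `truth`, `estimate`,
#'   `rel_error`, `objective`.
#' @export
fit_recovery_study <- function(truth = cs_params(),
                               n_trials = 20, noise_frac = 0.05, seed = 1,
                               restarts = 2, dt = 0.002,
                               init_jitter = 0.25) {
  battery <- protocol_battery(dt = dt)
  clean <- purrr::map(battery, function(s) {
    simulate_response(s, truth, x0 = "adapted")$rate_hz
  })
  peak <- max(unlist(clean))
  tr <- c(a = truth$a, b = truth$b, c = truth$c, d = truth$d,
          tau = truth$tau)
  trial_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max,
                                             n_trials))
  purrr::map_dfr(seq_len(n_trials), function(k) {
    withr::local_seed(trial_seeds[k])
    ys <- purrr::map(clean, function(y) {
      y + rnorm(length(y), 0, noise_frac * peak)
    })
    init <- cs_params(
      a = tr["a"] * exp(rnorm(1, 0, init_jitter)),
      b = tr["b"] * exp(rnorm(1, 0, init_jitter * 0.6)),
      c = tr["c"] * exp(rnorm(1, 0, init_jitter)),
      d = tr["d"] + rnorm(1, 0, 0.3 * max(1, abs(tr["d"]))),
      tau = tr["tau"] * exp(rnorm(1, 0, init_jitter)),
      subgroup = truth$subgroup, input_sign = truth$input_sign)
    fit <- fit_params(battery, ys, init = init, seed = trial_seeds[k],
                      restarts = restarts, x0 = "adapted")
    est <- tidy(fit)
    tibble(trial = k, term = est$term, truth = unname(tr[est$term]),
           estimate = est$estimate,
           rel_error = abs(est$estimate - tr[est$term]) / abs(tr[est$term]),
           objective = fit$objective)
  })
}
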