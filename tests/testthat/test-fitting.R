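small_battery <- function(dt = 0.004) {
  c(
    lapply(c(0, 0.5), function(off) {
      stim_ramp_hold(amplitude = 0.85, rise_rate = 8.5, hold_s = 1,
                     baseline = off, pre_s = 0.3, post_s = 0.3, dt = dt)
    }),
    stim_duration_series(durations = c(0.25, 2), amplitude = 1, rate = 10,
                         pre_s = 0.2, post_s = 0.2, dt = dt),
    stim_rate_series(rates = c(2, 10), amplitude = 1, hold_s = 0.5,
                     pre_s = 0.2, post_s = 0.2, dt = dt)
  )
}

test_that("the objective vanishes at the generating parameters", {
  truth <- cs_params()
  battery <- small_battery()
  ys <- lapply(battery, function(s) {
    simulate_response(s, truth, x0 = "adapted")$rate_hz
  })
  fit <- fit_params(battery, ys, init = truth, restarts = 1,
                    x0 = "adapted")
  expect_lt(fit$objective, 1e-8)
  est <- tidy(fit)$estimate
  expect_equal(est, c(truth$a, truth$b, truth$c, truth$d, truth$tau),
               tolerance = 1e-3)
  g <- glance(fit)
  expect_equal(g$n_restarts, 1)
  expect_true(g$n_obs > 0)
})

test_that("noiseless recovery from a perturbed start is near-exact", {
  truth <- cs_params()
  battery <- small_battery()
  ys <- lapply(battery, function(s) {
    simulate_response(s, truth, x0 = "adapted")$rate_hz
  })
  init <- cs_params(a = truth$a * 1.3, b = truth$b * 0.8,
                    c = truth$c * 0.7, d = truth$d * 1.3,
                    tau = truth$tau * 1.25)
  fit <- fit_params(battery, ys, init = init, seed = 5, restarts = 2,
                    x0 = "adapted")
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  tr <- c(a = truth$a, b = truth$b, c = truth$c, d = truth$d,
          tau = truth$tau)
  for (nm in c("a", "c", "d", "tau")) {
    expect_lt(abs(est[nm] - tr[nm]) / abs(tr[nm]), 0.01)
  }
})

test_that("objective profiles dip at the truth and respect symmetry", {
  truth <- cs_params()
  stim <- small_battery()[[1]]
  y <- simulate_response(stim, truth, x0 = "adapted")$rate_hz
  prof <- profile_objective(stim, y, truth, axis = "tau",
                            grid = seq(0.2, 0.6, by = 0.05),
                            x0 = "adapted")
  expect_equal(prof$value[which.min(prof$objective)], 0.4)
  # widening the grid can only lower (or keep) the minimum
  wide <- profile_objective(stim, y, truth, axis = "tau",
                            grid = seq(0.1, 0.9, by = 0.05),
                            x0 = "adapted")
  expect_lte(min(wide$objective), min(prof$objective))
  # sign-flipped stimulus with flipped input sign gives the same objective
  ant <- cs_params(a = truth$a, b = truth$b, c = truth$c, d = truth$d,
                   tau = truth$tau, subgroup = "antagonist")
  neg <- new_stimulus(stim$time_s, -stim$force_mN)
  prof_neg <- profile_objective(neg, y, ant, axis = "tau",
                                grid = seq(0.2, 0.6, by = 0.05),
                                x0 = "adapted")
  expect_equal(prof_neg$objective, prof$objective, tolerance = 1e-12)
})

test_that("a single ramp leaves the tonic gain and offset entangled", {
  truth <- cs_params()
  ramp <- stim_ramp_hold(amplitude = 1, rise_rate = 10, hold_s = 1,
                         pre_s = 0.2, post_s = 0.2, dt = 0.004)
  y1 <- simulate_response(ramp, truth, x0 = "adapted")$rate_hz
  battery <- small_battery()
  yb <- lapply(battery, function(s) {
    simulate_response(s, truth, x0 = "adapted")$rate_hz
  })
  # move along the c/d trade-off direction (c + delta, d - delta * u_hold)
  delta <- 2
  shifted <- cs_params(a = truth$a, b = truth$b, c = truth$c + delta,
                       d = truth$d - delta * 1, tau = truth$tau)
  obj_single <- profile_objective(ramp, y1, shifted, axis = "a",
                                  grid = truth$a, x0 = "adapted")$objective
  obj_battery <- sum(vapply(seq_along(battery), function(i) {
    profile_objective(battery[[i]], yb[[i]], shifted, axis = "a",
                      grid = truth$a, x0 = "adapted")$objective
  }, numeric(1)))
  # the single-ramp objective barely notices the shift that the
  # multi-offset battery rejects
  expect_lt(obj_single, 0.1 * obj_battery)
})

test_that("fits serialize and invalid setups error early", {
  truth <- cs_params()
  stim <- stim_ramp_hold(amplitude = 1, rise_rate = 10, hold_s = 0.5,
                         dt = 0.005)
  y <- simulate_response(stim, truth)$rate_hz
  fit <- fit_params(stim, y, init = truth, restarts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  blob <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(blob$params$tau, tidy(fit)$estimate[5], tolerance = 1e-12)
  out <- cs_params(tau = 200, subgroup = "agonist")
  expect_error(fit_params(stim, y, init = out),
               class = "campaniform_parameter_error")
  expect_error(fit_params(stim, y[-1], init = truth),
               class = "campaniform_input_error")
})
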