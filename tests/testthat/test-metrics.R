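test_that("force rate is the unsmoothed finite difference", {
  st <- stim_ramp_hold(amplitude = 5, rise_rate = 10, hold_s = 0.5)
  fr <- force_rate(st)
  p <- stim_protocol(st)
  rise <- p$epochs[p$epochs$epoch == "rise", ]
  interior <- fr$time_s > rise$t_start + 0.002 &
    fr$time_s < rise$t_end - 0.002
  expect_equal(unique(round(fr$rate_mN_s[interior], 6)), 10)
  flat <- stim_constant(1, duration_s = 0.5)
  expect_true(all(force_rate(flat)$rate_mN_s == 0))
  expect_error(force_rate(new_stimulus(c(0, 0.001), c(0, 0))),
               class = "campaniform_input_error")
})

test_that("epoch segmentation recovers the generating protocol", {
  st <- stim_ramp_hold(amplitude = 2, rise_rate = 10, hold_s = 1)
  ep <- segment_epochs(st)
  expect_equal(sum(ep$epoch == "rise"), 1)
  expect_equal(sum(ep$epoch == "fall"), 1)
  # boundaries match the protocol truth to one sample
  truth <- stim_protocol(st)$epochs
  truth_rise <- truth[truth$epoch == "rise", ]
  got_rise <- ep[ep$epoch == "rise", ]
  expect_lt(abs(got_rise$t_start - truth_rise$t_start), 2 * stim_dt(st))
  expect_lt(abs(got_rise$t_end - truth_rise$t_end), 2 * stim_dt(st))

  flat <- stim_constant(1, duration_s = 0.5)
  epf <- segment_epochs(flat, rate_eps = 0.1)
  expect_equal(nrow(epf), 1)
  expect_equal(epf$epoch, "hold")

  stair <- stim_staircase(n_steps = 5, plateau_s = 0.5)
  eps <- segment_epochs(stair)
  expect_equal(sum(eps$epoch == "rise"), 5)
  expect_equal(sum(eps$epoch == "fall"), 5)
})

test_that("off-response summarizes the fall epoch", {
  st <- stim_ramp_hold(amplitude = 1, rise_rate = 10, hold_s = 0.5)
  ep <- segment_epochs(st)
  fall <- ep[ep$epoch == "fall", ]
  # rectangular synthetic rate: mean = peak inside the fall epoch
  y <- rep(0, nrow(st))
  y[fall$start:fall$end] <- 10
  resp <- structure(tibble::tibble(time_s = st$time_s,
                                   force_mN = st$force_mN, rate_hz = y),
                    class = c("cs_response", class(tibble::tibble())))
  off <- off_response(resp, ep)
  expect_equal(off$mean_hz, 10)
  expect_equal(off$peak_hz, 10)
  # silent fall epoch gives (0, 0)
  resp$rate_hz <- 0
  off0 <- off_response(resp, ep)
  expect_equal(c(off0$mean_hz, off0$peak_hz), c(0, 0))
  flat <- stim_constant(1, 0.5)
  respf <- simulate_response(flat, cs_params())
  expect_error(off_response(respf, segment_epochs(flat, rate_eps = 1)),
               class = "campaniform_metric_error")
})

test_that("relative gain normalizes to the minimal offset", {
  g <- relative_gain(c(60, 30, 15), c(0, 2.9, 5.4))
  expect_equal(g$gain, c(1, 0.5, 0.25))
  expect_equal(relative_gain(42, 1)$gain, 1)
  # scale invariance
  g2 <- relative_gain(7 * c(60, 30, 15), c(0, 2.9, 5.4))
  expect_equal(g2$gain, g$gain)
  expect_error(relative_gain(c(0, 1), c(0, 1)),
               class = "campaniform_metric_error")
})

test_that("slope fits agree with the normal equations", {
  f <- slope_fit(c(0, 1, 2), c(10, 8, 6))
  expect_equal(f$slope, -2)
  expect_equal(f$r_squared, 1)
  expect_equal(slope_fit(1:5, rep(3, 5))$slope, 0)
  # independent normal-equations oracle on a random cloud
  withr::with_seed(7, {
    x <- runif(20)
    y <- 2 - 3 * x + rnorm(20, 0, 0.3)
  })
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  f2 <- slope_fit(x, y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  expect_error(slope_fit(rep(1, 5), 1:5),
               class = "campaniform_metric_error")
})

test_that("threshold creep matches the closed form and saturates", {
  # piecewise-constant hold with b = 1: creep over the hold is the
  # closed-form gap difference
  p <- cs_params(b = 1, tau = 0.4)
  st <- stim_ramp_hold(amplitude = 2, rise_rate = 10, hold_s = 1)
  resp <- simulate_response(st, p)
  ep <- segment_epochs(resp)
  hold <- ep[ep$epoch == "hold" &
               c("", head(ep$epoch, -1)) == "rise", ][1, ]
  w0 <- 2 - resp$threshold_mN[hold$start]
  t_hold <- resp$time_s[hold$end] - resp$time_s[hold$start]
  want <- w0 * (1 - exp(-t_hold / 0.4))
  expect_equal(threshold_creep(resp, ep), want, tolerance = 1e-4)
  # a fast threshold equilibrates within the ramp: negligible creep
  fast <- simulate_response(st, cs_params(b = 1, tau = 0.001))
  expect_lt(abs(threshold_creep(fast)), 0.02)
  # creep grows with hold duration
  dx <- vapply(stim_duration_series(durations = c(0.5, 1, 2)),
               function(s) threshold_creep(simulate_response(s, cs_params())),
               numeric(1))
  expect_true(all(diff(dx) > 0))
})

test_that("rate-sensitivity curves are monotone in the ramp rate", {
  stims <- stim_rate_series(rates = c(1, 2, 4, 8), amplitude = 2,
                            hold_s = 1)
  for (sg in c("agonist", "antagonist")) {
    resps <- lapply(stims, function(s) {
      simulate_response(s, cs_params(subgroup = sg))
    })
    cur <- rate_sensitivity_curve(resps)
    expect_equal(nrow(cur), 4)
    expect_true(all(diff(cur$peak_hz) > 0))
  }
  one <- rate_sensitivity_curve(
    simulate_response(stims[[1]], cs_params()))
  expect_equal(nrow(one), 1)
})
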