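test_that("ramp-and-hold traces have exact trapezoidal geometry", {
  st <- stim_ramp_hold(amplitude = 0.85, rise_rate = 8.5, hold_s = 1,
                       baseline = 0)
  p <- stim_protocol(st)
  # ramp duration follows from amplitude and rate
  rise <- p$epochs[p$epochs$epoch == "rise", ]
  expect_equal(rise$t_end - rise$t_start, 0.1)
  # plateau samples sit exactly at baseline + amplitude
  plateau <- st$force_mN[st$time_s > rise$t_end &
                           st$time_s < rise$t_end + 1]
  expect_true(all(plateau == 0.85))
  # starts and ends at baseline
  expect_equal(st$force_mN[1], 0)
  expect_equal(st$force_mN[nrow(st)], 0)
  # no discontinuity beyond rate * dt
  expect_lte(max(abs(diff(st$force_mN))), 8.5 * 0.001 + 1e-12)
  # zero amplitude degenerates to a constant trace
  flat <- stim_ramp_hold(amplitude = 0, rise_rate = 8.5, hold_s = 1,
                         baseline = 0.5)
  expect_true(all(flat$force_mN == 0.5))
  expect_error(stim_ramp_hold(amplitude = -1, rise_rate = 1),
               class = "campaniform_input_error")
})

test_that("offset loads shift the trapezoid vertically without reshaping", {
  offs <- c(0, 2.9, 5.4)
  traces <- lapply(offs, function(o) {
    stim_ramp_hold(amplitude = 0.85, rise_rate = 8.5, hold_s = 1,
                   baseline = o)
  })
  for (i in 2:3) {
    expect_equal(traces[[i]]$force_mN - offs[i], traces[[1]]$force_mN)
    expect_equal(traces[[i]]$time_s, traces[[1]]$time_s)
  }
})

test_that("staircase traces climb and descend through the step levels", {
  st <- stim_staircase(step_mN = 1, n_steps = 5, rate = 10, plateau_s = 0.5)
  p <- stim_protocol(st)
  holds <- p$epochs[p$epochs$epoch == "hold", ]
  # plateau levels between the padding holds: 1..5 then 4..1
  mids <- holds[-c(1, nrow(holds)), ]
  lvl <- vapply(seq_len(nrow(mids)), function(i) {
    st$force_mN[which(st$time_s >= mids$t_start[i] &
                        st$time_s <= mids$t_end[i])][2]
  }, numeric(1))
  expect_equal(lvl, c(1:5, 4:1))
  expect_equal(max(st$force_mN) - min(st$force_mN), 5)
  expect_equal(sum(p$epochs$epoch == "rise"), 5)
  expect_equal(sum(p$epochs$epoch == "fall"), 5)
  # a single step is the same waveform as a ramp-and-hold
  one <- stim_staircase(step_mN = 2, n_steps = 1, rate = 10,
                        plateau_s = 1, pre_s = 0.5, post_s = 0.5)
  rh <- stim_ramp_hold(amplitude = 2, rise_rate = 10, hold_s = 1,
                       pre_s = 0.5, post_s = 0.5)
  expect_equal(one$force_mN, rh$force_mN)
})

test_that("duration series vary only the hold phase", {
  durs <- c(0.25, 0.5, 1, 2, 4)
  traces <- stim_duration_series(durations = durs, amplitude = 2,
                                 rate = 10)
  expect_length(traces, 5)
  rise_end <- stim_protocol(traces[[1]])$epochs
  rise_end <- rise_end[rise_end$epoch == "rise", ]$t_end
  n_rise <- sum(traces[[1]]$time_s <= rise_end)
  for (tr in traces) {
    expect_equal(tr$force_mN[seq_len(n_rise)],
                 traces[[1]]$force_mN[seq_len(n_rise)])
    expect_equal(max(tr$force_mN), 2)
  }
  expect_error(stim_duration_series(durations = c(1, 0.5)),
               class = "campaniform_input_error")
  single <- stim_duration_series(durations = 1, amplitude = 2, rate = 10)
  rh <- stim_ramp_hold(amplitude = 2, rise_rate = 10, hold_s = 1)
  expect_equal(single[[1]]$force_mN, rh$force_mN)
})

test_that("rate series sweep the ramp rate at fixed amplitude", {
  rates <- c(1, 3, 10, 30, 100)
  traces <- stim_rate_series(rates = rates, amplitude = 1, hold_s = 0.5)
  for (i in seq_along(rates)) {
    p <- stim_protocol(traces[[i]])
    rise <- p$epochs[p$epochs$epoch == "rise", ]
    expect_equal(rise$t_end - rise$t_start, 1 / rates[i])
    expect_equal(max(traces[[i]]$force_mN), 1)
    # measured dF/dt on the ramp recovers the requested rate
    fr <- force_rate(traces[[i]])
    on_ramp <- fr$time_s > rise$t_start + 0.002 &
      fr$time_s < rise$t_end - 0.002
    if (any(on_ramp)) {
      expect_equal(median(fr$rate_mN_s[on_ramp]), rates[i],
                   tolerance = 1e-6)
    }
  }
  expect_error(stim_rate_series(rates = c(1, -1)),
               class = "campaniform_input_error")
})

test_that("generated traces are uniformly sampled and carry their spec", {
  st <- stim_ramp_hold(amplitude = 1, rise_rate = 5, hold_s = 0.7,
                       baseline = 0.3, dt = 0.002)
  expect_equal(stim_dt(st), 0.002)
  expect_true(all(diff(st$time_s) > 0))
  p <- stim_protocol(st)
  expect_equal(p$kind, "ramp_hold")
  expect_equal(p$amplitude, 1)
  expect_equal(p$rise_rate, 5)
  expect_equal(p$hold_s, 0.7)
  expect_equal(p$baseline, 0.3)
  expect_error(new_stimulus(c(0, 1, 1.5), c(0, 0, 0)),
               class = "campaniform_input_error")
  expect_error(new_stimulus(c(0, 1, 0.5), c(0, 0, 0)),
               class = "campaniform_input_error")
})
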