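test_that("velocity estimator handles flat, linear and smooth inputs", {
  flat <- data.frame(trial_id = 1, t_ms = 0:100, x_deg = 1.5, y_deg = -0.5)
  expect_equal(compute_velocity(flat), rep(0, 101))
  # pure horizontal ramp at 10 deg/s
  ramp <- data.frame(trial_id = 1, t_ms = 0:100, x_deg = 0.01 * (0:100),
                     y_deg = 0)
  v <- compute_velocity(ramp, smoothing_halfwidth = 0)
  expect_equal(v[2:100], rep(10, 99))
  # raised-cosine saccade: peak speed equals the analytic 2A/D maximum
  tr <- make_saccade_trace(amplitude = 7, duration = 40, onset = 500)
  v <- compute_velocity(tr, smoothing_halfwidth = 0)
  expect_equal(max(v), 2 * 7 / 0.040, tolerance = 0.01)
  expect_error(compute_velocity(flat[1:2, ]), "3 samples")
  gap <- data.frame(trial_id = 1, t_ms = c(0:10, 12:20), x_deg = 0, y_deg = 0)
  expect_error(compute_velocity(gap), "gap|uniform")
})

test_that("threshold detector finds pulses at their crossing samples", {
  tr <- make_pulse_trace(speed = 100, from = 100, to = 140)
  ev <- detect_saccades(tr, threshold = 50, smoothing_halfwidth = 0)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset - 100), 1)
  expect_lte(abs(ev$offset - 140), 1)
  expect_equal(ev$peak_velocity, 100)
  # nothing crosses: flat trace, or threshold above the peak
  flat <- data.frame(trial_id = 1, t_ms = 0:50, x_deg = 0, y_deg = 0)
  expect_equal(nrow(detect_saccades(flat)), 0)
  expect_equal(nrow(detect_saccades(tr, threshold = 150,
                                    smoothing_halfwidth = 0)), 0)
  expect_error(detect_saccades(tr, threshold = -1), "positive")
})

test_that("detector recall: onsets/offsets within 2 samples of ground truth", {
  cfg <- tiny_scenario(20, seed = 9L, fixation_noise_sd = 0.001,
                       glissade = c(probability = 0, amplitude = 0.5,
                                    duration = 20))
  set.seed(9)
  trials <- sample_trial_schedule(cfg)
  truth <- simulate_truth(trials, cfg)
  trials <- sample_behavior(trials, truth, cfg)
  for (i in seq_len(nrow(trials))) {
    tr <- synth_eye_trace(trials[i, ], truth[i, ], cfg)
    ev <- detect_saccades(tr, threshold = 5)
    ev <- ev[ev$amplitude >= 1, ]
    expect_equal(nrow(ev), 1)
    expect_lte(abs(ev$onset - truth$onset_true[i]), 2)
    expect_lte(abs(ev$offset - truth$offset_true[i]), 2)
  }
})

test_that("raising the threshold never adds events or lengthens them", {
  set.seed(42)
  for (rep in 1:10) {
    tr <- make_saccade_trace(amplitude = runif(1, 3, 9),
                             duration = sample(30:60, 1), onset = 400,
                             noise = 0.02, glissade_amp = 0.4, seed = rep)
    thresholds <- c(20, 35, 50, 80)
    evs <- lapply(thresholds, function(th)
      detect_saccades(tr, threshold = th, min_duration = 5))
    n_ev <- vapply(evs, nrow, 0L)
    expect_true(all(diff(n_ev) <= 0))
    durs <- vapply(evs, function(e)
      if (nrow(e)) max(e$offset - e$onset) else 0, 0)
    expect_true(all(diff(durs) <= 0))
  }
})

test_that("glissades stay out at a high threshold and merge at a low one", {
  tr <- make_saccade_trace(amplitude = 7, duration = 40, onset = 500,
                           glissade_amp = 0.5, glissade_dur = 20)
  lag50 <- crossing_lag(7, 40, 50)
  hi <- detect_saccades(tr, threshold = 50)
  hi <- hi[hi$amplitude >= 1, ]
  # offset near the main profile's crossing; the 50 deg/s-peak glissade
  # neither extends it nor forms its own event
  expect_equal(nrow(detect_saccades(tr, threshold = 50)), 1)
  expect_lte(abs(hi$offset - (540 - lag50)), 2)
  # threshold below the glissade peak, small gaps merged: offset moves later
  lo <- detect_saccades(tr, threshold = 30, min_duration = 5, min_gap = 10)
  expect_equal(nrow(lo), 1)
  expect_gt(lo$offset, hi$offset + 10)
  # without merging the glissade shows up as a separate small event
  lo2 <- detect_saccades(tr, threshold = 30, min_duration = 5)
  expect_equal(nrow(lo2), 2)
  expect_lt(lo2$amplitude[2], 1)
})

test_that("fixation windows: fixed-center and median rules", {
  tr <- data.frame(trial_id = 1, t_ms = 0:200, x_deg = 0, y_deg = 0)
  expect_true(fixation_ok(tr, c(0, 0), 2, c(0, 201))$ok)
  tr2 <- tr; tr2$x_deg[100] <- 2.5
  res <- fixation_ok(tr2, c(0, 0), 2, c(0, 201))
  expect_false(res$ok)
  expect_equal(res$first_violation, 99)   # t_ms of the displaced sample
  # nested windows: the 0.5 median rule is at least as strict on these data
  expect_false(fixation_ok_median(tr2, 0.5, c(0, 201))$ok)
  # constant trace passes the median rule for any positive radius
  expect_true(fixation_ok_median(tr, 1e-6, c(0, 201))$ok)
  # 1.2 deg linear drift: max deviation from the median is 0.6
  drift <- data.frame(trial_id = 1, t_ms = 0:200, x_deg = seq(0, 1.2, length.out = 201),
                      y_deg = 0)
  r <- fixation_ok_median(drift, 0.5, c(0, 201))
  expect_false(r$ok)
  expect_equal(r$max_deviation, 0.6)
  expect_true(fixation_ok_median(drift, 2, c(0, 201))$ok)
  expect_error(fixation_ok(tr, c(0, 0), 2, c(100, 100)), "empty")
})
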