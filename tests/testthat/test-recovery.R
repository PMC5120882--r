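test_that("binning is half-open, anchored at the span edge, and counts right", {
  b <- bin_performance(c(5, 15, 25), c(TRUE, FALSE, TRUE), 10, c(0, 30))
  expect_equal(b$bin_start, c(0, 10, 20))
  expect_equal(b$n, c(1, 1, 1))
  expect_equal(b$rate, c(1, 0, 1))
  expect_true(all(b$lo <= b$rate & b$rate <= b$hi))
  # a value exactly on an edge goes to the right-hand bin
  b2 <- bin_performance(10, TRUE, 10, c(0, 30))
  expect_equal(b2$n, c(0, 1, 0))
  expect_true(is.na(b2$rate[1]))        # empty bins have undefined rate
  expect_equal(sum(b2$n), 1)
  expect_error(bin_performance(1, TRUE, 0, c(0, 10)), "positive")
  expect_error(bin_performance(1, TRUE, 10, c(30, 0)), "reversed")
})

test_that("bin totals conserve the included trials within the span", {
  set.seed(8)
  t_rel <- runif(500, -200, 400)
  hit <- runif(500) < 0.8
  b <- bin_performance(t_rel, hit, 20, c(-200, 400))
  expect_equal(sum(b$n), 500)
  expect_equal(sum(b$hits), sum(hit))
})

test_that("80%-of-baseline interpolation reproduces the arithmetic", {
  b <- structure(data.frame(bin_start = c(0, 20), bin_mid = c(10, 30),
                            n = c(50, 50), hits = c(20, 50),
                            rate = c(0.4, 1), lo = 0, hi = 1),
                 class = c("binned_performance", "data.frame"))
  expect_equal(recovery_interp80(b, 1), 10 + 20 * (0.8 - 0.4) / (1 - 0.4),
               tolerance = 1e-9)  # 23.33 ms
  # first bin already above criterion: its center, no extrapolation
  b$rate <- c(0.9, 1); b$hits <- c(45, 50)
  expect_equal(recovery_interp80(b, 1), 10)
  b$rate <- c(0.1, 0.2); b$hits <- c(5, 10)
  expect_warning(out <- recovery_interp80(b, 1), "never reaches")
  expect_true(is.na(out))
})

test_that("recovery estimator handles the degenerate extremes", {
  set.seed(2)
  t_rel <- runif(4000, 0, 500)
  # all hits: the first bin is already indistinguishable from baseline
  rec <- estimate_recovery(t_rel, rep(TRUE, 4000))
  expect_equal(rec$recovery_time, 0)
  expect_equal(rec$status, "recovered")
  # total suppression in 0-100, perfect baseline: never recovers in-window
  hit <- t_rel >= 100
  rec2 <- estimate_recovery(t_rel, hit)
  expect_true(is.na(rec2$recovery_time))
  expect_equal(rec2$status, "not recovered")
  expect_true(all(rec2$per_bin$significant))
  # p-values live in (0, 1] and the trail covers the whole test window
  expect_true(all(rec2$per_bin$p_value > 0 & rec2$per_bin$p_value <= 1))
  expect_equal(rec2$per_bin$bin_start, seq(0, 90, 10))
  expect_error(estimate_recovery(runif(10, 0, 50), rep(TRUE, 10)),
               "empty baseline")
})

test_that("recovery time is monotone in the significance cutoff", {
  cl <- simulate_classified(tiny_scenario(8000, seed = 41L), use_traces = FALSE)
  inc <- cl[cl$included, ]
  hit <- inc$outcome == "hit"
  r10 <- estimate_recovery(inc$t_rel_offset, hit, alpha = 0.1,
                           confirm_bin_width = NULL)
  r05 <- estimate_recovery(inc$t_rel_offset, hit, alpha = 0.05,
                           confirm_bin_width = NULL)
  expect_lte(r05$recovery_time, r10$recovery_time)
})

test_that("onset- and offset-referenced recovery differ by the saccade time", {
  # single-dataset estimates carry the exact test's type-I noise at the
  # first recovered bin, so assert the median over a few replicates
  diffs <- vapply(43:47, function(seed) {
    cfg <- tiny_scenario(12000, seed = seed)
    cl <- simulate_classified(cfg, use_traces = FALSE)
    inc <- cl[cl$included, ]
    hit <- inc$outcome == "hit"
    r_off <- estimate_recovery(inc$t_rel_offset, hit, confirm_bin_width = NULL)
    r_on <- estimate_recovery(inc$t_rel_onset, hit, confirm_bin_width = NULL,
                              test_window = c(0, 150),
                              baseline_window = c(150, 550))
    r_on$recovery_time - r_off$recovery_time
  }, 0)
  # operational saccade duration = support duration minus two crossing lags
  dur <- 40 - 2 * crossing_lag(7, 40, 50)
  expect_lte(abs(median(diffs) - dur), 10)
})

test_that("the 5 ms confirmation pass agrees on clean step data", {
  mains <- conf <- numeric(3)
  for (i in 1:3) {
    cl <- simulate_classified(tiny_scenario(12000, seed = 46L + i),
                              use_traces = FALSE)
    inc <- cl[cl$included, ]
    rec <- estimate_recovery(inc$t_rel_offset, inc$outcome == "hit")
    mains[i] <- rec$recovery_time
    conf[i] <- rec$confirmation$recovery_time
  }
  # modal estimate hits the generating step; fine pass within one coarse bin
  expect_equal(as.numeric(names(which.max(table(mains)))), 30)
  expect_true(all(abs(conf - mains) <= 10))
})

test_that("latency groups are half-open and tolerate empty groups", {
  lat <- c(74.9, 75, 124.9, 125, 200)
  t_rel <- rep(50, 5); hit <- rep(TRUE, 5)
  out <- latency_split_curves(lat, t_rel, hit, bin_width = 50,
                              span = c(0, 100))
  expect_equal(sum(out$predictive$n), 1)   # only 74.9
  expect_equal(sum(out$express$n), 2)      # 75 and 124.9
  expect_equal(sum(out$regular$n), 2)      # 125 and 200
  none <- latency_split_curves(numeric(0), numeric(0), logical(0))
  expect_true(all(vapply(none, function(b) sum(b$n), 0) == 0))
  expect_error(latency_split_curves(lat, t_rel, hit,
                                    groups = list(c(0, 80), c(75, 125))),
               "overlap")
})

test_that("false-positive report: zero rates give p = 1 everywhere", {
  loc <- rep(c("below", "right"), each = 40)
  t_d <- rep(75, 80)
  fp <- false_positive_analysis(loc, t_d, rep(FALSE, 80))
  expect_equal(fp$rate, c(0, 0))
  expect_equal(fp$p_vs_control[fp$location == "right"], 1)
  expect_true(is.na(fp$p_vs_control[fp$location == "below"]))
})

test_that("false-positive comparison detects a genuinely raised rate", {
  set.seed(99)
  n <- 300
  loc <- rep(c("below", "right"), each = n)
  t_d <- runif(2 * n, 0, 150)
  resp <- c(runif(n) < 0.01, runif(n) < 0.30)
  fp <- false_positive_analysis(loc, t_d, resp)
  expect_lt(fp$p_vs_control[fp$location == "right"], 0.01)
})

test_that("under equal rates the comparison rarely flags a difference", {
  hits <- 0L
  for (seed in 1:30) {
    set.seed(seed)
    n <- 150
    loc <- rep(c("below", "right"), each = n)
    resp <- runif(2 * n) < 0.05
    fp <- false_positive_analysis(loc, rep(75, 2 * n), resp)
    if (fp$p_vs_control[fp$location == "right"] > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 27)  # exact one-sided test is conservative under the null
})

test_that("distractor changes outside the window are ignored", {
  loc <- c("below", "right", "right")
  fp <- false_positive_analysis(loc, c(75, 75, 400), c(FALSE, TRUE, TRUE))
  expect_equal(fp$n_changes[fp$location == "right"], 1)
  expect_equal(fp$n_responses[fp$location == "right"], 1)
})
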