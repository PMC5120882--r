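test_that("response classification implements the timing rules", {
  rows <- rbind(
    make_trial(1, tc = 1500, resp = 1800),              # hit
    make_trial(2, tc = 1500, resp = 2200),              # past the deadline
    make_trial(3, tc = 1500, resp = 2100),              # boundary: exactly +600
    make_trial(4, tc = 1600, dc = 900, resp = 1400),    # distractor response
    make_trial(5, tc = 1600, resp = 1400),              # early, no distractor
    make_trial(6, tc = 1500),                           # no press
    make_trial(7, catch = TRUE),                        # quiet catch
    make_trial(8, catch = TRUE, resp = 1000),           # catch false alarm
    make_trial(9, catch = TRUE, dc = 900, resp = 1400)) # catch, pressed for distractor
  out <- classify_response(rows)
  expect_equal(out, c("hit", "miss", "hit", "distractor_response",
                      "early_response", "miss", "catch_correct", "catch_fa",
                      "distractor_response"))
})

test_that("a response in the hit window takes precedence over the distractor rule", {
  # press after the target change that is also within 800 ms of a distractor
  tr <- make_trial(1, tc = 1500, dc = 1000, resp = 1700)
  expect_equal(classify_response(tr), "hit")
})

test_that("inclusion rules exclude on the first failing criterion", {
  base <- make_trial(1, tc = 1500, resp = 1800)
  mk <- function(n_sacc = 1, latency = 150, landing = 0.2, pre = TRUE,
                 post = TRUE, trial = base) {
    cl <- cbind(trial, data.frame(
      n_valid_saccades = n_sacc, saccade_onset = 1235 + latency,
      saccade_offset = 1235 + latency + 40, latency = latency,
      peak_velocity = 350, amplitude = 7, landing_dist = landing,
      fixation_pre_ok = pre, fixation_post_ok = post))
    cl$outcome <- classify_response(trial)
    cl$t_rel_offset <- cl$target_change_time - cl$saccade_offset
    cl$t_rel_onset <- cl$target_change_time - cl$saccade_onset
    cl$t_d_rel_offset <- cl$distractor_change_time - cl$saccade_offset
    cl
  }
  ok <- select_trials(mk())
  expect_true(ok$included)
  expect_equal(ok$exclusion_reason, "")
  expect_equal(select_trials(mk(n_sacc = 2))$exclusion_reason, "multiple_saccades")
  expect_equal(select_trials(mk(n_sacc = 0))$exclusion_reason, "no_saccade")
  expect_equal(select_trials(mk(latency = -60))$exclusion_reason,
               "latency_out_of_window")
  expect_true(select_trials(mk(latency = -50))$included)   # bounds inclusive
  expect_true(select_trials(mk(latency = 450))$included)
  expect_equal(select_trials(mk(landing = 2.4))$exclusion_reason,
               "landing_off_target")
  expect_equal(select_trials(mk(pre = FALSE))$exclusion_reason, "fixation_break")
  expect_equal(select_trials(mk(trial = make_trial(1, catch = TRUE)))$exclusion_reason,
               "catch_trial")
})

test_that("alignment to the saccade is a plain subtraction, sign preserved", {
  cl <- data.frame(target_change_time = c(1500, 1500, 1400),
                   saccade_onset = c(1430, 1430, 1430),
                   saccade_offset = c(1470, 1470, 1470))
  cl$t_rel_offset <- cl$target_change_time - cl$saccade_offset
  cl$t_rel_onset <- cl$target_change_time - cl$saccade_onset
  expect_equal(align_to_saccade(cl, "offset"), c(30, 30, -70))
  expect_equal(align_to_saccade(cl, "onset")[1], 70)
})

test_that("outcome partition and trial counts are conserved end to end", {
  cfg <- tiny_scenario(800, seed = 31L)
  cl <- simulate_classified(cfg, use_traces = FALSE)
  outcomes <- c("hit", "miss", "early_response", "distractor_response",
                "catch_correct", "catch_fa")
  expect_true(all(cl$outcome %in% outcomes))
  expect_equal(nrow(cl), 800)
  expect_equal(sum(cl$included) + sum(!cl$included), 800)
  tab <- table(cl$exclusion_reason[!cl$included])
  expect_equal(sum(cl$included) + sum(tab), 800)
  expect_true(all(cl$outcome[cl$included] %in% c("hit", "miss")))
  # t_rel present iff a saccade was found and a target change exists
  has <- cl$n_valid_saccades == 1 & !cl$catch
  expect_true(all(!is.na(cl$t_rel_offset[has])))
  expect_true(all(is.na(cl$t_rel_offset[cl$catch])))
})

test_that("with no false alarms there are no early or distractor responses", {
  cfg <- tiny_scenario(600, seed = 13L,
                       false_alarm_prob_per_distractor_change = 0)
  cl <- simulate_classified(cfg, use_traces = FALSE)
  expect_equal(sum(cl$outcome == "distractor_response"), 0)
  expect_equal(sum(cl$outcome == "early_response"), 0)
})

test_that("early responses are rare at the default settings", {
  cfg <- tiny_scenario(4000, seed = 17L)
  cl <- simulate_classified(cfg, use_traces = FALSE)
  expect_lt(mean(cl$outcome == "early_response"), 0.02)
  # responses attributed to distractors are a few percent of trials
  expect_lt(mean(cl$outcome == "distractor_response"), 0.05)
})

test_that("a clean scenario yields inclusion fraction 1", {
  cfg <- tiny_scenario(150, seed = 19L, change_trial_fraction = 1,
                       distractor_change_fraction = 0,
                       false_alarm_prob_per_distractor_change = 0)
  cl <- simulate_classified(cfg, use_traces = FALSE)
  expect_equal(mean(cl$included), 1)
})
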