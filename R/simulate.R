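## Synthetic-data generator: trial schedules, saccade kinematics, behavior.
## All times are in ms on the trial clock (0 = fixation point onset).

draw_frames <- function(n, k_lo, k_hi) {
  # uniform integer frame indices in [k_lo, k_hi] (vectors recycled)
  k_lo + floor(stats::runif(n) * (k_hi - k_lo + 1))
}

#' Sample a schedule of trial events for one scenario
#'
#' Draws, for each trial, whether it is a change trial or a catch trial,
#' whether a distractor change occurs, and the change times. Change times are
#' snapped to the video frame grid (multiples of `1000/refresh_rate` ms after
#' random-dot-pattern onset) and stored with the second-frame convention.
#' When both a target and a distractor change are present the distractor
#' precedes the target by at least the configured separation.
#'
#' Uses the current RNG stream; call `set.seed()` (or use
#' [simulate_experiment()]) for reproducibility.
#'
#' @param config a [build_scenario()] config.
#' @return data frame with one row per trial: `trial_id`, `subject_id`,
#'   `experiment_id`, `fp_jump_time`, `rdp_onset`, `catch`,
#'   `target_change_time`, `distractor_change_time`, `distractor_location`.
#' @export
sample_trial_schedule <- function(config) {
  validate_scenario(config)
  n <- config$n_trials
  fd <- 1000 / config$refresh_rate
  rdp <- config$fixation_to_rdp
  fpj <- rdp + config$rdp_onset_to_fp_jump
  tw <- config$target_change_window
  dw <- config$distractor_change_window
  sep <- config$min_target_distractor_separation

  is_change <- stats::runif(n) < config$change_trial_fraction
  has_d <- stats::runif(n) < config$distractor_change_fraction

  k_lo <- ceiling(tw[1] / fd); k_hi <- floor(tw[2] / fd)
  dk_lo <- ceiling(dw[1] / fd); dk_hi_w <- floor(dw[2] / fd)
  # earliest target frame that leaves room for a distractor at dk_lo
  k_lo_d <- ceiling((dk_lo * fd + sep) / fd)
  if (k_lo_d > k_hi && any(is_change & has_d))
    stop("infeasible constraint: separation of ", sep,
         " ms leaves no feasible target-change frame")

  target_k <- rep(NA_real_, n)
  plain <- is_change & !has_d
  constrained <- is_change & has_d
  target_k[plain] <- draw_frames(sum(plain), k_lo, k_hi)
  target_k[constrained] <- draw_frames(sum(constrained), max(k_lo, k_lo_d), k_hi)
  tc_first <- target_k * fd
  target_change_time <- rdp + (target_k + 1) * fd   # second frame

  d_k <- rep(NA_real_, n)
  dc_con <- constrained
  d_k[dc_con] <- draw_frames(sum(dc_con), dk_lo,
                             pmin(dk_hi_w, floor((tc_first[dc_con] - sep) / fd)))
  dc_catch <- has_d & !is_change
  d_k[dc_catch] <- draw_frames(sum(dc_catch), dk_lo, dk_hi_w)
  distractor_change_time <- rdp + (d_k + 1) * fd

  locs <- names(config$distractor_locations)
  loc <- rep(NA_character_, n)
  loc[has_d] <- sample(locs, sum(has_d), replace = TRUE,
                       prob = config$distractor_locations)

  data.frame(trial_id = seq_len(n), subject_id = rep("s01", n),
             experiment_id = rep(config$experiment_id, n),
             fp_jump_time = rep(fpj, n), rdp_onset = rep(rdp, n),
             catch = !is_change,
             target_change_time = target_change_time,
             distractor_change_time = distractor_change_time,
             distractor_location = loc,
             stringsAsFactors = FALSE)
}

#' Analytic threshold-crossing lag of the raised-cosine velocity profile
#'
#' The saccade velocity profile is a raised cosine,
#' `v(tau) = (2A/D) sin^2(pi tau / D)` for `tau` in `[0, D]` (amplitude `A`
#' deg, duration `D` ms, peak velocity `2A/D` deg/ms). The speed first
#' exceeds a threshold `theta` deg/s at
#' `tau = (D/pi) asin(sqrt(theta / v_peak))`, and symmetrically drops below
#' it the same lag before the end of the profile.
#'
#' @param amplitude saccade amplitude (deg).
#' @param duration saccade duration (ms).
#' @param threshold speed threshold (deg/s), below peak velocity.
#' @return lag in ms from the profile's support endpoint to the crossing.
#' @export
crossing_lag <- function(amplitude, duration, threshold) {
  v_peak <- 2 * amplitude / duration * 1000  # deg/s
  if (threshold <= 0 || threshold >= v_peak)
    stop("threshold must lie in (0, peak velocity)")
  (duration / pi) * asin(sqrt(threshold / v_peak))
}

raised_cosine_pos <- function(u) u - sin(2 * pi * u) / (2 * pi)  # u in [0,1]

# Draw saccade latencies from the truncated Gaussian mixture.
draw_latencies <- function(n, mixture, range) {
  wts <- vapply(mixture, function(m) m[["weight"]], 0)
  comp <- sample(seq_along(mixture), n, replace = TRUE, prob = wts)
  mu <- vapply(mixture, function(m) m[["mean"]], 0)[comp]
  sdv <- vapply(mixture, function(m) m[["sd"]], 0)[comp]
  lat <- stats::rnorm(n, mu, sdv)
  bad <- which(lat < range[1] | lat > range[2])
  while (length(bad)) {
    lat[bad] <- stats::rnorm(length(bad), mu[bad], sdv[bad])
    bad <- bad[lat[bad] < range[1] | lat[bad] > range[2]]
  }
  lat
}

#' Draw ground-truth saccade kinematics for a schedule
#'
#' Samples a saccade latency per trial from the configured mixture and
#' derives two sets of landmarks: the velocity profile's support endpoints
#' (`onset_true`, `offset_true`; their difference is exactly the configured
#' saccade duration) and the operational landmarks (`onset_ref`,
#' `offset_ref`) where the noise-free speed crosses
#' `config$landmark_threshold`. The behavioral model keys suppression and
#' recovery to the operational landmarks.
#'
#' @param trials schedule from [sample_trial_schedule()].
#' @param config scenario config.
#' @return data frame: `trial_id`, `latency`, `onset_true`, `offset_true`,
#'   `onset_ref`, `offset_ref`, `glissade`.
#' @export
simulate_truth <- function(trials, config) {
  n <- nrow(trials)
  lat <- draw_latencies(n, config$saccade_latency_mixture, config$latency_range)
  onset <- trials$fp_jump_time + lat
  offset <- onset + config$saccade_duration
  lag <- crossing_lag(config$saccade_amplitude, config$saccade_duration,
                      config$landmark_threshold)
  data.frame(trial_id = trials$trial_id, latency = lat,
             onset_true = onset, offset_true = offset,
             onset_ref = onset + lag, offset_ref = offset - lag,
             glissade = stats::runif(n) < config$glissade[["probability"]])
}

# shifted log-normal with a given median, clamped to a ceiling
draw_rt <- function(n, median_ms, sdlog, shift = 150, ceiling_ms = Inf) {
  rt <- shift + stats::rlnorm(n, meanlog = log(median_ms - shift), sdlog = sdlog)
  pmin(rt, ceiling_ms)
}

#' Sample behavioral responses for a schedule
#'
#' Each change trial is a hit with the probability given by the scenario's
#' performance curve evaluated at the target-change time (second-frame
#' convention) against the trial's landmarks; hits get a reaction time drawn
#' from a shifted log-normal with the configured median, clamped at the
#' response deadline. Independently, each distractor change triggers a false
#' alarm with the configured probability, at a latency within 800 ms of the
#' distractor change. The recorded response is the earliest scheduled press
#' (trials end at the first key press).
#'
#' @param trials schedule data frame.
#' @param truth output of [simulate_truth()].
#' @param config scenario config.
#' @return `trials` with added columns `response_time` (ms or `NA`) and
#'   `p_hit` (generating detection probability; `NA` on catch trials).
#' @export
sample_behavior <- function(trials, truth, config) {
  n <- nrow(trials)
  curve <- config$performance_curve
  p_hit <- rep(NA_real_, n)
  ch <- !trials$catch
  p_hit[ch] <- eval_performance_curve(curve, trials$target_change_time[ch],
                                      trials$fp_jump_time[ch],
                                      truth$onset_ref[ch], truth$offset_ref[ch])
  hit <- !is.na(p_hit) & stats::runif(n) < p_hit
  hit_time <- rep(NA_real_, n)
  hit_time[hit] <- trials$target_change_time[hit] +
    draw_rt(sum(hit), config$rt_median, config$rt_spread,
            ceiling_ms = config$response_deadline)

  has_d <- !is.na(trials$distractor_change_time)
  fa <- has_d & stats::runif(n) < config$false_alarm_prob_per_distractor_change
  fa_time <- rep(NA_real_, n)
  fa_time[fa] <- trials$distractor_change_time[fa] +
    draw_rt(sum(fa), 450, 0.5, ceiling_ms = 800)

  trials$response_time <- pmin(hit_time, fa_time, na.rm = TRUE)
  trials$p_hit <- p_hit
  trials
}

#' Synthesize one eye-position trace
#'
#' Builds a 1000 Hz gaze trace for a trial: Gaussian fixation noise around
#' the fixation point, a horizontal saccade of the configured amplitude with
#' a raised-cosine velocity profile at the trial's true onset, optionally
#' followed by a small glissade (same profile shape), then fixation noise
#' around the saccade target.
#'
#' @param trial one-row data frame from the schedule (with `response_time`
#'   if behavior has been sampled).
#' @param truth_row matching one-row data frame from [simulate_truth()].
#' @param config scenario config.
#' @return data frame with columns `trial_id`, `t_ms`, `x_deg`, `y_deg`.
#' @export
synth_eye_trace <- function(trial, truth_row, config) {
  g_dur <- if (truth_row$glissade) config$glissade[["duration"]] else 0
  resp_end <- if (!is.na(trial$response_time)) trial$response_time + 100
              else if (!trial$catch) trial$target_change_time + config$response_deadline + 100
              else trial$fp_jump_time + 800
  t_end <- ceiling(max(resp_end, truth_row$offset_true + g_dur + 300))
  if (truth_row$offset_true + g_dur > t_end)
    stop("saccade would extend past trace end")
  t <- 0:t_end
  nt <- length(t)
  x <- stats::rnorm(nt, 0, config$fixation_noise_sd)
  y <- stats::rnorm(nt, 0, config$fixation_noise_sd)
  u <- pmin(pmax((t - truth_row$onset_true) / config$saccade_duration, 0), 1)
  x <- x + config$saccade_amplitude * raised_cosine_pos(u)
  if (g_dur > 0) {
    ug <- pmin(pmax((t - truth_row$offset_true) / g_dur, 0), 1)
    x <- x + config$glissade[["amplitude"]] * raised_cosine_pos(ug)
  }
  quick_df(list(trial_id = rep(trial$trial_id, nt), t_ms = t,
                x_deg = x, y_deg = y))
}

simulate_traces <- function(trials, truth, config, as_list = FALSE) {
  out <- lapply(seq_len(nrow(trials)), function(i)
    synth_eye_trace(trials[i, ], truth[i, ], config))
  if (as_list) { names(out) <- as.character(trials$trial_id); return(out) }
  do.call(rbind, out)
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator under a single RNG stream seeded from
#' `config$seed`: trial schedule, ground-truth saccade kinematics, behavioral
#' responses, and (optionally) 1000 Hz eye-position traces. Identical configs
#' produce bit-identical datasets.
#'
#' @param config a [build_scenario()] config.
#' @param traces logical; generate eye traces (set `FALSE` for schedule-level
#'   studies where the analysis uses ground-truth landmarks directly).
#' @return list of class `simulated_dataset`: `config`, `trials` (with
#'   responses), `truth`, and `traces` (long data frame, or `NULL`).
#' @examples
#' ds <- simulate_experiment(build_scenario("E1", list(n_trials = 20, seed = 7)))
#' head(ds$trials)
#' @export
simulate_experiment <- function(config, traces = TRUE) {
  validate_scenario(config)
  set.seed(as.integer(config$seed))
  trials <- sample_trial_schedule(config)
  truth <- simulate_truth(trials, config)
  trials <- sample_behavior(trials, truth, config)
  tr <- if (traces && nrow(trials)) simulate_traces(trials, truth, config)
        else NULL
  structure(list(config = config, trials = trials, truth = truth, traces = tr),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %s: %d trials (%d catch), seed %d, traces: %s\n",
              x$config$experiment_id, nrow(x$trials), sum(x$trials$catch),
              as.integer(x$config$seed),
              if (is.null(x$traces)) "no" else "yes"))
  invisible(x)
}
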