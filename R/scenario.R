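#' Frame-timing helpers
#'
#' Stimulus changes last a whole number of video frames, so event times are
#' quantized to the monitor refresh. `change_duration()` converts a frame
#' count to milliseconds; `change_event_time()` returns the display time of
#' the *second* frame of a two-frame change, the convention used throughout
#' the analysis to timestamp a change (a conservative choice when measuring
#' how quickly performance recovers after the saccade).
#'
#' @param frames number of video frames.
#' @param refresh_rate monitor refresh rate in Hz; must be positive.
#' @param first_frame_index zero-based index of the frame on which the change
#'   starts, counted from the reference event (e.g. random-dot-pattern onset).
#' @return time in ms.
#' @examples
#' change_duration(2, 85)          # 23.5 ms two-frame change at 85 Hz
#' change_event_time(10, 85)       # display time of the second changed frame
#' @export
change_duration <- function(frames, refresh_rate) {
  if (any(refresh_rate <= 0)) stop("refresh_rate must be positive")
  frames * 1000 / refresh_rate
}

#' @rdname change_duration
#' @export
change_event_time <- function(first_frame_index, refresh_rate) {
  if (any(refresh_rate <= 0)) stop("refresh_rate must be positive")
  (first_frame_index + 1) * 1000 / refresh_rate
}

#' Piecewise peri-saccadic performance time-course
#'
#' Defines the probability of detecting a target change as a function of when
#' the change occurs relative to the trial's landmarks: a flat baseline, a
#' shallow linear dip that begins when the fixation point jumps (attentional
#' resources divert to saccade planning), a steep drop into a suppression
#' floor shortly before saccade onset, and a recovery back to baseline at a
#' fixed delay after saccade offset (step by default).
#'
#' Landmark convention: the suppression and recovery segments are keyed to
#' the *operational* saccade onset/offset, i.e. the times at which the eye
#' speed crosses the detection threshold used by the analysis. This makes the
#' generating recovery delay directly comparable to what a velocity-threshold
#' pipeline measures; see the methods vignette for the rationale.
#'
#' @param baseline_p detection probability far from the saccade.
#' @param dip_depth drop (probability units) reached just before suppression.
#' @param suppression_floor_p detection probability during suppression.
#' @param suppression_start ms before saccade onset at which the steep
#'   pre-saccadic drop begins.
#' @param recovery_time ms after saccade offset at which performance is back
#'   at baseline.
#' @param recovery_shape `"step"` (baseline resumes abruptly at
#'   `offset + recovery_time`) or `"linear_ramp"` (linear rise from the floor
#'   starting at offset).
#' @param lapse_rate probability of missing regardless of timing; the curve
#'   is scaled by `1 - lapse_rate`.
#' @return an object of class `performance_curve`.
#' @export
performance_curve <- function(baseline_p = 0.98, dip_depth = 0.08,
                              suppression_floor_p = 0.05,
                              suppression_start = 30, recovery_time = 30,
                              recovery_shape = c("step", "linear_ramp"),
                              lapse_rate = 0) {
  recovery_shape <- match.arg(recovery_shape)
  stopifnot(baseline_p >= 0, baseline_p <= 1,
            suppression_floor_p >= 0, suppression_floor_p <= baseline_p,
            dip_depth >= 0, dip_depth <= baseline_p,
            recovery_time >= 0, lapse_rate >= 0, lapse_rate < 1)
  structure(list(baseline_p = baseline_p, dip_depth = dip_depth,
                 suppression_floor_p = suppression_floor_p,
                 dip_start_ref = "fp_jump",
                 suppression_start = suppression_start,
                 recovery_time = recovery_time,
                 recovery_shape = recovery_shape,
                 lapse_rate = lapse_rate),
            class = "performance_curve")
}

#' Evaluate a performance curve at given change times
#'
#' @param curve a [performance_curve()].
#' @param t_change change times (ms, trial clock; second-frame convention).
#' @param fp_jump fixation-point jump time (ms), scalar or vector.
#' @param onset,offset operational saccade onset/offset times (ms), scalar or
#'   vector recycled against `t_change`.
#' @return vector of detection probabilities.
#' @export
eval_performance_curve <- function(curve, t_change, fp_jump, onset, offset) {
  stopifnot(inherits(curve, "performance_curve"))
  n <- length(t_change)
  fp_jump <- rep_len(fp_jump, n); onset <- rep_len(onset, n)
  offset <- rep_len(offset, n)
  base <- curve$baseline_p
  floorp <- curve$suppression_floor_p
  s0 <- onset - curve$suppression_start
  rec <- offset + curve$recovery_time
  p <- rep(base, n)
  # dip: linear decline from baseline at fp jump to (baseline - dip) at s0
  in_dip <- t_change >= fp_jump & t_change < s0 & s0 > fp_jump
  frac <- (t_change[in_dip] - fp_jump[in_dip]) / (s0[in_dip] - fp_jump[in_dip])
  p[in_dip] <- base - curve$dip_depth * frac
  # steep pre-saccadic drop from (baseline - dip) into the floor
  in_drop <- t_change >= s0 & t_change < onset
  frac <- (t_change[in_drop] - s0[in_drop]) / (onset[in_drop] - s0[in_drop])
  p[in_drop] <- (base - curve$dip_depth) * (1 - frac) + floorp * frac
  in_supp <- t_change >= onset & t_change < rec
  p[in_supp] <- floorp
  if (curve$recovery_shape == "linear_ramp" && curve$recovery_time > 0) {
    in_ramp <- t_change >= offset & t_change < rec
    frac <- (t_change[in_ramp] - offset[in_ramp]) / curve$recovery_time
    p[in_ramp] <- floorp + (base - floorp) * frac
  }
  p * (1 - curve$lapse_rate)
}

scenario_fields <- c(
  "experiment_id", "refresh_rate", "sample_rate", "fixation_to_rdp",
  "rdp_onset_to_fp_jump", "target_change_window", "change_trial_fraction",
  "distractor_change_fraction", "distractor_change_window",
  "min_target_distractor_separation", "response_deadline",
  "saccade_amplitude", "saccade_latency_mixture", "latency_range",
  "fixation_noise_sd", "saccade_duration", "glissade", "performance_curve",
  "landmark_threshold", "distractor_locations", "control_location",
  "rt_median", "rt_spread", "false_alarm_prob_per_distractor_change",
  "n_trials", "seed")

# Latency mixture: three truncated-Gaussian components whose means put mass
# in the predictive (0-75), express (75-125) and regular (125-250) ranges.
default_latency_mixture <- list(c(weight = 0.10, mean = 50,  sd = 15),
                                c(weight = 0.30, mean = 100, sd = 15),
                                c(weight = 0.60, mean = 170, sd = 40))

scenario_defaults <- function(experiment_id) {
  base <- list(
    experiment_id = experiment_id,
    refresh_rate = 85, sample_rate = 1000,
    fixation_to_rdp = 647, rdp_onset_to_fp_jump = 588,
    target_change_window = c(118, 1882),
    change_trial_fraction = 0.90,
    distractor_change_fraction = 0.39,
    distractor_change_window = c(118, 1882),
    min_target_distractor_separation = 400,
    response_deadline = 600,
    saccade_amplitude = 7,
    saccade_latency_mixture = default_latency_mixture,
    latency_range = c(-50, 450),
    fixation_noise_sd = 0.02,
    saccade_duration = 40,
    glissade = c(probability = 0.3, amplitude = 0.5, duration = 20),
    performance_curve = performance_curve(),
    landmark_threshold = 50,
    distractor_locations = c(below = 0.5, right = 0.5),
    control_location = "below",
    rt_median = 324, rt_spread = 0.35,
    false_alarm_prob_per_distractor_change = 0.056,
    n_trials = 1000, seed = 1L)
  switch(experiment_id,
    E1 = base,
    E2easy = utils::modifyList(base, list(
      fixation_to_rdp = 412, rdp_onset_to_fp_jump = 823,
      target_change_window = c(235, 1647),
      distractor_change_window = c(118, 1224),
      distractor_change_fraction = 0.27,
      change_trial_fraction = 0.93,
      performance_curve = performance_curve(baseline_p = 0.90))),
    E2hard = utils::modifyList(base, list(
      fixation_to_rdp = 412, rdp_onset_to_fp_jump = 823,
      target_change_window = c(235, 1647),
      distractor_change_window = c(118, 1224),
      distractor_change_fraction = 0.27,
      change_trial_fraction = 0.93,
      performance_curve = performance_curve(baseline_p = 0.70))),
    E3 = utils::modifyList(base, list(
      target_change_window = c(412, 2176),
      distractor_change_window = c(470, 941),
      distractor_change_fraction = 0.60,
      change_trial_fraction = 0.94,
      distractor_locations = c(right = 0.4, left = 0.4, below = 0.2),
      performance_curve = performance_curve(baseline_p = 0.95),
      false_alarm_prob_per_distractor_change = 0.023)),
    stop("unknown experiment id: ", experiment_id))
}

#' Build a fully-populated simulation scenario
#'
#' Returns the complete generative parameter set for one of the emulated
#' experiments. `E1` is the reference design: random-dot patterns appear
#' 647 ms after fixation onset, the fixation point jumps 7 degrees rightward
#' 588 ms later (1235 ms into the trial), target changes fall 118-1882 ms
#' after pattern onset on ~90% of trials, and ~39% of trials carry a
#' distractor change at least 400 ms before the target change. `E2easy` /
#' `E2hard` shift the timing (patterns at 412 ms, changes 235-1647 ms,
#' distractors on ~27% of trials, 7% catch trials) and lower the baseline
#' detection rate; `E3` delays target changes (412-2176 ms), concentrates
#' distractor changes in 470-941 ms on ~60% of trials, and adds a distractor
#' location to the left of the target.
#'
#' @param experiment_id one of `"E1"`, `"E2easy"`, `"E2hard"`, `"E3"`.
#' @param overrides named list replacing individual config fields; unknown
#'   names are an error.
#' @return a list of class `scenario_config`.
#' @examples
#' cfg <- build_scenario("E1", overrides = list(n_trials = 200, seed = 42))
#' cfg$rdp_onset_to_fp_jump  # 588 ms
#' @export
build_scenario <- function(experiment_id = c("E1", "E2easy", "E2hard", "E3"),
                           overrides = list()) {
  experiment_id <- match.arg(experiment_id)
  cfg <- scenario_defaults(experiment_id)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), scenario_fields)
    if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
    # direct assignment: list-valued fields (mixture, curve) are replaced
    # wholesale, never merged element-wise
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  }
  cfg <- structure(cfg, class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants: probabilities in \[0, 1\], ordered time
#' windows, non-negative separation, and latency-mixture weights summing to
#' one.
#'
#' @param config a `scenario_config`.
#' @return the config, invisibly; errors on violation.
#' @export
validate_scenario <- function(config) {
  probs <- c(config$change_trial_fraction, config$distractor_change_fraction,
             config$false_alarm_prob_per_distractor_change,
             config$glissade[["probability"]])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (w in list(config$target_change_window, config$distractor_change_window)) {
    if (length(w) != 2 || w[1] >= w[2]) stop("windows must be ordered low < high")
  }
  if (config$min_target_distractor_separation < 0)
    stop("min_target_distractor_separation must be >= 0")
  wts <- vapply(config$saccade_latency_mixture, function(m) m[["weight"]], 0)
  if (abs(sum(wts) - 1) > 1e-8) stop("latency mixture weights must sum to 1")
  if (config$refresh_rate <= 0 || config$sample_rate <= 0)
    stop("rates must be positive")
  peak <- 2 * config$saccade_amplitude / config$saccade_duration * 1000
  if (config$landmark_threshold >= peak)
    stop("landmark_threshold must be below the saccade's peak velocity")
  invisible(config)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: %d trials, seed %d\n", x$experiment_id,
              x$n_trials, as.integer(x$seed)))
  cat(sprintf("  fp jump at %g ms; target changes %g-%g ms after RDP onset\n",
              x$fixation_to_rdp + x$rdp_onset_to_fp_jump,
              x$target_change_window[1], x$target_change_window[2]))
  cat(sprintf("  change trials %.0f%%, distractor changes %.0f%% (sep >= %g ms)\n",
              100 * x$change_trial_fraction, 100 * x$distractor_change_fraction,
              x$min_target_distractor_separation))
  invisible(x)
}
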