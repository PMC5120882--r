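## End-to-end orchestration: velocity -> detection -> classification ->
## selection -> binning -> recovery -> false-positive analysis.

#' Analyze a dataset of eye traces and trial events
#'
#' Runs the complete analysis chain on a set of trials: saccade detection on
#' every trace, response classification, the inclusion rules, alignment of
#' change times to the chosen saccade landmark, binned performance with
#' Wilson bands, the sequential exact-test recovery estimator, the
#' 80%-of-baseline interpolation estimator, latency-split curves, and the
#' distractor false-positive comparison. Per-stage trial counts are logged
#' with `message()`.
#'
#' @param traces long eye-trace data frame or per-trial list.
#' @param trials trial event table.
#' @param threshold velocity threshold in deg/s; may be a named vector keyed
#'   by `subject_id` for individualized thresholds.
#' @param reference `"offset"` or `"onset"` alignment landmark.
#' @param bin_width test/plot bin width in ms.
#' @param alpha non-significance cutoff of the recovery scan.
#' @param span plotted span for the binned curve.
#' @param baseline_window,test_window recovery-estimator windows (ms).
#' @param fixation_rule,latency_window,landing_radius inclusion settings,
#'   see [classify_trials()] and [select_trials()].
#' @param control control distractor location of the false-positive report.
#' @param ... further arguments passed to [classify_trials()].
#' @return list of class `perisacc_analysis`: `classified`, `binned`,
#'   `recovery`, `interp80`, `latency_curves`, `fp_report`, `counts`,
#'   `settings`.
#' @export
analyze_experiment <- function(traces, trials, threshold = 50,
                               reference = c("offset", "onset"),
                               bin_width = 10, alpha = 0.1,
                               span = c(-300, 500),
                               baseline_window = c(100, 500),
                               test_window = c(0, 100),
                               fixation_rule = "radius2",
                               latency_window = c(-50, 450),
                               landing_radius = 2, control = "below", ...) {
  reference <- match.arg(reference)
  thr <- threshold
  if (!is.null(names(thr))) {
    thr <- unname(thr[as.character(trials$subject_id[1])])
    if (is.na(thr)) stop("no threshold for subject ", trials$subject_id[1])
  }
  classified <- classify_trials(trials, traces, threshold = thr,
                                fixation_rule = fixation_rule, ...)
  classified <- select_trials(classified, latency_window, landing_radius)
  analyze_classified(classified, reference = reference, bin_width = bin_width,
                     alpha = alpha, span = span,
                     baseline_window = baseline_window,
                     test_window = test_window, control = control)
}

#' Analysis stages downstream of trial classification
#'
#' Same as [analyze_experiment()] but starting from an already classified and
#' selected trial table — useful when traces are processed in chunks or when
#' re-analyzing saved classification output.
#'
#' @param classified output of [select_trials()].
#' @inheritParams analyze_experiment
#' @return list of class `perisacc_analysis`.
#' @export
analyze_classified <- function(classified, reference = "offset",
                               bin_width = 10, alpha = 0.1,
                               span = c(-300, 500),
                               baseline_window = c(100, 500),
                               test_window = c(0, 100), control = "below") {
  excl <- table(classified$exclusion_reason[!classified$included])
  counts <- list(n_input = nrow(classified),
                 n_included = sum(classified$included),
                 n_excluded_by_reason = as.list(excl))
  message(sprintf("trials: %d in, %d included, %d excluded [%s]",
                  counts$n_input, counts$n_included,
                  counts$n_input - counts$n_included,
                  paste(sprintf("%s: %d", names(excl), excl), collapse = ", ")))
  inc <- classified[classified$included, ]
  t_rel <- align_to_saccade(inc, reference)
  hit <- inc$outcome == "hit"
  binned <- bin_performance(t_rel, hit, bin_width, span, reference = reference)
  recovery <- estimate_recovery(t_rel, hit, bin_width = bin_width,
                                alpha = alpha,
                                baseline_window = baseline_window,
                                test_window = test_window)
  interp80 <- recovery_interp80(binned, recovery$baseline$rate)
  message(sprintf("recovery: %s ms (interp80 %.1f ms), baseline %.3f",
                  format(recovery$recovery_time), interp80,
                  recovery$baseline$rate))
  latency_curves <- latency_split_curves(inc$latency, t_rel, hit)
  has_sacc <- classified$n_valid_saccades == 1
  fp_report <- false_positive_analysis(
    classified$distractor_location[has_sacc],
    classified$t_d_rel_offset[has_sacc],
    classified$outcome[has_sacc] == "distractor_response", control = control)
  structure(list(classified = classified, binned = binned, recovery = recovery,
                 interp80 = interp80, latency_curves = latency_curves,
                 fp_report = fp_report, counts = counts,
                 settings = list(reference = reference, bin_width = bin_width,
                                 alpha = alpha,
                                 baseline_window = baseline_window,
                                 test_window = test_window, span = span)),
            class = "perisacc_analysis")
}

#' @export
print.perisacc_analysis <- function(x, ...) {
  cat(sprintf("<perisacc_analysis> %d trials, %d included (reference: %s)\n",
              x$counts$n_input, x$counts$n_included, x$settings$reference))
  cat(sprintf("  recovery: %s ms (alpha %g, %g ms bins); 80%%-of-baseline: %.1f ms\n",
              format(x$recovery$recovery_time), x$settings$alpha,
              x$settings$bin_width, x$interp80))
  invisible(x)
}

#' Simulate a scenario and classify its trials in chunks
#'
#' Generates a full synthetic dataset (schedule, kinematics, behavior) and
#' pushes the trials through saccade detection, classification, and the
#' inclusion rules, synthesizing eye traces in chunks so that large datasets
#' never hold all traces in memory. With `use_traces = FALSE` the detector is
#' bypassed and the ground-truth operational landmarks stand in for detected
#' events — the schedule-level fast path used in calibration studies of the
#' recovery estimator.
#'
#' @param config a [build_scenario()] config (its `seed` drives everything).
#' @param threshold detector threshold (deg/s); defaults to the scenario's
#'   landmark threshold.
#' @param chunk_size trials per trace chunk.
#' @param use_traces logical; synthesize and analyze real traces.
#' @param ... passed to [classify_trials()].
#' @inheritParams select_trials
#' @return classified and selected trial table (one row per trial).
#' @export
simulate_classified <- function(config, threshold = config$landmark_threshold,
                                chunk_size = 2000, use_traces = TRUE,
                                latency_window = c(-50, 450),
                                landing_radius = 2, ...) {
  validate_scenario(config)
  set.seed(as.integer(config$seed))
  trials <- sample_trial_schedule(config)
  truth <- simulate_truth(trials, config)
  trials <- sample_behavior(trials, truth, config)
  n <- nrow(trials)
  if (!use_traces) {
    # pseudo-events from the operational landmarks: onset/offset as a
    # 1000 Hz detector would report them (first sample past the crossing)
    events <- data.frame(trial_id = trials$trial_id,
                         onset = ceiling(truth$onset_ref),
                         offset = ceiling(truth$offset_ref),
                         peak_velocity = 2 * config$saccade_amplitude /
                           config$saccade_duration * 1000,
                         amplitude = config$saccade_amplitude,
                         latency = truth$latency,
                         x_end = config$saccade_amplitude, y_end = 0)
    classified <- classify_trials(trials, traces = NULL, events = events,
                                  deadline = config$response_deadline, ...)
    return(select_trials(classified, latency_window, landing_radius))
  }
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    tr_list <- simulate_traces(trials[idx, ], truth[idx, ], config,
                               as_list = TRUE)
    cl <- classify_trials(trials[idx, ], traces = tr_list,
                          threshold = threshold,
                          saccade_target = c(config$saccade_amplitude, 0),
                          deadline = config$response_deadline, ...)
    out[[ci]] <- select_trials(cl, latency_window, landing_radius)
  }
  do.call(rbind, out)
}
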