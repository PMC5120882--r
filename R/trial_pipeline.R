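## Response classification, the trial inclusion rules, and alignment of
## change times to the detected saccade.

#' Classify the behavioral outcome of each trial
#'
#' Applies the response rules: a press within `deadline` ms after the target
#' change (half-open window `(change, change + deadline]`) is a hit; a press
#' at or before the target change that falls within `distractor_window` ms
#' after a distractor change is a response to the distractor; any other press
#' before the target change is an early response; a change trial without a
#' press in the window is a miss. Catch trials are correct without a press;
#' a press on a catch trial is a distractor response when attributable to a
#' distractor change and a false alarm otherwise.
#'
#' @param trials data frame with columns `catch`, `target_change_time`,
#'   `distractor_change_time`, `response_time` (`NA` = no press).
#' @param deadline response deadline in ms (default 600).
#' @param distractor_window attribution window after a distractor change
#'   (default 800 ms).
#' @return character vector of outcomes: `hit`, `miss`, `early_response`,
#'   `distractor_response`, `catch_correct`, `catch_fa`.
#' @export
classify_response <- function(trials, deadline = 600, distractor_window = 800) {
  n <- nrow(trials)
  rt <- trials$response_time
  tc <- trials$target_change_time
  dc <- trials$distractor_change_time
  near_d <- !is.na(dc) & !is.na(rt) & rt >= dc & rt <= dc + distractor_window
  out <- character(n)
  catch <- trials$catch
  out[catch & is.na(rt)] <- "catch_correct"
  out[catch & !is.na(rt)] <- ifelse(near_d[catch & !is.na(rt)],
                                    "distractor_response", "catch_fa")
  ch <- !catch
  out[ch & is.na(rt)] <- "miss"
  resp <- ch & !is.na(rt)
  early <- resp & rt <= tc
  out[early] <- ifelse(near_d[early], "distractor_response", "early_response")
  out[resp & rt > tc & rt <= tc + deadline] <- "hit"
  out[resp & rt > tc + deadline] <- "miss"
  out
}

# Container for the per-trial saccade/fixation check columns.
empty_checks <- function(n) {
  data.frame(n_valid_saccades = rep(0L, n), saccade_onset = rep(NA_real_, n),
             saccade_offset = rep(NA_real_, n), latency = rep(NA_real_, n),
             peak_velocity = rep(NA_real_, n), amplitude = rep(NA_real_, n),
             landing_dist = rep(NA_real_, n), fixation_pre_ok = rep(NA, n),
             fixation_post_ok = rep(NA, n))
}

#' Attach saccade, outcome and alignment information to each trial
#'
#' Runs saccade detection on each trial's trace, classifies the behavioral
#' outcome, performs the landing and fixation checks, and computes the
#' change time relative to saccade offset and onset. Inclusion itself is
#' decided by [select_trials()].
#'
#' @param trials trial event table (one row per trial).
#' @param traces long eye-trace data frame (`trial_id`, `t_ms`, `x_deg`,
#'   `y_deg`), a named list of per-trial traces, or `NULL` to skip
#'   trace-based checks (events must then be supplied).
#' @param events optional precomputed saccade events with a `trial_id`
#'   column; detected from the traces when omitted.
#' @param threshold,min_duration,smoothing_halfwidth detector settings, see
#'   [detect_saccades()].
#' @param min_amplitude smallest displacement (deg) counted as the
#'   target-directed saccade; smaller events are ignored.
#' @param fixation_rule `"radius2"` (fixed window around the fixated point)
#'   or `"median0.5"` (per-axis deviation from the epoch median).
#' @param fixation_radius,median_radius radii (deg) for the two rules.
#' @param fixation_center,saccade_target fixated positions (deg) before and
#'   after the saccade.
#' @param deadline,distractor_window response rules, see [classify_response()].
#' @return `trials` with added columns: `outcome`, `n_valid_saccades`,
#'   `saccade_onset`, `saccade_offset`, `latency`, `peak_velocity`,
#'   `amplitude`, `landing_dist`, `fixation_pre_ok`, `fixation_post_ok`,
#'   `t_rel_offset`, `t_rel_onset`, `t_d_rel_offset`.
#' @export
classify_trials <- function(trials, traces = NULL, events = NULL,
                            threshold = 50, min_duration = 8,
                            smoothing_halfwidth = 2, min_amplitude = 1,
                            fixation_rule = c("radius2", "median0.5"),
                            fixation_radius = 2, median_radius = 0.5,
                            fixation_center = c(0, 0), saccade_target = NULL,
                            deadline = 600, distractor_window = 800) {
  fixation_rule <- match.arg(fixation_rule)
  if (is.null(traces) && is.null(events))
    stop("need traces or precomputed events")
  if (is.null(saccade_target)) saccade_target <- fixation_center + c(7, 0)
  n <- nrow(trials)
  checks <- empty_checks(n)

  if (is.null(traces)) {
    # events-only fast path: vectorized over trials
    big <- events[events$amplitude >= min_amplitude, , drop = FALSE]
    fct <- factor(big$trial_id, levels = trials$trial_id)
    checks$n_valid_saccades <- tabulate(fct, nbins = n)
    single <- which(checks$n_valid_saccades == 1)
    ord <- big[as.integer(fct) %in% single, , drop = FALSE]
    idx <- match(ord$trial_id, trials$trial_id)
    checks$saccade_onset[idx] <- ord$onset
    checks$saccade_offset[idx] <- ord$offset
    checks$latency[idx] <- ord$onset - trials$fp_jump_time[idx]
    checks$peak_velocity[idx] <- ord$peak_velocity
    checks$amplitude[idx] <- ord$amplitude
    checks$landing_dist[idx] <- sqrt((ord$x_end - saccade_target[1])^2 +
                                     (ord$y_end - saccade_target[2])^2)
    checks$fixation_pre_ok[single] <- TRUE
    checks$fixation_post_ok[single] <- TRUE
  } else {
    trace_list <- if (is.data.frame(traces))
      split(traces, factor(traces$trial_id, levels = trials$trial_id))
    else traces
    ev_list <- if (!is.null(events))
      split(events, factor(events$trial_id, levels = trials$trial_id))
    else NULL
    nsac <- integer(n); ons <- rep(NA_real_, n); offs <- rep(NA_real_, n)
    pk <- rep(NA_real_, n); amp <- rep(NA_real_, n); land <- rep(NA_real_, n)
    pre_ok <- rep(NA, n); post_ok <- rep(NA, n)
    for (i in seq_len(n)) {
      trace <- trace_list[[as.character(trials$trial_id[i])]]
      ev <- if (!is.null(ev_list)) ev_list[[as.character(trials$trial_id[i])]]
            else detect_saccades(trace, threshold = threshold,
                                 min_duration = min_duration,
                                 smoothing_halfwidth = smoothing_halfwidth,
                                 fp_jump_time = trials$fp_jump_time[i])
      big <- ev[ev$amplitude >= min_amplitude, , drop = FALSE]
      nsac[i] <- nrow(big)
      if (nrow(big) != 1) next
      ons[i] <- big$onset; offs[i] <- big$offset
      pk[i] <- big$peak_velocity; amp[i] <- big$amplitude
      land[i] <- sqrt((big$x_end - saccade_target[1])^2 +
                      (big$y_end - saccade_target[2])^2)
      t1 <- trace$t_ms[nrow(trace)]
      pre <- c(trace$t_ms[1], big$onset); post <- c(big$offset, t1 + 1)
      if (fixation_rule == "median0.5") {
        pre_ok[i] <- fixation_ok_median(trace, median_radius, pre)$ok
        post_ok[i] <- fixation_ok_median(trace, median_radius, post)$ok
      } else {
        pre_ok[i] <- fixation_ok(trace, fixation_center, fixation_radius, pre)$ok
        post_ok[i] <- fixation_ok(trace, saccade_target, fixation_radius, post)$ok
      }
    }
    checks <- data.frame(n_valid_saccades = nsac, saccade_onset = ons,
                         saccade_offset = offs, latency = ons - trials$fp_jump_time,
                         peak_velocity = pk, amplitude = amp,
                         landing_dist = land, fixation_pre_ok = pre_ok,
                         fixation_post_ok = post_ok)
  }
  out <- cbind(trials, checks)
  out$outcome <- classify_response(trials, deadline, distractor_window)
  out$t_rel_offset <- out$target_change_time - out$saccade_offset
  out$t_rel_onset <- out$target_change_time - out$saccade_onset
  out$t_d_rel_offset <- out$distractor_change_time - out$saccade_offset
  out
}

#' Apply the trial inclusion rules
#'
#' A trial enters the performance analysis only if the subject made exactly
#' one valid saccade (displacement at least the configured minimum
#' amplitude), that saccade's latency lies within `latency_window` of the
#' fixation-point jump, its endpoint lands within `landing_radius` of the
#' saccade target, both fixation epochs pass the fixation check, and the
#' behavioral outcome is a hit or a miss. Every excluded trial records the
#' first rule it failed.
#'
#' @param classified output of [classify_trials()].
#' @param latency_window inclusive latency bounds in ms, default
#'   `c(-50, 450)`.
#' @param landing_radius maximal distance (deg) of the saccade endpoint from
#'   the saccade target.
#' @return `classified` with added logical `included` and character
#'   `exclusion_reason` (`""` for included trials).
#' @export
select_trials <- function(classified, latency_window = c(-50, 450),
                          landing_radius = 2) {
  n <- nrow(classified)
  reason <- rep("", n)
  flag <- function(cond, label) reason <<- ifelse(reason == "" & cond, label, reason)
  flag(classified$n_valid_saccades == 0, "no_saccade")
  flag(classified$n_valid_saccades > 1, "multiple_saccades")
  flag(!is.na(classified$latency) &
         (classified$latency < latency_window[1] |
          classified$latency > latency_window[2]), "latency_out_of_window")
  flag(!is.na(classified$landing_dist) &
         classified$landing_dist > landing_radius, "landing_off_target")
  flag(!is.na(classified$fixation_pre_ok) & !classified$fixation_pre_ok,
       "fixation_break")
  flag(!is.na(classified$fixation_post_ok) & !classified$fixation_post_ok,
       "fixation_break")
  flag(classified$outcome == "early_response", "early_response")
  flag(classified$outcome == "distractor_response", "distractor_response")
  flag(classified$outcome %in% c("catch_correct", "catch_fa"), "catch_trial")
  classified$included <- reason == ""
  classified$exclusion_reason <- reason
  classified
}

#' Change time relative to the saccade
#'
#' Returns the target-change time (second-frame convention, already baked
#' into the stored change times) minus the detected saccade offset or onset.
#' Negative values mean the change preceded the landmark.
#'
#' @param classified output of [classify_trials()].
#' @param reference `"offset"` (default) or `"onset"`.
#' @return numeric vector of relative times (ms); `NA` where the trial has
#'   no saccade or no target change.
#' @export
align_to_saccade <- function(classified, reference = c("offset", "onset")) {
  reference <- match.arg(reference)
  if (reference == "offset") classified$t_rel_offset else classified$t_rel_onset
}
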