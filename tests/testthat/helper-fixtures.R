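# Shared fixture builders: all synthetic, built in code at test time.

tiny_scenario <- function(n = 100, seed = 1L, ...) {
  build_scenario("E1", overrides = utils::modifyList(
    list(n_trials = n, seed = seed), list(...)))
}

# Noise-free (or low-noise) single-saccade trace with known kinematics.
make_saccade_trace <- function(amplitude = 7, duration = 40, onset = 500,
                               len = 1200, noise = 0, glissade_amp = 0,
                               glissade_dur = 20, trial_id = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- 0:len
  x <- if (noise > 0) rnorm(length(t), 0, noise) else numeric(length(t))
  y <- if (noise > 0) rnorm(length(t), 0, noise) else numeric(length(t))
  u <- pmin(pmax((t - onset) / duration, 0), 1)
  x <- x + amplitude * (u - sin(2 * pi * u) / (2 * pi))
  if (glissade_amp > 0) {
    ug <- pmin(pmax((t - onset - duration) / glissade_dur, 0), 1)
    x <- x + glissade_amp * (ug - sin(2 * pi * ug) / (2 * pi))
  }
  data.frame(trial_id = trial_id, t_ms = t, x_deg = x, y_deg = y)
}

# Trace whose speed is a rectangular pulse: linear ramp at `speed` deg/s on
# [from, to), constant elsewhere.
make_pulse_trace <- function(speed = 100, from = 100, to = 140, len = 400) {
  t <- 0:len
  x <- cumsum(c(0, ifelse(t[-1] > from & t[-1] <= to, speed / 1000, 0)))
  data.frame(trial_id = 1L, t_ms = t, x_deg = x, y_deg = 0)
}

# Minimal trial table for classification tests.
make_trial <- function(trial_id = 1L, fp_jump = 1235, tc = NA, dc = NA,
                       resp = NA, catch = FALSE, loc = NA_character_) {
  data.frame(trial_id = trial_id, subject_id = "s01", experiment_id = "E1",
             fp_jump_time = fp_jump, rdp_onset = 647, catch = catch,
             target_change_time = tc, distractor_change_time = dc,
             distractor_location = loc, response_time = resp,
             stringsAsFactors = FALSE)
}

# Brute-force Boschloo oracle: full table enumeration over a dense grid.
# Deliberately independent of the package's conditional-decomposition path.
boschloo_bruteforce <- function(k1, n1, k2, n2,
                                grid = seq(1e-6, 1 - 1e-6, length.out = 2001)) {
  fobs <- phyper(k1, k1 + k2, n1 + n2 - k1 - k2, n1)
  tab <- expand.grid(x1 = 0:n1, x2 = 0:n2)
  f <- phyper(tab$x1, tab$x1 + tab$x2, n1 + n2 - tab$x1 - tab$x2, n1)
  keep <- f <= fobs + 1e-12
  t1 <- tab$x1[keep]; t2 <- tab$x2[keep]
  max(vapply(grid, function(p) sum(dbinom(t1, n1, p) * dbinom(t2, n2, p)), 0))
}
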