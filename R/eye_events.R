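## Saccade detection from 1000 Hz eye traces: smoothed central-difference
## velocity, maximal-run threshold crossing, fixation-window checks.

# data.frame constructor without the deparse/validation overhead of
# data.frame(); columns must already be equal-length vectors.
quick_df <- function(cols) {
  n <- length(cols[[1]])
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}

running_mean <- function(v, halfwidth) {
  if (halfwidth <= 0) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - halfwidth - 1L)
  hi <- pmin(n, seq_len(n) + halfwidth)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Eye speed from a position trace
#'
#' Differentiates the horizontal and vertical position with central
#' differences (one-sided at the endpoints), optionally smooths each
#' component with a moving average of the given half-width, and returns the
#' Euclidean norm in deg/s. The trace must be uniformly sampled at 1 ms.
#'
#' @param trace data frame with columns `t_ms`, `x_deg`, `y_deg`.
#' @param smoothing_halfwidth moving-average half-width in samples
#'   (window `2h + 1`); `0` disables smoothing.
#' @return numeric vector of speeds (deg/s), same length as the trace.
#' @export
compute_velocity <- function(trace, smoothing_halfwidth = 2) {
  n <- nrow(trace)
  if (n < 3) stop("trace shorter than 3 samples")
  if (any(abs(diff(trace$t_ms) - 1) > 1e-9))
    stop("trace must be uniformly sampled at 1 ms (no gaps)")
  deriv <- function(p) {
    d <- numeric(n)
    d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / 2
    d[1] <- p[2] - p[1]
    d[n] <- p[n] - p[n - 1]
    d * 1000  # deg/ms -> deg/s
  }
  vx <- running_mean(deriv(trace$x_deg), smoothing_halfwidth)
  vy <- running_mean(deriv(trace$y_deg), smoothing_halfwidth)
  sqrt(vx^2 + vy^2)
}

#' Velocity-threshold saccade detection
#'
#' Standard velocity-threshold algorithm: each maximal run of samples with
#' speed strictly above `threshold` and length at least `min_duration` yields
#' one event. Onset is the first supra-threshold sample; offset is the first
#' sample at which the speed has dropped below threshold again (half-open
#' run). With `min_gap > 0`, events separated by a sub-threshold gap of at
#' most `min_gap` ms are merged before the duration filter — useful to study
#' how including post-saccadic glissades moves the detected offset.
#'
#' @param trace data frame with `t_ms`, `x_deg`, `y_deg`.
#' @param threshold speed threshold in deg/s (> 0). The study design uses an
#'   individualized threshold between 40 and 70 deg/s; default 50.
#' @param min_duration minimum run length in ms.
#' @param smoothing_halfwidth passed to [compute_velocity()] when `speed` is
#'   not supplied.
#' @param min_gap merge events separated by gaps of at most this many ms.
#' @param fp_jump_time fixation-point jump time (ms) used to compute the
#'   saccade latency; `NA` leaves latency `NA`.
#' @param speed optional precomputed speed vector.
#' @return data frame of events sorted by onset: `onset`, `offset`,
#'   `peak_velocity`, `amplitude` (Euclidean displacement onset to offset),
#'   `latency`, `x_end`, `y_end`. Zero rows if nothing crosses.
#' @export
detect_saccades <- function(trace, threshold = 50, min_duration = 8,
                            smoothing_halfwidth = 2, min_gap = 0,
                            fp_jump_time = NA_real_, speed = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(speed)) speed <- compute_velocity(trace, smoothing_halfwidth)
  above <- speed > threshold
  empty <- quick_df(list(onset = numeric(0), offset = numeric(0),
                         peak_velocity = numeric(0), amplitude = numeric(0),
                         latency = numeric(0), x_end = numeric(0),
                         y_end = numeric(0)))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]
  e <- ends[r$values]
  if (min_gap > 0 && length(s) > 1) {
    keep_s <- s[1]; keep_e <- e[1]
    for (i in 2:length(s)) {
      if (s[i] - keep_e[length(keep_e)] - 1L <= min_gap) {
        keep_e[length(keep_e)] <- e[i]
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
      }
    }
    s <- keep_s; e <- keep_e
  }
  long <- (e - s + 1L) >= min_duration
  s <- s[long]; e <- e[long]
  if (!length(s)) return(empty)
  n <- nrow(trace)
  off_idx <- pmin(e + 1L, n)
  peak <- vapply(seq_along(s), function(i) max(speed[s[i]:e[i]]), 0)
  dx <- trace$x_deg[off_idx] - trace$x_deg[s]
  dy <- trace$y_deg[off_idx] - trace$y_deg[s]
  onset <- trace$t_ms[s]
  quick_df(list(onset = onset, offset = trace$t_ms[off_idx],
                peak_velocity = peak, amplitude = sqrt(dx^2 + dy^2),
                latency = onset - fp_jump_time,
                x_end = trace$x_deg[off_idx], y_end = trace$y_deg[off_idx]))
}

epoch_index <- function(trace, epoch) {
  if (length(epoch) != 2 || epoch[2] <= epoch[1]) stop("empty or reversed epoch")
  if (epoch[1] < trace$t_ms[1] || epoch[2] > trace$t_ms[nrow(trace)] + 1)
    stop("epoch outside trace span")
  idx <- which(trace$t_ms >= epoch[1] & trace$t_ms < epoch[2])
  if (!length(idx)) stop("empty epoch")
  idx
}

#' Fixation-window check around a fixed center
#'
#' Tests whether every sample in the epoch (half-open, `[from, to)`) lies
#' within `radius` degrees (Euclidean) of `center`.
#'
#' @param trace eye trace data frame.
#' @param center numeric `c(x, y)` in degrees.
#' @param radius window radius in degrees.
#' @param epoch numeric `c(from, to)` in ms.
#' @return list with `ok` (logical) and `first_violation` (time in ms of the
#'   first sample outside the window, or `NA`).
#' @export
fixation_ok <- function(trace, center, radius, epoch) {
  idx <- epoch_index(trace, epoch)
  d2 <- (trace$x_deg[idx] - center[1])^2 + (trace$y_deg[idx] - center[2])^2
  bad <- which(d2 > radius^2)
  list(ok = length(bad) == 0,
       first_violation = if (length(bad)) trace$t_ms[idx[bad[1]]] else NA_real_)
}

#' Fixation check against the per-epoch median position
#'
#' The stricter control criterion: within the epoch, neither the horizontal
#' nor the vertical eye position may deviate from its own epoch median by
#' more than `radius` (per-axis, compensating for across-trial calibration
#' drifts).
#'
#' @inheritParams fixation_ok
#' @return list with `ok` and `max_deviation` (largest per-axis deviation).
#' @export
fixation_ok_median <- function(trace, radius, epoch) {
  idx <- epoch_index(trace, epoch)
  dx <- abs(trace$x_deg[idx] - stats::median(trace$x_deg[idx]))
  dy <- abs(trace$y_deg[idx] - stats::median(trace$y_deg[idx]))
  mx <- max(dx, dy)
  list(ok = mx <= radius, max_deviation = mx)
}
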