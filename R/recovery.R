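## Binned performance curves, the sequential exact-test recovery estimator,
## the 80%-of-baseline interpolation estimator, latency splits, and the
## distractor false-positive comparison.

#' Bin hit/miss outcomes over time relative to a saccade landmark
#'
#' Tiles `span` with left-closed, right-open bins of width `bin_width`
#' starting at the span's left edge, assigns each trial to the unique bin
#' with `bin_start <= t_rel < bin_start + bin_width`, and computes the hit
#' rate and 95% Wilson score band per bin. Empty bins carry `n = 0` and an
#' undefined rate.
#'
#' @param t_rel change times relative to the saccade landmark (ms).
#' @param hit logical (or 0/1) vector: was the change detected.
#' @param bin_width bin width in ms (> 0).
#' @param span numeric `c(from, to)` in ms; trials outside are dropped.
#' @param confidence confidence level of the Wilson bands.
#' @param reference label of the alignment landmark (`"offset"`/`"onset"`).
#' @return data frame of class `binned_performance` with columns
#'   `bin_start`, `bin_mid`, `n`, `hits`, `rate`, `lo`, `hi`.
#' @export
bin_performance <- function(t_rel, hit, bin_width, span,
                            confidence = 0.95, reference = "offset") {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(span) != 2 || span[2] <= span[1]) stop("reversed or empty span")
  stopifnot(length(t_rel) == length(hit))
  hit <- as.logical(hit)
  keep <- !is.na(t_rel) & !is.na(hit) & t_rel >= span[1] & t_rel < span[2]
  t_rel <- t_rel[keep]; hit <- hit[keep]
  nb <- ceiling((span[2] - span[1]) / bin_width)
  idx <- floor((t_rel - span[1]) / bin_width) + 1L
  n <- tabulate(idx, nbins = nb)
  hits <- tabulate(idx[hit], nbins = nb)
  bin_start <- span[1] + (seq_len(nb) - 1L) * bin_width
  rate <- ifelse(n > 0, hits / n, NA_real_)
  lo <- hi <- rep(NA_real_, nb)
  nz <- n > 0
  if (any(nz)) {
    w <- wilson_interval(hits[nz], n[nz], confidence)
    lo[nz] <- w$lo; hi[nz] <- w$hi
  }
  structure(data.frame(bin_start = bin_start,
                       bin_mid = bin_start + bin_width / 2,
                       n = n, hits = hits, rate = rate, lo = lo, hi = hi),
            class = c("binned_performance", "data.frame"),
            bin_width = bin_width, reference = reference,
            confidence = confidence)
}

pool_counts <- function(t_rel, hit, window) {
  keep <- !is.na(t_rel) & t_rel >= window[1] & t_rel < window[2]
  c(k = sum(hit[keep]), n = sum(keep))
}

recovery_scan <- function(t_rel, hit, bin_width, alpha, baseline, test_window,
                          grid_size) {
  k2 <- baseline[["k"]]; n2 <- baseline[["n"]]
  starts <- seq(test_window[1], test_window[2] - bin_width, by = bin_width)
  per_bin <- data.frame(bin_start = starts, k = NA_integer_, n = NA_integer_,
                        p_value = NA_real_, significant = NA)
  for (i in seq_along(starts)) {
    cnt <- pool_counts(t_rel, hit, c(starts[i], starts[i] + bin_width))
    per_bin$k[i] <- cnt[["k"]]; per_bin$n[i] <- cnt[["n"]]
    if (cnt[["n"]] > 0) {
      p <- boschloo_one_sided(cnt[["k"]], cnt[["n"]], k2, n2,
                              direction = "p1_less", grid_size = grid_size)
      per_bin$p_value[i] <- p
      per_bin$significant[i] <- p <= alpha   # p must strictly exceed alpha to stop
    }
  }
  ok <- which(!is.na(per_bin$significant) & !per_bin$significant)
  list(recovery_time = if (length(ok)) per_bin$bin_start[ok[1]] else NA_real_,
       per_bin = per_bin)
}

#' Recovery time of detection performance after the saccade
#'
#' Pools the baseline hit rate over `baseline_window` (relative to the
#' saccade landmark), then walks successive non-overlapping bins of
#' `bin_width` ms across `test_window`, comparing each bin with the baseline
#' using a one-sided Boschloo exact test (bin performance lower than
#' baseline). The start of the first bin whose p-value strictly exceeds
#' `alpha` is the recovery time; if every bin is significantly below
#' baseline the performance has not recovered within the test window. A
#' confirmation pass with `confirm_bin_width` ms bins is run alongside, with
#' a warning if the two disagree by more than one coarse bin (the coarse
#' result is authoritative).
#'
#' Bins with no trials cannot be tested; they are recorded with `NA` and do
#' not stop the scan.
#'
#' @param t_rel change times relative to the saccade landmark (ms); only
#'   included hit/miss trials should be supplied.
#' @param hit logical vector of hits.
#' @param bin_width test bin width in ms (default 10).
#' @param alpha non-significance cutoff (default 0.1; a bin with `p == alpha`
#'   still counts as significant).
#' @param baseline_window pooled-baseline window, default `c(100, 500)` ms.
#' @param test_window scanned window, default `c(0, 100)` ms.
#' @param confirm_bin_width width of the confirmation pass (default 5 ms);
#'   `NULL` skips it.
#' @param grid_size nuisance grid for the exact tests.
#' @return object of class `recovery_estimate`: `recovery_time` (ms or `NA`),
#'   `status`, `baseline` (k, n, rate, window), `per_bin` test trail,
#'   `confirmation` (same structure at the fine width), `alpha`, `bin_width`.
#' @export
estimate_recovery <- function(t_rel, hit, bin_width = 10, alpha = 0.1,
                              baseline_window = c(100, 500),
                              test_window = c(0, 100),
                              confirm_bin_width = 5, grid_size = 1001) {
  stopifnot(length(t_rel) == length(hit))
  hit <- as.logical(hit)
  keep <- !is.na(t_rel) & !is.na(hit)
  t_rel <- t_rel[keep]; hit <- hit[keep]
  base <- pool_counts(t_rel, hit, baseline_window)
  if (base[["n"]] == 0) stop("empty baseline window")
  main <- recovery_scan(t_rel, hit, bin_width, alpha, base, test_window,
                        grid_size)
  confirmation <- NULL
  if (!is.null(confirm_bin_width)) {
    conf <- recovery_scan(t_rel, hit, confirm_bin_width, alpha, base,
                          test_window, grid_size)
    confirmation <- list(bin_width = confirm_bin_width,
                         recovery_time = conf$recovery_time,
                         per_bin = conf$per_bin)
    if (!is.na(main$recovery_time) && !is.na(conf$recovery_time) &&
        abs(main$recovery_time - conf$recovery_time) > bin_width)
      warning(sprintf(
        "confirmation pass (%g ms bins) disagrees: %g vs %g ms; the %g ms result is authoritative",
        confirm_bin_width, conf$recovery_time, main$recovery_time, bin_width))
  }
  structure(list(
    recovery_time = main$recovery_time,
    status = if (is.na(main$recovery_time)) "not recovered" else "recovered",
    baseline = list(k = base[["k"]], n = base[["n"]],
                    rate = base[["k"]] / base[["n"]], window = baseline_window),
    per_bin = main$per_bin, confirmation = confirmation,
    alpha = alpha, bin_width = bin_width, test_window = test_window),
    class = "recovery_estimate")
}

#' @export
print.recovery_estimate <- function(x, ...) {
  cat("<recovery_estimate>\n")
  cat(sprintf("  baseline: %d/%d = %.3f over [%g, %g) ms\n", x$baseline$k,
              x$baseline$n, x$baseline$rate, x$baseline$window[1],
              x$baseline$window[2]))
  cat(sprintf("  %g ms bins over [%g, %g) ms, one-sided Boschloo, cutoff p > %g\n",
              x$bin_width, x$test_window[1], x$test_window[2], x$alpha))
  if (is.na(x$recovery_time)) cat("  not recovered within the test window\n")
  else cat(sprintf("  recovery time: %g ms\n", x$recovery_time))
  if (!is.null(x$confirmation))
    cat(sprintf("  confirmation (%g ms bins): %s ms\n", x$confirmation$bin_width,
                format(x$confirmation$recovery_time)))
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' Time at which performance reaches 80% of baseline (linear interpolation)
#'
#' Connects the post-saccadic bin centers of a binned performance curve with
#' straight lines and returns the first time after the landmark at which the
#' interpolated rate crosses `0.8 * baseline_rate` from below. If the first
#' non-empty bin is already at or above the criterion its bin center is
#' returned (there is no earlier data to interpolate from).
#'
#' @param binned a [bin_performance()] result.
#' @param baseline_rate pooled baseline hit rate (> 0).
#' @param criterion fraction of baseline to reach (default 0.8).
#' @return crossing time in ms, or `NA` (with a warning) if the curve never
#'   reaches the criterion.
#' @export
recovery_interp80 <- function(binned, baseline_rate, criterion = 0.8) {
  stopifnot(baseline_rate > 0)
  b <- binned[binned$bin_start >= 0 & binned$n > 0, ]
  if (!nrow(b)) stop("no post-saccadic bins with data")
  target <- criterion * baseline_rate
  if (b$rate[1] >= target) return(b$bin_mid[1])
  if (nrow(b) > 1) for (i in 2:nrow(b)) {
    if (b$rate[i] >= target && b$rate[i - 1] < target) {
      frac <- (target - b$rate[i - 1]) / (b$rate[i] - b$rate[i - 1])
      return(b$bin_mid[i - 1] + frac * (b$bin_mid[i] - b$bin_mid[i - 1]))
    }
  }
  warning("performance never reaches the criterion; returning NA")
  NA_real_
}

#' Binned performance split by saccade latency group
#'
#' Partitions included trials into half-open saccade-latency intervals
#' (defaults: predictive 0-75 ms, express 75-125 ms, regular 125-250 ms
#' after the fixation-point jump) and bins each group's performance
#' separately.
#'
#' @param latency saccade latencies (ms).
#' @param t_rel change times relative to the saccade landmark (ms).
#' @param hit logical hit vector.
#' @param groups list of `c(lo, hi)` latency intervals; must not overlap.
#' @param bin_width bin width in ms (default 50).
#' @param span plotted span, default `c(-300, 500)` ms.
#' @return named list of [bin_performance()] results (possibly with all-empty
#'   bins for groups without trials).
#' @export
latency_split_curves <- function(latency, t_rel, hit,
                                 groups = list(predictive = c(0, 75),
                                               express = c(75, 125),
                                               regular = c(125, 250)),
                                 bin_width = 50, span = c(-300, 500)) {
  gm <- do.call(rbind, groups)
  ord <- order(gm[, 1])
  if (any(gm[ord, 1][-1] < gm[ord, 2][-length(groups)]))
    stop("overlapping latency groups")
  if (is.null(names(groups)))
    names(groups) <- vapply(groups, function(g) paste0(g[1], "-", g[2]), "")
  out <- lapply(groups, function(g) {
    sel <- !is.na(latency) & latency >= g[1] & latency < g[2]
    bin_performance(t_rel[sel], hit[sel], bin_width, span)
  })
  out
}

#' Post-saccadic distractor false-positive comparison
#'
#' For trials whose distractor change falls inside `window` (ms relative to
#' saccade offset), computes the per-location rate of responses attributed
#' to the distractor and compares each non-control location against the
#' control location with a one-sided Boschloo test (rate greater than
#' control). A raised rate at the location sharing the target's pre-saccadic
#' retinotopic coordinates would indicate retinotopic persistence of the
#' attentional focus.
#'
#' @param distractor_location character vector of locations.
#' @param t_d_rel distractor change time relative to saccade offset (ms).
#' @param distractor_response logical: was the response attributed to the
#'   distractor.
#' @param window analysis window, default `c(0, 150)` ms.
#' @param control control location name (default `"below"`).
#' @param grid_size nuisance grid for the exact tests.
#' @return data frame of class `fp_report`: `location`, `n_changes`,
#'   `n_responses`, `rate`, `p_vs_control` (`NA` for the control itself and
#'   for locations without data).
#' @export
false_positive_analysis <- function(distractor_location, t_d_rel,
                                    distractor_response,
                                    window = c(0, 150), control = "below",
                                    grid_size = 1001) {
  keep <- !is.na(distractor_location) & !is.na(t_d_rel) &
    t_d_rel >= window[1] & t_d_rel < window[2]
  loc <- distractor_location[keep]
  resp <- distractor_response[keep]
  locations <- sort(unique(distractor_location[!is.na(distractor_location)]))
  res <- data.frame(location = locations,
                    n_changes = vapply(locations, function(l) sum(loc == l), 0L),
                    n_responses = vapply(locations, function(l)
                      sum(resp[loc == l]), 0L),
                    stringsAsFactors = FALSE)
  res$rate <- ifelse(res$n_changes > 0, res$n_responses / res$n_changes,
                     NA_real_)
  res$p_vs_control <- NA_real_
  ctrl <- res[res$location == control, ]
  if (nrow(ctrl) == 1 && ctrl$n_changes > 0) {
    for (i in seq_len(nrow(res))) {
      if (res$location[i] == control || res$n_changes[i] == 0) next
      res$p_vs_control[i] <- boschloo_one_sided(
        res$n_responses[i], res$n_changes[i], ctrl$n_responses, ctrl$n_changes,
        direction = "p1_greater", grid_size = grid_size)
    }
  }
  structure(res, class = c("fp_report", "data.frame"),
            window = window, control = control)
}
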