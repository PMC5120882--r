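## File-format plumbing: CSV interchange tables, YAML scenario configs,
## JSON manifests and analysis reports, and the command-style entry points.

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

read_csv_plain <- function(path, required = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("missing column(s) in ", basename(path), ": ",
           paste(missing, collapse = ", "))
  }
  df
}

scenario_to_list <- function(config) {
  out <- unclass(config)
  out$performance_curve <- unclass(out$performance_curve)
  out$saccade_latency_mixture <- lapply(out$saccade_latency_mixture, as.list)
  out$distractor_locations <- as.list(out$distractor_locations)
  out$glissade <- as.list(out$glissade)
  out
}

scenario_from_list <- function(lst) {
  pc <- lst$performance_curve
  pc$dip_start_ref <- NULL
  lst$performance_curve <- do.call(performance_curve, pc)
  lst$saccade_latency_mixture <- lapply(lst$saccade_latency_mixture, unlist)
  lst$distractor_locations <- unlist(lst$distractor_locations)
  lst$glissade <- unlist(lst$glissade)
  cfg <- structure(lst, class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Write or read a simulated dataset on disk
#'
#' A dataset directory holds `traces.csv` (`trial_id`, `t_ms`, `x_deg`,
#' `y_deg`), `trials.csv` (one row per trial), `scenario.yaml` (the full
#' generative config), and `manifest.json` binding the three files with the
#' seed.
#'
#' @param dataset a [simulate_experiment()] result.
#' @param dir output directory, created if needed.
#' @return `write_dataset()`: the directory, invisibly. `read_dataset()`:
#'   list with `traces`, `trials`, `config`, `manifest`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- dataset$traces
  if (is.null(tr))
    tr <- data.frame(trial_id = integer(0), t_ms = numeric(0),
                     x_deg = numeric(0), y_deg = numeric(0))
  write_csv_plain(tr, file.path(dir, "traces.csv"))
  write_csv_plain(dataset$trials, file.path(dir, "trials.csv"))
  yaml::write_yaml(scenario_to_list(dataset$config),
                   file.path(dir, "scenario.yaml"))
  manifest <- list(scenario = "scenario.yaml", traces = "traces.csv",
                   trials = "trials.csv",
                   experiment_id = dataset$config$experiment_id,
                   n_trials = nrow(dataset$trials),
                   seed = as.integer(dataset$config$seed))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  traces <- read_csv_plain(file.path(dir, manifest$traces),
                           required = c("trial_id", "t_ms", "x_deg", "y_deg"))
  trials <- read_csv_plain(file.path(dir, manifest$trials),
                           required = c("trial_id", "fp_jump_time", "catch"))
  config <- scenario_from_list(yaml::read_yaml(file.path(dir, manifest$scenario)))
  if (nrow(traces) &&
      !all(unique(traces$trial_id) %in% trials$trial_id))
    stop("trial ids mismatched between traces and trials files")
  list(traces = traces, trials = trials, config = config, manifest = manifest)
}

report_list <- function(analysis) {
  sig <- function(x) if (is.numeric(x)) signif(x, 6) else x
  curve_tab <- function(b)
    lapply(as.list(b[c("bin_start", "n", "hits", "rate", "lo", "hi")]), sig)
  rec_list <- function(r) list(
    recovery_time = sig(r$recovery_time), status = r$status,
    alpha = r$alpha, bin_width = r$bin_width,
    baseline = lapply(r$baseline, sig),
    per_bin = lapply(as.list(r$per_bin), sig),
    confirmation = if (is.null(r$confirmation)) NULL else list(
      bin_width = r$confirmation$bin_width,
      recovery_time = sig(r$confirmation$recovery_time),
      per_bin = lapply(as.list(r$confirmation$per_bin), sig)))
  list(settings = analysis$settings, counts = analysis$counts,
       binned = curve_tab(analysis$binned),
       recovery = rec_list(analysis$recovery),
       interp80 = sig(analysis$interp80),
       latency_curves = lapply(analysis$latency_curves, curve_tab),
       fp_report = lapply(as.list(analysis$fp_report), sig))
}

#' Serialize an analysis to JSON and curve CSVs
#'
#' Writes `report.json` (settings, stage counts, binned curve, recovery
#' estimate with its per-bin exact-test trail, false-positive report; numbers
#' at 6 significant digits) and `curve.csv` mirroring the binned-performance
#' table layout (`bin_start`, `n`, `hits`, `rate`, `wilson_lo`, `wilson_hi`).
#'
#' @param analysis an [analyze_experiment()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_list(analysis), file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  b <- analysis$binned
  curve <- data.frame(bin_start = b$bin_start, n = b$n, hits = b$hits,
                      rate = b$rate, wilson_lo = b$lo, wilson_hi = b$hi)
  write_csv_plain(curve, file.path(dir, "curve.csv"))
  invisible(dir)
}

#' Command-style entry points
#'
#' Thin wrappers binding the modules into the two workflows. `cmd_simulate()`
#' generates a dataset and writes it to disk (identical seeds give
#' byte-identical CSV bodies); `cmd_analyze()` reads a dataset directory (or
#' explicit trace/trial CSV paths), runs the full analysis, and writes the
#' JSON report and curve CSV; `cmd_recovery_report()` re-derives a recovery
#' estimate from a saved curve table, pooling its own baseline from the
#' 100-500 ms bins. A ready-made command-line front end for these functions
#' ships at `system.file("cli", "perisacc.R", package = "perisacc")`.
#'
#' @param experiment experiment id passed to [build_scenario()].
#' @param n number of trials.
#' @param seed RNG seed.
#' @param out output directory.
#' @param overrides extra scenario overrides.
#' @return `cmd_simulate()`: the dataset directory. `cmd_analyze()`: the
#'   analysis object. `cmd_recovery_report()`: a `recovery_estimate`.
#' @export
cmd_simulate <- function(experiment, n, seed, out, overrides = list()) {
  cfg <- build_scenario(experiment,
                        utils::modifyList(overrides,
                                          list(n_trials = n, seed = seed)))
  ds <- simulate_experiment(cfg)
  write_dataset(ds, out)
  message(sprintf("wrote %s dataset (%d trials, seed %d) to %s",
                  experiment, n, as.integer(seed), out))
  invisible(out)
}

#' @rdname cmd_simulate
#' @param dir dataset directory written by [cmd_simulate()]; alternatively
#'   pass `traces` and `trials` CSV paths.
#' @param traces,trials CSV paths (used when `dir` is `NULL`).
#' @param ... analysis settings forwarded to [analyze_experiment()].
#' @export
cmd_analyze <- function(dir = NULL, traces = NULL, trials = NULL,
                        out = NULL, ...) {
  if (!is.null(dir)) {
    ds <- read_dataset(dir)
    tr <- ds$traces; tl <- ds$trials
  } else {
    tr <- read_csv_plain(traces, c("trial_id", "t_ms", "x_deg", "y_deg"))
    tl <- read_csv_plain(trials, c("trial_id", "fp_jump_time", "catch"))
    if (nrow(tr) && !all(unique(tr$trial_id) %in% tl$trial_id))
      stop("trial ids mismatched between traces and trials files")
  }
  if (!nrow(tl)) stop("no trials to analyze")
  analysis <- analyze_experiment(tr, tl, ...)
  if (!is.null(out)) write_report(analysis, out)
  analysis
}

#' @rdname cmd_simulate
#' @param curve_csv saved curve table (`bin_start`, `n`, `hits`, ...).
#' @param bin_width,alpha,baseline_window,test_window estimator settings.
#' @export
cmd_recovery_report <- function(curve_csv, bin_width = 10, alpha = 0.1,
                                baseline_window = c(100, 500),
                                test_window = c(0, 100)) {
  curve <- read_csv_plain(curve_csv, c("bin_start", "n", "hits"))
  # expand bin counts back to pseudo-trials at bin centers
  reps <- rep(seq_len(nrow(curve)), curve$n)
  t_rel <- curve$bin_start[reps] + 0.5 * min(diff(curve$bin_start))
  hit <- sequence(curve$n) <= curve$hits[reps]
  estimate_recovery(t_rel, hit, bin_width = bin_width, alpha = alpha,
                    baseline_window = baseline_window,
                    test_window = test_window,
                    confirm_bin_width = NULL)
}
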