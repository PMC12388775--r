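# On-disk formats: recordings and cycles as CSV (`time_s,pressure_pa,flow_cm3s`),
# thresholds and labeled-set manifests as JSON. All numeric output is written
# with 17 significant digits so read(write(x)) round-trips to full double
# precision.

SCENARIOS <- c("none", "saturated_or_weak", "not_worn_properly",
               "multiple_breaths")

#' Construct a raw two-channel recording
#'
#' A `raw_recording` holds synchronized transnasal pressure (Pa) and nasal
#' airflow (cm3/s) series sampled at a fixed rate (100 Hz for the supported
#' acquisition hardware).
#'
#' @param pressure numeric vector, pressure in Pa.
#' @param flow numeric vector, flow in cm3/s; must match `pressure` in length.
#' @param sampling_rate_hz positive sampling rate, default 100.
#' @param t0_s start-time offset in seconds.
#' @return An object of class `raw_recording` with elements `pressure`,
#'   `flow`, `sampling_rate_hz`, `t0_s`.
#' @export
raw_recording <- function(pressure, flow, sampling_rate_hz = 100, t0_s = 0) {
  pressure <- as.numeric(pressure)
  flow <- as.numeric(flow)
  if (length(pressure) != length(flow))
    stop_format("pressure and flow must have equal length")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive number")
  assert_finite(pressure, "pressure")
  assert_finite(flow, "flow")
  structure(list(pressure = pressure, flow = flow,
                 sampling_rate_hz = sampling_rate_hz, t0_s = t0_s),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$pressure), x$sampling_rate_hz,
              length(x$pressure) / x$sampling_rate_hz))
  invisible(x)
}

#' Construct an FFT/VPP threshold set
#'
#' The six bounds of the effective-cycle decision rule: dominant-frequency
#' window (Hz, applied to both channels) and peak-to-peak amplitude windows
#' for pressure (Pa) and flow (cm3/s).
#'
#' @param minft_hz,maxft_hz dominant-frequency bounds in Hz.
#' @param minpvt_pa,maxpvt_pa pressure peak-to-peak bounds in Pa.
#' @param minfvt_cm3s,maxfvt_cm3s flow peak-to-peak bounds in cm3/s.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(minft_hz, maxft_hz, minpvt_pa, maxpvt_pa,
                          minfvt_cm3s, maxfvt_cm3s) {
  vals <- c(minft_hz = minft_hz, maxft_hz = maxft_hz,
            minpvt_pa = minpvt_pa, maxpvt_pa = maxpvt_pa,
            minfvt_cm3s = minfvt_cm3s, maxfvt_cm3s = maxfvt_cm3s)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("all thresholds must be finite and non-negative")
  if (minft_hz >= maxft_hz) stop("minft_hz must be < maxft_hz")
  if (minpvt_pa >= maxpvt_pa) stop("minpvt_pa must be < maxpvt_pa")
  if (minfvt_cm3s >= maxfvt_cm3s) stop("minfvt_cm3s must be < maxfvt_cm3s")
  structure(as.list(vals), class = "threshold_set")
}

#' Default (optimized) threshold set
#'
#' The threshold combination found optimal by exhaustive grid search on a
#' physician-labeled corpus: 0.12--0.6 Hz, 300--1000 Pa, 100--1650 cm3/s.
#' @return A `threshold_set`.
#' @export
default_thresholds <- function() {
  threshold_set(0.12, 0.6, 300, 1000, 100, 1650)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> f: [%g, %g] Hz; pressure VPP: [%g, %g] Pa; flow VPP: [%g, %g] cm3/s\n",
    x$minft_hz, x$maxft_hz, x$minpvt_pa, x$maxpvt_pa,
    x$minfvt_cm3s, x$maxfvt_cm3s))
  invisible(x)
}

#' Construct a labeled cycle
#'
#' Pairs a segmented respiratory cycle with its ground-truth label and (for
#' ineffective cycles) the interference scenario that produced it.
#'
#' @param cycle a [respiratory_cycle()].
#' @param truth_label `"effective"` or `"ineffective"`.
#' @param scenario one of `"none"`, `"saturated_or_weak"`,
#'   `"not_worn_properly"`, `"multiple_breaths"`. Must be `"none"` iff the
#'   label is `"effective"`.
#' @param seed optional integer recorded for provenance.
#' @return An object of class `labeled_cycle`.
#' @export
labeled_cycle <- function(cycle, truth_label, scenario = "none", seed = NA) {
  stopifnot(inherits(cycle, "respiratory_cycle"))
  truth_label <- match.arg(truth_label, c("effective", "ineffective"))
  scenario <- match.arg(scenario, SCENARIOS)
  if ((scenario == "none") != (truth_label == "effective"))
    stop("scenario must be 'none' if and only if truth_label is 'effective'")
  structure(list(cycle = cycle, truth_label = truth_label,
                 scenario = scenario, seed = seed),
            class = "labeled_cycle")
}

fmt_num <- function(x) sprintf("%.17g", x)

write_channels_csv <- function(pressure, flow, sampling_rate_hz, path,
                               t0_s = 0) {
  n <- length(pressure)
  t <- t0_s + (seq_len(n) - 1) / sampling_rate_hz
  lines <- c("time_s,pressure_pa,flow_cm3s",
             paste(fmt_num(t), fmt_num(pressure), fmt_num(flow), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-channel recording from CSV
#'
#' Expects the header `time_s,pressure_pa,flow_cm3s` with rows in time order;
#' the time column is validated against the declared sampling rate to within
#' 1e-6 s per step.
#'
#' @param path CSV file path.
#' @param sampling_rate_hz declared sampling rate, default 100 Hz.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, sampling_rate_hz = 100) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time_s", "pressure_pa", "flow_cm3s")
  if (!all(need %in% names(df)))
    stop_format("missing column(s): ",
                paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) stop_format("no samples")
  t <- df$time_s
  if (nrow(df) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop_format("time column is not strictly increasing")
    if (any(abs(dt - 1 / sampling_rate_hz) > 1e-6))
      stop_format("time steps inconsistent with declared sampling rate ",
                  sampling_rate_hz, " Hz")
  }
  raw_recording(df$pressure_pa, df$flow_cm3s, sampling_rate_hz, t0_s = t[1L])
}

#' Write a recording to CSV
#'
#' @param rec a [raw_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  write_channels_csv(rec$pressure, rec$flow, rec$sampling_rate_hz, path,
                     t0_s = rec$t0_s)
}

#' Write a labeled cycle set (one CSV per cycle + JSON manifest)
#'
#' @param cycles non-empty list of [labeled_cycle()] objects.
#' @param dir output directory (created if needed).
#' @param name base name for the manifest, default `"cycles"`.
#' @return Path of the written manifest JSON, invisibly.
#' @export
write_labeled_cycles <- function(cycles, dir, name = "cycles") {
  if (length(cycles) == 0L) stop("empty cycle list")
  stopifnot(all(vapply(cycles, inherits, logical(1), "labeled_cycle")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(cycles))
  for (i in seq_along(cycles)) {
    lc <- cycles[[i]]
    file_i <- sprintf("%s_%04d.csv", name, i)
    write_channels_csv(lc$cycle$pressure, lc$cycle$flow,
                       lc$cycle$sampling_rate_hz,
                       file.path(dir, file_i))
    entries[[i]] <- list(file = file_i,
                         truth_label = lc$truth_label,
                         scenario = lc$scenario,
                         seed = lc$seed,
                         start_index = lc$cycle$start_index,
                         sampling_rate_hz = lc$cycle$sampling_rate_hz)
  }
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(list(format = "rhinoflow_labeled_cycles",
                            cycles = entries),
                       manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a labeled cycle set written by [write_labeled_cycles()]
#'
#' @param manifest path to the manifest JSON.
#' @return List of [labeled_cycle()] objects.
#' @export
read_labeled_cycles <- function(manifest) {
  if (!file.exists(manifest)) stop_format("manifest not found: ", manifest)
  m <- jsonlite::read_json(manifest)
  if (!identical(m$format, "rhinoflow_labeled_cycles"))
    stop_format("not a labeled-cycle manifest")
  dir <- dirname(manifest)
  lapply(m$cycles, function(e) {
    rec <- read_recording(file.path(dir, e$file),
                          e$sampling_rate_hz %||% 100)
    cyc <- respiratory_cycle(rec$pressure, rec$flow, rec$sampling_rate_hz,
                             start_index = e$start_index %||% 1L)
    labeled_cycle(cyc, e$truth_label, e$scenario %||% "none",
                  seed = e$seed %||% NA)
  })
}

#' Read a threshold set from JSON (or return the optimized defaults)
#'
#' @param path JSON file with the six keys `minft_hz`, `maxft_hz`,
#'   `minpvt_pa`, `maxpvt_pa`, `minfvt_cm3s`, `maxfvt_cm3s`; `NULL` (default)
#'   returns [default_thresholds()].
#' @return A `threshold_set`.
#' @export
read_thresholds <- function(path = NULL) {
  if (is.null(path)) return(default_thresholds())
  if (!file.exists(path)) stop_format("file not found: ", path)
  x <- jsonlite::read_json(path)
  need <- c("minft_hz", "maxft_hz", "minpvt_pa", "maxpvt_pa",
            "minfvt_cm3s", "maxfvt_cm3s")
  if (!all(need %in% names(x)))
    stop_format("threshold JSON missing key(s): ",
                paste(setdiff(need, names(x)), collapse = ", "))
  threshold_set(x$minft_hz, x$maxft_hz, x$minpvt_pa, x$maxpvt_pa,
                x$minfvt_cm3s, x$maxfvt_cm3s)
}

#' Write a threshold set to JSON
#'
#' @param ts a `threshold_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(ts, path) {
  stopifnot(inherits(ts, "threshold_set"))
  jsonlite::write_json(unclass(ts), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
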