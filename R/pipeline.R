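# End-to-end pipeline: DC removal -> segmentation -> effective-cycle
# filtering -> per-cycle mean/Broms resistance and averaged-cycle
# vertex/effective resistance, with counts and rejection reasons logged.

#' Pipeline configuration
#'
#' @param sampling_rate_hz sampling rate, default 100 Hz.
#' @param thresholds a [threshold_set()], default the optimized set.
#' @param min_cycle_s minimum cycle duration, default 0.5 s.
#' @param max_cycles optional cap on accepted effective cycles.
#' @param baseline_window_s DC-estimation window, default 2 s.
#' @param remove_dc whether to subtract the baseline, default TRUE.
#' @param p_ref_pa reference pressure for mean resistance, default 150 Pa.
#' @param broms_r_ref,broms_band,broms_unit_pa,broms_unit_cm3s Broms fit
#'   settings (reference radius 2, band 0.25, 100 Pa and 100 cm3/s per
#'   radial unit).
#' @param resample_n resampling length, default 2000.
#' @param seed RNG seed recorded in results, default 1.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sampling_rate_hz = 100,
                            thresholds = default_thresholds(),
                            min_cycle_s = 0.5, max_cycles = NULL,
                            baseline_window_s = 2, remove_dc = TRUE,
                            p_ref_pa = 150, broms_r_ref = 2,
                            broms_band = 0.25, broms_unit_pa = 100,
                            broms_unit_cm3s = 100, resample_n = 2000L,
                            seed = 1L) {
  stopifnot(inherits(thresholds, "threshold_set"))
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 thresholds = thresholds, min_cycle_s = min_cycle_s,
                 max_cycles = max_cycles,
                 baseline_window_s = baseline_window_s,
                 remove_dc = remove_dc, p_ref_pa = p_ref_pa,
                 broms_r_ref = broms_r_ref, broms_band = broms_band,
                 broms_unit_pa = broms_unit_pa,
                 broms_unit_cm3s = broms_unit_cm3s,
                 resample_n = as.integer(resample_n),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_resistance <- function(config) {
  list(p_ref_pa = config$p_ref_pa, broms_r_ref = config$broms_r_ref,
       broms_band = config$broms_band, broms_unit_pa = config$broms_unit_pa,
       broms_unit_cm3s = config$broms_unit_cm3s,
       resample_n = config$resample_n)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path)
  # jsonlite parses whole numbers as integers; the config stores doubles
  x <- lapply(x, function(v) if (is.integer(v)) as.numeric(v) else v)
  ts <- x$thresholds
  pipeline_config(
    sampling_rate_hz = x$sampling_rate_hz %||% 100,
    thresholds = threshold_set(ts$minft_hz, ts$maxft_hz, ts$minpvt_pa,
                               ts$maxpvt_pa, ts$minfvt_cm3s, ts$maxfvt_cm3s),
    min_cycle_s = x$min_cycle_s %||% 0.5,
    max_cycles = x$max_cycles,
    baseline_window_s = x$baseline_window_s %||% 2,
    remove_dc = x$remove_dc %||% TRUE,
    p_ref_pa = x$p_ref_pa %||% 150,
    broms_r_ref = x$broms_r_ref %||% 2,
    broms_band = x$broms_band %||% 0.25,
    broms_unit_pa = x$broms_unit_pa %||% 100,
    broms_unit_cm3s = x$broms_unit_cm3s %||% 100,
    resample_n = x$resample_n %||% 2000L,
    seed = x$seed %||% 1L)
}

#' Run the full measurement pipeline on a recording
#'
#' Segments the (optionally DC-corrected) recording, filters effective
#' cycles, and computes the four resistance indicators. Raises a classed
#' error (`rhinoflow_no_effective_cycles`) listing per-cycle failure reasons
#' when no cycle passes validation.
#'
#' @param config a [pipeline_config()].
#' @param input a [raw_recording()] or a path to a recording CSV.
#' @return List with `resistances` (a `resistance_result`), `n_segmented`,
#'   `n_effective`, `validation` (per-cycle `cycle_validation_result`s), and
#'   `config`.
#' @export
run_pipeline <- function(config, input) {
  stopifnot(inherits(config, "pipeline_config"))
  rec <- if (inherits(input, "raw_recording")) input
  else read_recording(input, config$sampling_rate_hz)
  if (config$remove_dc) rec <- remove_dc(rec, config$baseline_window_s)
  cycles <- segment_cycles(rec, config$min_cycle_s)
  filt <- filter_effective(cycles, config$thresholds, config$max_cycles)
  if (length(filt$effective) == 0L) {
    reasons <- vapply(filt$results, function(r)
      paste(r$failed_criteria, collapse = ","), character(1))
    stop(errorCondition(
      paste0("no effective cycles among ", length(cycles), " segmented; ",
             "rejection reasons: ",
             paste(sprintf("[%d] %s", seq_along(reasons), reasons),
                   collapse = "; ")),
      class = c("rhinoflow_no_effective_cycles", "error", "condition")))
  }
  res <- compute_all(filt$effective, config_to_resistance(config))
  list(resistances = res,
       n_segmented = length(cycles),
       n_effective = length(filt$effective),
       validation = filt$results,
       config = config)
}

#' Serialize a pipeline result bundle to JSON
#'
#' Mirrors the clinical result table layout: the four indicators by phase,
#' plus per-cycle arrays and acceptance counts.
#'
#' @param result a list from [run_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  res <- result$resistances
  cfg <- result$config
  x <- list(
    indicators = as.list(res$group),
    status = as.list(res$status),
    severity = lapply(res$group[c("vertex_ins", "vertex_exp",
                                  "effective_ins", "effective_exp")],
                      function(v) if (is.na(v)) NA else interpret_severity(v)),
    per_cycle = as.list(res$per_cycle),
    n_segmented = result$n_segmented,
    n_effective = result$n_effective,
    config = {
      y <- unclass(cfg)
      y$thresholds <- unclass(y$thresholds)
      y
    })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
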