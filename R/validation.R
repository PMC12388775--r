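# Time-frequency effective-cycle decision: a cycle is effective iff the
# dominant FFT frequency of BOTH channels and the peak-to-peak amplitude of
# each channel fall inside the six threshold bounds (all bounds inclusive).

FFT_NFFT <- 16384L  # zero-padded length: 100/16384 ~ 0.0061 Hz resolution,
                    # finer than the 0.01 Hz threshold grid step

#' Dominant frequency of a series
#'
#' Subtracts the series mean, periodically extends (tiles) the series to
#' 16384 samples, and returns the frequency of the largest-magnitude spectral
#' bin excluding DC. A segmented respiratory cycle is one period of the
#' breathing signal, so periodic extension recovers the cycle fundamental to
#' within one bin (`fs_hz / 16384`, about 0.0061 Hz at 100 Hz), whereas plain
#' zero-padding of a single period biases the magnitude peak visibly below
#' the fundamental (interference between the positive- and negative-frequency
#' sinc lobes).
#'
#' @param series numeric vector, length >= 8.
#' @param fs_hz sampling rate in Hz.
#' @return Dominant frequency in Hz (resolution `fs_hz / 16384`).
#' @export
dominant_frequency <- function(series, fs_hz) {
  if (length(series) < 8L) stop("series too short (need >= 8 samples)")
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  x <- series - mean(series)
  scale <- max(abs(x))
  if (scale == 0) stop("no dominant frequency: constant series")
  n <- max(FFT_NFFT, length(x))
  mag <- Mod(stats::fft(rep_len(x, n)))
  half <- mag[2:(n %/% 2 + 1L)]               # positive frequencies, no DC
  if (max(half) < 1e-12 * scale * n) stop("no dominant frequency")
  which.max(half) * fs_hz / n
}

#' Peak-to-peak amplitude
#'
#' @param series non-empty numeric vector.
#' @return `max(series) - min(series)`.
#' @export
peak_to_peak <- function(series) {
  if (length(series) == 0L) stop("empty series")
  max(series) - min(series)
}

#' Classify a respiratory cycle as effective or ineffective
#'
#' Applies the four-clause rule: dominant frequency of the pressure channel
#' and of the flow channel inside `[minft, maxft]`, pressure VPP inside
#' `[minpvt, maxpvt]`, flow VPP inside `[minfvt, maxfvt]`; all bounds
#' inclusive. A channel whose dominant frequency is undefined (constant
#' signal) fails its FFT criterion.
#'
#' @param cycle a [respiratory_cycle()].
#' @param ts a [threshold_set()], default [default_thresholds()].
#' @return An object of class `cycle_validation_result`: dominant frequencies
#'   (`NA` when undefined), VPPs, `is_effective`, and `failed_criteria`
#'   (subset of `fft_pressure`, `fft_flow`, `vpp_pressure`, `vpp_flow`).
#' @export
classify_cycle <- function(cycle, ts = default_thresholds()) {
  stopifnot(inherits(cycle, "respiratory_cycle"),
            inherits(ts, "threshold_set"))
  fs <- cycle$sampling_rate_hz
  fp <- tryCatch(dominant_frequency(cycle$pressure, fs),
                 error = function(e) NA_real_)
  ff <- tryCatch(dominant_frequency(cycle$flow, fs),
                 error = function(e) NA_real_)
  vpp_p <- peak_to_peak(cycle$pressure)
  vpp_f <- peak_to_peak(cycle$flow)
  failed <- character(0)
  if (is.na(fp) || fp < ts$minft_hz || fp > ts$maxft_hz)
    failed <- c(failed, "fft_pressure")
  if (is.na(ff) || ff < ts$minft_hz || ff > ts$maxft_hz)
    failed <- c(failed, "fft_flow")
  if (vpp_p < ts$minpvt_pa || vpp_p > ts$maxpvt_pa)
    failed <- c(failed, "vpp_pressure")
  if (vpp_f < ts$minfvt_cm3s || vpp_f > ts$maxfvt_cm3s)
    failed <- c(failed, "vpp_flow")
  structure(list(f_cycle_pressure_hz = fp, f_cycle_flow_hz = ff,
                 vpp_pressure_pa = vpp_p, vpp_flow_cm3s = vpp_f,
                 is_effective = length(failed) == 0L,
                 failed_criteria = failed),
            class = "cycle_validation_result")
}

#' @export
print.cycle_validation_result <- function(x, ...) {
  cat(sprintf("<cycle_validation_result> %s | f_p=%s Hz f_f=%s Hz vpp_p=%.3g Pa vpp_f=%.3g cm3/s%s\n",
              if (x$is_effective) "effective" else "ineffective",
              format(x$f_cycle_pressure_hz, digits = 3),
              format(x$f_cycle_flow_hz, digits = 3),
              x$vpp_pressure_pa, x$vpp_flow_cm3s,
              if (length(x$failed_criteria))
                paste0(" | failed: ", paste(x$failed_criteria, collapse = ","))
              else ""))
  invisible(x)
}

#' Filter a list of cycles down to the effective ones
#'
#' Order-preserving; optionally stops once `max_count` effective cycles have
#' been collected (the acquisition stop rule: once the expected number of
#' effective cycles is reached, collection ends).
#'
#' @param cycles list of [respiratory_cycle()] objects.
#' @param ts a [threshold_set()].
#' @param max_count optional cap on the number of effective cycles returned.
#' @return List with `effective` (the accepted cycles) and `results`
#'   (a `cycle_validation_result` for every inspected cycle).
#' @export
filter_effective <- function(cycles, ts = default_thresholds(),
                             max_count = NULL) {
  effective <- list()
  results <- list()
  for (cyc in cycles) {
    res <- classify_cycle(cyc, ts)
    results[[length(results) + 1L]] <- res
    if (res$is_effective) {
      effective[[length(effective) + 1L]] <- cyc
      if (!is.null(max_count) && length(effective) >= max_count) break
    }
  }
  list(effective = effective, results = results)
}
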