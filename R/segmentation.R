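# Streaming segmentation of a DC-corrected recording into respiratory cycles.
# The flow channel drives segmentation: a cycle starts when a 5-sample sum of
# flow turns positive (inspiration onset) and ends at the last negative sample
# before flow turns positive again (expiration -> next inspiration).

#' Construct a respiratory cycle
#'
#' One segmented inspiration + expiration span of both channels. `Ln` (the
#' number of samples) is derived from the channel length.
#'
#' @param pressure,flow aligned numeric vectors (Pa, cm3/s).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param start_index 1-based offset of the first sample in the source
#'   recording.
#' @return An object of class `respiratory_cycle` with fields `pressure`,
#'   `flow`, `sampling_rate_hz`, `start_index`, `Ln`.
#' @export
respiratory_cycle <- function(pressure, flow, sampling_rate_hz = 100,
                              start_index = 1L) {
  pressure <- as.numeric(pressure)
  flow <- as.numeric(flow)
  if (length(pressure) != length(flow))
    stop("pressure and flow must have equal length")
  if (length(flow) == 0L) stop("empty cycle")
  assert_finite(pressure, "pressure")
  assert_finite(flow, "flow")
  structure(list(pressure = pressure, flow = flow,
                 sampling_rate_hz = sampling_rate_hz,
                 start_index = as.integer(start_index),
                 Ln = length(flow)),
            class = "respiratory_cycle")
}

#' @export
print.respiratory_cycle <- function(x, ...) {
  cat(sprintf("<respiratory_cycle> Ln=%d (%.2f s @ %g Hz), start_index=%d\n",
              x$Ln, x$Ln / x$sampling_rate_hz, x$sampling_rate_hz,
              x$start_index))
  invisible(x)
}

#' Remove the DC component of a recording
#'
#' Subtracts, per channel, the mean of the first `baseline_window_s` seconds
#' (the sensor baseline captured at the start of acquisition).
#'
#' @param rec a [raw_recording()].
#' @param baseline_window_s baseline window length in seconds, default 2.
#' @return A DC-corrected `raw_recording`.
#' @export
remove_dc <- function(rec, baseline_window_s = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  w <- round(baseline_window_s * rec$sampling_rate_hz)
  if (w < 1L || length(rec$pressure) < w)
    stop("recording shorter than the baseline window")
  raw_recording(rec$pressure - mean(rec$pressure[seq_len(w)]),
                rec$flow - mean(rec$flow[seq_len(w)]),
                rec$sampling_rate_hz, rec$t0_s)
}

#' Inspiration-onset test on a 5-sample flow window
#'
#' @param buffer exactly 5 consecutive flow samples.
#' @return `TRUE` iff the sum is strictly positive (the window belongs to an
#'   inspiratory phase).
#' @export
detect_cycle_start <- function(buffer) {
  if (length(buffer) != 5L) stop("buffer must hold exactly 5 samples")
  sum(buffer) > 0
}

#' Cycle-end test on two consecutive flow samples
#'
#' The cycle ends at `x_prev` when the product of the two samples is negative
#' and `x_prev` is negative: the expiration -> inspiration alternation.
#' Exact zeros are non-crossings.
#'
#' @param x_prev,x_last consecutive flow samples.
#' @return `TRUE` iff `x_prev * x_last < 0` and `x_prev < 0`.
#' @export
detect_cycle_end <- function(x_prev, x_last) {
  (x_prev * x_last < 0) && (x_prev < 0)
}

#' Segment a recording into respiratory cycles
#'
#' Streams through the flow channel with a sliding 5-sample window. When a
#' window sum turns positive, the cycle starts at the first strictly positive
#' flow sample in that window; samples then accumulate until the
#' expiration -> inspiration sign alternation ([detect_cycle_end()]) fires,
#' which closes the cycle at the last negative sample. One refinement makes
#' the end rule robust to baseline noise: once a candidate cycle is at least
#' `min_cycle_s` old, the end alternation counts only when the trailing
#' five-sample sum is negative (expiration established) — the same
#' five-sample summation that admits a start, applied symmetrically. Without
#' it, a single noise dip at the near-zero inspiration -> expiration
#' transition truncates the cycle to its inspiratory half. Candidates
#' younger than `min_cycle_s` close on the plain alternation, so a false
#' start on baseline noise dies within a few samples (and is discarded as
#' too short) instead of swallowing the next true onset. Start detection
#' resumes after the emitted or discarded span.
#'
#' @param rec a DC-corrected [raw_recording()].
#' @param min_cycle_s minimum cycle duration in seconds, default 0.5.
#' @param max_cycles optional cap: stop after emitting this many cycles.
#' @return List of [respiratory_cycle()] objects, in recording order. Pressure
#'   is sliced by the flow-derived indices.
#' @export
segment_cycles <- function(rec, min_cycle_s = 0.5, max_cycles = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  flow <- rec$flow
  n <- length(flow)
  min_len <- max(1L, as.integer(ceiling(min_cycle_s * rec$sampling_rate_hz)))
  csum <- c(0, cumsum(flow))
  cycles <- list()
  pos <- 1L
  while (pos + 4L <= n) {
    # --- start detection: first 5-window (within the candidate region) with
    # positive sum; trim leading non-positive samples inside the window.
    start <- NA_integer_
    i <- pos + 4L
    while (i <= n) {
      if (csum[i + 1L] - csum[i - 4L] > 0) {
        w <- (i - 4L):i
        start <- w[which(flow[w] > 0)[1L]]
        break
      }
      i <- i + 1L
    }
    if (is.na(start)) break
    # --- end detection: expiration -> inspiration alternation; mature
    # candidates additionally require a negative trailing 5-sample sum
    # (expiration established).
    cand <- start + which(flow[start:(n - 1L)] < 0 &
                            flow[(start + 1L):n] > 0) - 1L
    lo <- pmax(start, cand - 4L)
    cand <- cand[cand - start + 1L < min_len |
                   csum[cand + 1L] - csum[lo] < 0]
    if (length(cand) == 0L) break            # unterminated cycle: dropped
    end <- cand[1L]                          # last negative sample
    if (end - start + 1L >= min_len) {
      cycles[[length(cycles) + 1L]] <-
        respiratory_cycle(rec$pressure[start:end], flow[start:end],
                          rec$sampling_rate_hz, start_index = start)
      if (!is.null(max_cycles) && length(cycles) >= max_cycles) break
    }
    pos <- end + 1L                          # x_last begins the next candidate
  }
  cycles
}
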