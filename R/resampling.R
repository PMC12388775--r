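# Natural cubic spline interpolation over unit-spaced knots at sample
# indices 1..Ln, and resampling of each accepted cycle to a fixed 2000-point
# grid so cycles of different durations can be averaged pointwise.

#' Fit a natural cubic spline over unit-spaced knots
#'
#' Solves the standard tridiagonal system for the knot second derivatives
#' with natural end conditions (zero curvature at both end knots). Knot
#' abscissae are the sample indices `1..Ln`.
#'
#' @param values numeric vector of length >= 3.
#' @return An object of class `spline_model` with `knots` (the values) and
#'   `coefficients`, an `(Ln-1) x 4` matrix of per-interval coefficients
#'   `(a, b, c, d)` such that on interval `k`,
#'   `S_k(I) = a (I-k)^3 + b (I-k)^2 + c (I-k) + d`.
#' @export
fit_natural_cubic_spline <- function(values) {
  y <- as.numeric(values)
  n <- length(y)
  if (n < 3L) stop("need at least 3 values to fit a cubic spline")
  if (!all(is.finite(y))) stop("values must be finite")
  # Thomas algorithm for M[2..n-1]: M[i-1] + 4 M[i] + M[i+1] = 6 * d2y[i]
  m <- n - 2L
  rhs <- 6 * (y[1:(n - 2L)] - 2 * y[2:(n - 1L)] + y[3:n])
  M <- numeric(n)                      # natural ends: M[1] = M[n] = 0
  if (m == 1L) {
    M[2L] <- rhs / 4
  } else {
    cp <- numeric(m); dp <- numeric(m)
    cp[1L] <- 1 / 4
    dp[1L] <- rhs[1L] / 4
    for (i in 2:m) {
      denom <- 4 - cp[i - 1L]
      cp[i] <- 1 / denom
      dp[i] <- (rhs[i] - dp[i - 1L]) / denom
    }
    sol <- numeric(m)
    sol[m] <- dp[m]
    for (i in (m - 1L):1L) sol[i] <- dp[i] - cp[i] * sol[i + 1L]
    M[2:(n - 1L)] <- sol
  }
  k <- seq_len(n - 1L)
  a <- (M[k + 1L] - M[k]) / 6
  b <- M[k] / 2
  cc <- (y[k + 1L] - y[k]) - (2 * M[k] + M[k + 1L]) / 6
  d <- y[k]
  structure(list(knots = y,
                 coefficients = cbind(a = a, b = b, c = cc, d = d)),
            class = "spline_model")
}

#' Evaluate a fitted spline
#'
#' Inside `[1, Ln]` evaluates the interval cubic by Horner's rule; outside,
#' extends linearly with the end-knot slope (the natural-spline extension,
#' matching `stats::spline(method = "natural")`). The resampling grid's last
#' point `1 + 1999 Ln / 2000` exceeds `Ln` whenever `Ln < 2000`, so the
#' right-side extension is exercised routinely (by less than one index unit).
#'
#' @param model a `spline_model`.
#' @param x numeric vector of evaluation points (index units).
#' @return Numeric vector of spline values.
#' @export
eval_spline <- function(model, x) {
  stopifnot(inherits(model, "spline_model"))
  y <- model$knots
  co <- model$coefficients
  n <- length(y)
  out <- numeric(length(x))
  inside <- x >= 1 & x <= n
  if (any(inside)) {
    k <- pmin(pmax(floor(x[inside]), 1), n - 1L)
    t <- x[inside] - k
    out[inside] <- ((co[k, "a"] * t + co[k, "b"]) * t + co[k, "c"]) * t +
      co[k, "d"]
  }
  if (any(!inside)) {
    lo <- !inside & x < 1
    hi <- !inside & x > n
    # slopes at the end knots (t = 0 on interval 1; t = 1 on interval n-1)
    s1 <- co[1L, "c"]
    sn <- 3 * co[n - 1L, "a"] + 2 * co[n - 1L, "b"] + co[n - 1L, "c"]
    out[lo] <- y[1L] + s1 * (x[lo] - 1)
    out[hi] <- y[n] + sn * (x[hi] - n)
  }
  out
}

new_resampled_cycle <- function(pressure, flow, source_length_Ln, delta_T,
                                duration_s) {
  stopifnot(length(pressure) == length(flow))
  structure(list(pressure = pressure, flow = flow,
                 source_length_Ln = source_length_Ln,
                 delta_T = delta_T, duration_s = duration_s),
            class = "resampled_cycle")
}

#' @export
print.resampled_cycle <- function(x, ...) {
  cat(sprintf("<resampled_cycle> %d points (source Ln=%.0f, %.2f s)\n",
              length(x$pressure), x$source_length_Ln, x$duration_s))
  invisible(x)
}

#' Resample a cycle to a fixed 2000-point grid
#'
#' Fits a natural cubic spline per channel over knots `1..Ln` and evaluates
#' it at the grid `I_1 = 1`, `I_{j+1} = I_j + Ln/2000`. The first output
#' sample equals the first input sample.
#'
#' @param cycle a [respiratory_cycle()] with at least 3 samples.
#' @param n_out number of output samples, default 2000.
#' @return A `resampled_cycle` with `delta_T = Ln / n_out` and
#'   `duration_s = Ln / sampling_rate_hz`.
#' @export
resample_cycle <- function(cycle, n_out = 2000L) {
  stopifnot(inherits(cycle, "respiratory_cycle"))
  Ln <- cycle$Ln
  if (Ln < 3L) stop("cycle too short to resample (need >= 3 samples)")
  delta_T <- Ln / n_out
  grid <- 1 + (seq_len(n_out) - 1) * delta_T
  new_resampled_cycle(
    eval_spline(fit_natural_cubic_spline(cycle$pressure), grid),
    eval_spline(fit_natural_cubic_spline(cycle$flow), grid),
    source_length_Ln = Ln, delta_T = delta_T,
    duration_s = Ln / cycle$sampling_rate_hz)
}

#' Average resampled cycles pointwise
#'
#' @param cycles non-empty list of `resampled_cycle` objects of equal length.
#' @return A `resampled_cycle`: the pointwise arithmetic mean per channel;
#'   `delta_T` and `duration_s` are the means of the inputs'.
#' @export
average_cycles <- function(cycles) {
  if (length(cycles) == 0L) stop("empty cycle list")
  stopifnot(all(vapply(cycles, inherits, logical(1), "resampled_cycle")))
  lens <- vapply(cycles, function(c) length(c$pressure), integer(1))
  if (length(unique(lens)) != 1L) stop("cycles must have equal length")
  n <- length(cycles)
  new_resampled_cycle(
    Reduce(`+`, lapply(cycles, `[[`, "pressure")) / n,
    Reduce(`+`, lapply(cycles, `[[`, "flow")) / n,
    source_length_Ln = mean(vapply(cycles, `[[`, numeric(1), "source_length_Ln")),
    delta_T = mean(vapply(cycles, `[[`, numeric(1), "delta_T")),
    duration_s = mean(vapply(cycles, `[[`, numeric(1), "duration_s")))
}
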