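# Four nasal-resistance indicators, all in Pa/(cm3/s), computed separately
# for the inspiratory and expiratory phases:
#   mean resistance      - flow interpolated at the 150 Pa reference pressure;
#   vertex resistance    - pressure/flow at the maximal-flow sample;
#   effective resistance - ratio of RMS pressure to RMS flow;
#   Broms resistance     - tangent of the polar angle where the scaled
#                          pressure-flow curve crosses the radius-2 circle.
# Expiratory segments are negated on construction so every calculator works
# on positive magnitudes; all reported resistances are positive.

not_computable <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Split a cycle into inspiratory and expiratory phase segments
#'
#' Splits at the first index where flow turns negative and stays negative for
#' at least 2 samples. The expiratory segment's channels are negated so both
#' segments carry positive magnitudes.
#'
#' @param x a [respiratory_cycle()] or a `resampled_cycle`.
#' @return List with `inspiratory` and `expiratory`, each a `phase_segment`
#'   (fields `phase`, `pressure`, `flow`, `dt`) or `NULL` when the phase is
#'   absent (no sign change: `expiratory` is `NULL`).
#' @export
split_phases <- function(x) {
  if (inherits(x, "respiratory_cycle")) {
    dt <- 1 / x$sampling_rate_hz
  } else if (inherits(x, "resampled_cycle")) {
    dt <- x$duration_s / (length(x$flow) - 1)
  } else stop("x must be a respiratory_cycle or resampled_cycle")
  p <- x$pressure
  v <- x$flow
  n <- length(v)
  neg <- v < 0
  split_at <- NA_integer_
  if (n >= 2L) {
    idx <- which(neg[-n] & neg[-1L])
    if (length(idx)) split_at <- idx[1L]
  }
  seg <- function(i, phase, sgn) {
    if (length(i) == 0L) return(NULL)
    structure(list(phase = phase, pressure = sgn * p[i], flow = sgn * v[i],
                   dt = dt),
              class = "phase_segment")
  }
  if (is.na(split_at) || split_at == 1L) {
    # no sustained negative run, or cycle starts negative (degenerate)
    if (is.na(split_at))
      return(list(inspiratory = seg(seq_len(n), "inspiratory", 1),
                  expiratory = NULL))
  }
  list(inspiratory = seg(seq_len(split_at - 1L), "inspiratory", 1),
       expiratory = seg(split_at:n, "expiratory", -1))
}

#' Classic mean resistance at the reference pressure
#'
#' Finds the first adjacent sample pair whose pressures straddle `p_ref_pa`,
#' linearly interpolates the flow along their connecting line, and returns
#' `p_ref / V_pred`.
#'
#' @param seg a `phase_segment` (positive magnitudes).
#' @param p_ref_pa reference pressure, default 150 Pa.
#' @return Resistance in Pa/(cm3/s), or `NA` with a `reason` attribute when
#'   the segment never reaches the reference pressure.
#' @export
mean_resistance <- function(seg, p_ref_pa = 150) {
  if (is.null(seg)) return(not_computable("phase absent"))
  p <- seg$pressure
  v <- seg$flow
  n <- length(p)
  if (max(p) < p_ref_pa)
    return(not_computable("reference pressure not reached"))
  hit <- which(p == p_ref_pa)
  if (length(hit)) {
    v_pred <- v[hit[1L]]
  } else {
    cross <- which((p[-n] - p_ref_pa) * (p[-1L] - p_ref_pa) < 0)
    if (length(cross) == 0L)
      return(not_computable("reference pressure not bracketed"))
    i <- cross[1L]
    v_pred <- v[i] + (v[i + 1L] - v[i]) * (p_ref_pa - p[i]) / (p[i + 1L] - p[i])
  }
  if (!is.finite(v_pred) || v_pred <= 0)
    return(not_computable("non-positive interpolated flow"))
  p_ref_pa / v_pred
}

#' Vertex resistance (resistance at maximal flow)
#'
#' @param seg a `phase_segment`.
#' @return `|P_vertex| / |V_vertex|` at the earliest sample of maximal
#'   absolute flow, or `NA` with a `reason` attribute.
#' @export
vertex_resistance <- function(seg) {
  if (is.null(seg)) return(not_computable("phase absent"))
  i <- which.max(abs(seg$flow))          # earliest maximal sample
  if (abs(seg$flow[i]) == 0) return(not_computable("zero maximal flow"))
  abs(seg$pressure[i]) / abs(seg$flow[i])
}

#' Effective (RMS) resistance
#'
#' RMS pressure over RMS flow, both computed by trapezoidal integration of
#' the squared signal over the segment duration.
#'
#' @param seg a `phase_segment`.
#' @return `P_eff / V_eff`, or `NA` with a `reason` attribute.
#' @export
effective_resistance <- function(seg) {
  if (is.null(seg)) return(not_computable("phase absent"))
  n <- length(seg$pressure)
  if (n < 2L) return(not_computable("segment too short"))
  T <- (n - 1) * seg$dt
  p_eff <- sqrt(trapz(seg$pressure^2, seg$dt) / T)
  v_eff <- sqrt(trapz(seg$flow^2, seg$dt) / T)
  if (v_eff == 0) return(not_computable("zero effective flow"))
  p_eff / v_eff
}

#' Broms resistance (polar-coordinate fit at radius 2)
#'
#' Scales the pressure-flow curve to Broms coordinates (`x = |v| / unit_cm3s`,
#' `y = |p| / unit_pa`), converts to polar form (`r`, angle `v = atan2(y, x)`),
#' fits `v = v0 + c r` by ordinary least squares over the points with
#' `|r - r_ref| <= band`, and returns `tan(v0 + c * r_ref)`.
#'
#' @param seg a `phase_segment`.
#' @param r_ref reference radius, default 2.
#' @param band half-width of the radial selection band, default 0.25.
#' @param unit_pa,unit_cm3s axis scaling: Pa (resp. cm3/s) per radial unit,
#'   default 100 each (so the radius-2 circle crosses the axes at 200 Pa and
#'   200 cm3/s).
#' @return Resistance with a `fit` attribute (list `v0`, `c`, `r_ref`,
#'   `band_halfwidth`, `n_points`), or `NA` with a `reason` attribute when
#'   fewer than 2 points fall in the band.
#' @export
broms_resistance <- function(seg, r_ref = 2, band = 0.25,
                             unit_pa = 100, unit_cm3s = 100) {
  if (is.null(seg)) return(not_computable("phase absent"))
  x <- abs(seg$flow) / unit_cm3s
  y <- abs(seg$pressure) / unit_pa
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x)
  sel <- abs(r - r_ref) <= band
  if (sum(sel) < 2L)
    return(not_computable("curve does not cross the reference radius"))
  rs <- r[sel]
  as <- ang[sel]
  sxx <- sum((rs - mean(rs))^2)
  c_hat <- if (sxx < 1e-12) 0 else sum((rs - mean(rs)) * (as - mean(as))) / sxx
  v0 <- mean(as) - c_hat * mean(rs)
  v_pred <- v0 + c_hat * r_ref
  val <- tan(v_pred)
  if (!is.finite(val) || val <= 0)
    return(not_computable("fitted angle outside (0, pi/2)"))
  structure(val, fit = list(v0 = v0, c = c_hat, r_ref = r_ref,
                            band_halfwidth = band, n_points = sum(sel)))
}

#' Default resistance configuration
#'
#' @return Named list: `p_ref_pa` 150, `broms_r_ref` 2, `broms_band` 0.25,
#'   `broms_unit_pa` 100, `broms_unit_cm3s` 100, `resample_n` 2000.
#' @export
resistance_config <- function() {
  list(p_ref_pa = 150, broms_r_ref = 2, broms_band = 0.25,
       broms_unit_pa = 100, broms_unit_cm3s = 100, resample_n = 2000L)
}

cycle_indicators <- function(phases, rphases, config) {
  c(mean_ins = as.numeric(mean_resistance(phases$inspiratory, config$p_ref_pa)),
    mean_exp = as.numeric(mean_resistance(phases$expiratory, config$p_ref_pa)),
    broms_ins = as.numeric(broms_resistance(phases$inspiratory,
      config$broms_r_ref, config$broms_band,
      config$broms_unit_pa, config$broms_unit_cm3s)),
    broms_exp = as.numeric(broms_resistance(phases$expiratory,
      config$broms_r_ref, config$broms_band,
      config$broms_unit_pa, config$broms_unit_cm3s)),
    vertex_ins = as.numeric(vertex_resistance(rphases$inspiratory)),
    vertex_exp = as.numeric(vertex_resistance(rphases$expiratory)),
    effective_ins = as.numeric(effective_resistance(rphases$inspiratory)),
    effective_exp = as.numeric(effective_resistance(rphases$expiratory)))
}

#' Compute all four resistance indicators for a set of effective cycles
#'
#' Group-level routing: mean and Broms resistance are computed per cycle on
#' the raw effective cycles and averaged; vertex and effective resistance
#' are computed on the pointwise average of the spline-resampled cycles.
#' Per-cycle values of all four indicators (vertex/effective from each
#' cycle's own resampled version) are also returned for stability analysis.
#'
#' @param effective_cycles non-empty list of [respiratory_cycle()] objects.
#' @param config configuration list, see [resistance_config()].
#' @return An object of class `resistance_result`: `group` (named vector of
#'   the 8 group indicators), `status` (named character, `"ok"` or the
#'   not-computable reason), and `per_cycle` (data.frame of per-cycle
#'   indicator values).
#' @export
compute_all <- function(effective_cycles, config = resistance_config()) {
  if (length(effective_cycles) == 0L) stop("no effective cycles")
  stopifnot(all(vapply(effective_cycles, inherits, logical(1),
                       "respiratory_cycle")))
  resampled <- lapply(effective_cycles, resample_cycle, n_out = config$resample_n)
  per <- t(vapply(seq_along(effective_cycles), function(i) {
    cycle_indicators(split_phases(effective_cycles[[i]]),
                     split_phases(resampled[[i]]), config)
  }, numeric(8)))
  per_cycle <- as.data.frame(per)
  avg <- average_cycles(resampled)
  avg_phases <- split_phases(avg)
  group_of <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  group <- c(
    mean_ins = group_of(per_cycle$mean_ins),
    mean_exp = group_of(per_cycle$mean_exp),
    broms_ins = group_of(per_cycle$broms_ins),
    broms_exp = group_of(per_cycle$broms_exp),
    vertex_ins = as.numeric(vertex_resistance(avg_phases$inspiratory)),
    vertex_exp = as.numeric(vertex_resistance(avg_phases$expiratory)),
    effective_ins = as.numeric(effective_resistance(avg_phases$inspiratory)),
    effective_exp = as.numeric(effective_resistance(avg_phases$expiratory)))
  status <- ifelse(is.na(group), "not_computable", "ok")
  structure(list(group = group, status = status, per_cycle = per_cycle,
                 n_cycles = length(effective_cycles)),
            class = "resistance_result")
}

#' @export
print.resistance_result <- function(x, ...) {
  cat(sprintf("<resistance_result> %d effective cycle(s), Pa/(cm3/s)\n",
              x$n_cycles))
  g <- x$group
  m <- matrix(g[c("vertex_ins", "effective_ins", "mean_ins", "broms_ins",
                  "vertex_exp", "effective_exp", "mean_exp", "broms_exp")],
              nrow = 2, byrow = TRUE,
              dimnames = list(c("Ins", "Exp"),
                              c("Vertex", "Effective", "Mean", "Broms")))
  print(round(m, 3))
  invisible(x)
}

#' Interpret a 4-phase resistance value against the clinical cutoff
#'
#' @param resistance non-negative resistance value.
#' @return `"normal"` if below 0.75, `"obstructed"` if at or above 0.75.
#' @export
interpret_severity <- function(resistance) {
  if (!is.finite(resistance) || resistance < 0)
    stop("resistance must be a non-negative number")
  if (resistance < 0.75) "normal" else "obstructed"
}
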