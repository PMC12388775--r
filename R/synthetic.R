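# Seeded synthetic breath simulator. Effective cycles are raised-sine half
# waves on the flow channel (asymmetric inspiration/expiration), with pressure
# coupled through the quadratic-magnitude orifice law p = k * v * |v|, which
# reproduces the curved pressure-flow loop of real rhinomanometry. Three
# interference paradigms emulate the clinically observed artifact classes:
# saturated/weak breaths, a breathing mask not worn properly, and multiple
# superimposed breaths.

default_scenario_params <- function() {
  list(
    variant = NULL,            # scenario sub-type; drawn from the seed if NULL
    clip_level_pa = 600,       # sensor full scale, pressure
    clip_level_cm3s = 1800,    # sensor full scale, flow
    sat_scale = 3,             # over-range factor before clipping
    weak_pressure_amp_pa = 100,# weak-breath pressure half-amplitude
    leak_frac = 0.5,           # retained-phase attenuation, one-signed wear
    missing_phase = "expiratory",
    zeroed_channel = "pressure",
    zero_noise_sd = 0.5,       # residual ADC noise on a dead channel
    drift_freq_hz = 0.05,      # ambient drift, below the 0.12 Hz band edge
    burst_freq_hz = 1.2,       # above the 0.6 Hz band edge
    burst_amp_frac = 0.5,
    burst_phase = "both",      # "inspiratory", "expiratory", or "both"
    burst_peak_frac = 0.7      # base-peak reduction in the affected phase
  )
}

#' Specify a synthetic respiratory cycle
#'
#' Fields left `NULL` are drawn from the seed at generation time:
#' `frequency_hz` from U(0.2, 0.5) (the normal breathing band),
#' `pressure_amp_pa` from U(175, 450) (pressure VPP 350--900 Pa) and
#' `flow_amp_cm3s` from U(75, 750) (flow VPP 150--1500 cm3/s), i.e. strictly
#' inside the default acceptance thresholds.
#'
#' @param frequency_hz cycle fundamental in Hz, or `NULL` to draw.
#' @param pressure_amp_pa pressure half peak-to-peak target in Pa, or `NULL`.
#' @param flow_amp_cm3s flow half peak-to-peak target in cm3/s, or `NULL`.
#' @param insp_fraction inspiratory fraction of the cycle, in (0,1).
#' @param noise_sigma_frac Gaussian noise sd as a fraction of each channel's
#'   half-amplitude.
#' @param dc_offset_pa,dc_offset_cm3s constant sensor offsets.
#' @param scenario `"none"` (effective) or one of the interference paradigms
#'   `"saturated_or_weak"`, `"not_worn_properly"`, `"multiple_breaths"`.
#' @param scenario_params named list overriding the scenario defaults (see
#'   the methods vignette); unknown names are an error.
#' @param seed integer RNG seed; the generated cycle is a pure function of
#'   the spec (including this seed). `NA` (the default) is allowed only when
#'   the spec is passed to [generate_recording()], which derives a child
#'   seed for it.
#' @param sampling_rate_hz sampling rate, default 100 Hz.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(frequency_hz = NULL, pressure_amp_pa = NULL,
                           flow_amp_cm3s = NULL, insp_fraction = 0.45,
                           noise_sigma_frac = 0.02,
                           dc_offset_pa = 0, dc_offset_cm3s = 0,
                           scenario = "none", scenario_params = list(),
                           seed = NA_integer_, sampling_rate_hz = 100) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (!is.null(frequency_hz) && frequency_hz <= 0)
    stop("frequency_hz must be positive")
  if (insp_fraction <= 0 || insp_fraction >= 1)
    stop("insp_fraction must be in (0, 1)")
  if (noise_sigma_frac < 0) stop("noise_sigma_frac must be >= 0")
  sp <- default_scenario_params()
  unknown <- setdiff(names(scenario_params), names(sp))
  if (length(unknown))
    stop("unknown scenario_params: ", paste(unknown, collapse = ", "))
  sp[names(scenario_params)] <- scenario_params
  structure(list(frequency_hz = frequency_hz,
                 pressure_amp_pa = pressure_amp_pa,
                 flow_amp_cm3s = flow_amp_cm3s,
                 insp_fraction = insp_fraction,
                 noise_sigma_frac = noise_sigma_frac,
                 dc_offset_pa = dc_offset_pa,
                 dc_offset_cm3s = dc_offset_cm3s,
                 scenario = scenario, scenario_params = sp,
                 seed = as.integer(seed),
                 sampling_rate_hz = sampling_rate_hz),
            class = "synthetic_spec")
}

require_seed <- function(spec) {
  if (is.na(spec$seed))
    stop("spec has no seed; set one in synthetic_spec() or generate via ",
         "generate_recording(), which derives child seeds")
  invisible(spec)
}

# Draw any NULL waveform parameters; must run inside with_seed().
resolve_spec <- function(spec) {
  spec$frequency_hz <- spec$frequency_hz %||% stats::runif(1, 0.2, 0.5)
  spec$pressure_amp_pa <- spec$pressure_amp_pa %||% stats::runif(1, 175, 450)
  spec$flow_amp_cm3s <- spec$flow_amp_cm3s %||% stats::runif(1, 75, 750)
  spec
}

# Noise-free raised-sine flow waveform and quadratically coupled pressure for
# one cycle: flow positive over the inspiratory fraction, then negative.
# The two half-wave amplitudes are balanced so the flow integral vanishes
# (inhaled volume = exhaled volume) while the peak-to-peak span stays
# 2 * v_amp: amp_i * ni = amp_e * ne with amp_i + amp_e = 2 * v_amp.
base_waveform <- function(f, p_amp, v_amp, insp_fraction, fs) {
  n <- round(fs / f)
  ni <- max(1L, round(insp_fraction * n))
  ne <- max(1L, n - ni)
  amp_i <- 2 * v_amp * ne / (ni + ne)
  amp_e <- 2 * v_amp * ni / (ni + ne)
  v <- c(amp_i * sin(pi * seq_len(ni) / (ni + 1)),
         -amp_e * sin(pi * seq_len(ne) / (ne + 1)))
  k <- p_amp / v_amp^2
  list(v = v, k = k, n = length(v), ni = ni)
}

finalize_cycle <- function(spec, p, v, truth_label) {
  p <- p + spec$dc_offset_pa
  v <- v + spec$dc_offset_cm3s
  cyc <- respiratory_cycle(p, v, spec$sampling_rate_hz)
  labeled_cycle(cyc, truth_label, spec$scenario, seed = spec$seed)
}

#' Generate one effective respiratory cycle
#'
#' One full cycle of duration `1/frequency_hz`: flow is a positive raised-sine
#' half wave over the inspiratory fraction followed by a negative half wave;
#' pressure follows the orifice law `p = k v |v|` with `k` chosen so the
#' pressure peak equals `pressure_amp_pa`. Gaussian noise is added per
#' channel. Deterministic given the spec.
#'
#' @param spec a [synthetic_spec()] with `scenario = "none"`.
#' @return A [labeled_cycle()] with `truth_label = "effective"`.
#' @export
generate_effective_cycle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$scenario != "none")
    stop("effective cycles require scenario = 'none'")
  require_seed(spec)
  with_seed(spec$seed, {
    spec <- resolve_spec(spec)
    if (spec$noise_sigma_frac >= 1 || spec$pressure_amp_pa <= 0 ||
        spec$flow_amp_cm3s <= 0)
      stop("degenerate spec: pressure VPP below twice the noise floor")
    w <- base_waveform(spec$frequency_hz, spec$pressure_amp_pa,
                       spec$flow_amp_cm3s, spec$insp_fraction,
                       spec$sampling_rate_hz)
    p <- w$k * w$v * abs(w$v) +
      stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$pressure_amp_pa)
    v <- w$v + stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$flow_amp_cm3s)
    finalize_cycle(spec, p, v, "effective")
  })
}

#' Generate one ineffective (interference) respiratory cycle
#'
#' Scenario constructions:
#' \describe{
#'   \item{saturated_or_weak}{`variant = "saturated"`: both channels scaled by
#'     `sat_scale` and hard-clipped at the sensor full scale, so the clipped
#'     pressure VPP exceeds the upper VPP threshold. `variant = "weak"`: the
#'     whole breath rescaled so the pressure half-amplitude is
#'     `weak_pressure_amp_pa` (default 100 Pa: pressure never reaches
#'     +/-150 Pa).}
#'   \item{not_worn_properly}{`variant = "one_signed"`: the phase named by
#'     `missing_phase` is lost (sensor reads residual noise) and the retained
#'     phase is attenuated by `leak_frac` (leaky seal). `variant = "zeroed"`:
#'     the channel named by `zeroed_channel` is dead (residual ADC noise
#'     only). `variant = "drift"`: both channels replaced by one period of
#'     ambient drift at `drift_freq_hz` (below the frequency band) plus
#'     noise.}
#'   \item{multiple_breaths}{a burst oscillation at `burst_freq_hz` (above
#'     the frequency band) with amplitude `burst_amp_frac` of the flow
#'     amplitude is superimposed on the phase(s) named by `burst_phase`,
#'     whose base peak is reduced to `burst_peak_frac`; pressure is
#'     re-derived from the composite flow through the orifice law.}
#' }
#' When `variant` is `NULL` it is drawn uniformly from the scenario's
#' variants using the spec seed.
#'
#' @param spec a [synthetic_spec()] with `scenario != "none"`.
#' @return A [labeled_cycle()] with `truth_label = "ineffective"`.
#' @export
generate_ineffective_cycle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$scenario == "none")
    stop("ineffective cycles require a non-'none' scenario")
  require_seed(spec)
  with_seed(spec$seed, {
    spec <- resolve_spec(spec)
    sp <- spec$scenario_params
    fs <- spec$sampling_rate_hz
    switch(spec$scenario,
      saturated_or_weak = {
        variant <- sp$variant %||% sample(c("saturated", "weak"), 1L)
        if (variant == "saturated") {
          w <- base_waveform(spec$frequency_hz, spec$pressure_amp_pa,
                             spec$flow_amp_cm3s, spec$insp_fraction, fs)
          v <- sp$sat_scale * w$v
          p <- w$k * v * abs(v)
          p <- p + stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$pressure_amp_pa)
          v <- v + stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$flow_amp_cm3s)
          p <- pmin(pmax(p, -sp$clip_level_pa), sp$clip_level_pa)
          v <- pmin(pmax(v, -sp$clip_level_cm3s), sp$clip_level_cm3s)
        } else if (variant == "weak") {
          scale <- sp$weak_pressure_amp_pa / spec$pressure_amp_pa
          p_amp <- sp$weak_pressure_amp_pa
          v_amp <- spec$flow_amp_cm3s * sqrt(scale)
          w <- base_waveform(spec$frequency_hz, p_amp, v_amp,
                             spec$insp_fraction, fs)
          p <- w$k * w$v * abs(w$v) +
            stats::rnorm(w$n, 0, spec$noise_sigma_frac * p_amp)
          v <- w$v + stats::rnorm(w$n, 0, spec$noise_sigma_frac * v_amp)
        } else stop("unknown saturated_or_weak variant: ", variant)
        finalize_cycle(spec, p, v, "ineffective")
      },
      not_worn_properly = {
        variant <- sp$variant %||%
          sample(c("one_signed", "zeroed", "drift"), 1L)
        if (variant == "one_signed") {
          w <- base_waveform(spec$frequency_hz,
                             spec$pressure_amp_pa * sp$leak_frac,
                             spec$flow_amp_cm3s * sp$leak_frac,
                             spec$insp_fraction, fs)
          keep <- if (sp$missing_phase == "expiratory")
            seq_len(w$ni) else (w$ni + 1L):w$n
          v <- numeric(w$n)
          v[keep] <- w$v[keep]
          p <- w$k * v * abs(v)
          p <- p + stats::rnorm(w$n, 0, sp$zero_noise_sd)
          v <- v + stats::rnorm(w$n, 0, sp$zero_noise_sd)
        } else if (variant == "zeroed") {
          w <- base_waveform(spec$frequency_hz, spec$pressure_amp_pa,
                             spec$flow_amp_cm3s, spec$insp_fraction, fs)
          p <- w$k * w$v * abs(w$v) +
            stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$pressure_amp_pa)
          v <- w$v + stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$flow_amp_cm3s)
          if (sp$zeroed_channel == "pressure")
            p <- stats::rnorm(w$n, 0, sp$zero_noise_sd)
          else
            v <- stats::rnorm(w$n, 0, sp$zero_noise_sd)
        } else if (variant == "drift") {
          n <- round(fs / sp$drift_freq_hz)   # one full drift period
          tt <- (seq_len(n) - 1) / fs
          ph <- stats::runif(2, 0, 2 * pi)
          p <- spec$pressure_amp_pa * sin(2 * pi * sp$drift_freq_hz * tt + ph[1]) +
            stats::rnorm(n, 0, spec$noise_sigma_frac * spec$pressure_amp_pa)
          v <- spec$flow_amp_cm3s * sin(2 * pi * sp$drift_freq_hz * tt + ph[2]) +
            stats::rnorm(n, 0, spec$noise_sigma_frac * spec$flow_amp_cm3s)
        } else stop("unknown not_worn_properly variant: ", variant)
        finalize_cycle(spec, p, v, "ineffective")
      },
      multiple_breaths = {
        w <- base_waveform(spec$frequency_hz, spec$pressure_amp_pa,
                           spec$flow_amp_cm3s, spec$insp_fraction, fs)
        tt <- (seq_len(w$n) - 1) / fs
        idx <- switch(sp$burst_phase %||% "both",
                      inspiratory = seq_len(w$ni),
                      expiratory = (w$ni + 1L):w$n,
                      both = seq_len(w$n),
                      stop("unknown burst_phase"))
        v <- w$v
        v[idx] <- sp$burst_peak_frac * v[idx] +
          sp$burst_amp_frac * spec$flow_amp_cm3s *
            sin(2 * pi * sp$burst_freq_hz * tt[idx])
        p <- w$k * v * abs(v) +
          stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$pressure_amp_pa)
        v <- v + stats::rnorm(w$n, 0, spec$noise_sigma_frac * spec$flow_amp_cm3s)
        finalize_cycle(spec, p, v, "ineffective")
      },
      stop("unknown scenario: ", spec$scenario))
  })
}

#' Generate a cycle from a spec (dispatch on scenario)
#'
#' @param spec a [synthetic_spec()].
#' @return A [labeled_cycle()].
#' @export
generate_cycle <- function(spec) {
  if (spec$scenario == "none") generate_effective_cycle(spec)
  else generate_ineffective_cycle(spec)
}

#' Assemble a full recording from per-cycle specs
#'
#' Concatenates the generated cycles separated by `gap_s` seconds of
#' near-zero baseline noise, and returns the ground-truth cycle boundaries
#' for segmentation scoring. Specs whose `seed` is `NA` receive a child seed
#' derived from `seed`.
#'
#' @param specs non-empty list of [synthetic_spec()] objects.
#' @param gap_s gap duration between consecutive cycles in seconds.
#' @param baseline_noise_sigma sd of the Gaussian baseline noise in the gaps
#'   (applied to both channels, in their native units).
#' @param lead_in_s baseline noise prepended before the first cycle, default
#'   0 s. Use >= the DC-estimation window (2 s) when the recording will go
#'   through [remove_dc()]: estimating the baseline over breathing signal
#'   shifts both channels and corrupts segmentation.
#' @param tail_s baseline noise appended after the last cycle, default 0 s.
#'   The streaming end rule closes a cycle only when a later positive flow
#'   sample arrives, so without a tail the final cycle of a recording is
#'   never emitted.
#' @param seed recording-level seed for gap noise and derived cycle seeds.
#' @return List with `recording` (a [raw_recording()]), `cycles` (list of
#'   [labeled_cycle()]; each cycle's `start_index` locates it in the
#'   recording), and `boundaries` (data.frame of 1-based `start`, `end`).
#' @export
generate_recording <- function(specs, gap_s = 0.2, baseline_noise_sigma = 1,
                               lead_in_s = 0, tail_s = 0, seed = 1L) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  stopifnot(all(vapply(specs, inherits, logical(1), "synthetic_spec")))
  n_spec <- length(specs)
  child <- derive_seeds(seed, n_spec)
  cycles <- vector("list", n_spec)
  for (i in seq_len(n_spec)) {
    sp <- specs[[i]]
    if (is.na(sp$seed)) sp$seed <- child[i]
    cycles[[i]] <- generate_cycle(sp)
  }
  fs <- specs[[1L]]$sampling_rate_hz
  n_gap <- round(gap_s * fs)
  n_lead <- round(lead_in_s * fs)
  noise2 <- with_seed(seed + 1L, {
    gaps <- lapply(seq_len(n_spec - 1L), function(i)
      list(p = stats::rnorm(n_gap, specs[[i]]$dc_offset_pa, baseline_noise_sigma),
           v = stats::rnorm(n_gap, specs[[i]]$dc_offset_cm3s, baseline_noise_sigma)))
    lead <- list(p = stats::rnorm(n_lead, specs[[1L]]$dc_offset_pa, baseline_noise_sigma),
                 v = stats::rnorm(n_lead, specs[[1L]]$dc_offset_cm3s, baseline_noise_sigma))
    n_tail <- round(tail_s * fs)
    tail <- list(p = stats::rnorm(n_tail, specs[[n_spec]]$dc_offset_pa, baseline_noise_sigma),
                 v = stats::rnorm(n_tail, specs[[n_spec]]$dc_offset_cm3s, baseline_noise_sigma))
    list(gaps = gaps, lead = lead, tail = tail)
  })
  gaps <- noise2$gaps
  pressure <- noise2$lead$p
  flow <- noise2$lead$v
  starts <- ends <- integer(n_spec)
  for (i in seq_len(n_spec)) {
    starts[i] <- length(flow) + 1L
    cycles[[i]]$cycle$start_index <- starts[i]
    pressure <- c(pressure, cycles[[i]]$cycle$pressure)
    flow <- c(flow, cycles[[i]]$cycle$flow)
    ends[i] <- length(flow)
    if (i < n_spec) {
      pressure <- c(pressure, gaps[[i]]$p)
      flow <- c(flow, gaps[[i]]$v)
    }
  }
  pressure <- c(pressure, noise2$tail$p)
  flow <- c(flow, noise2$tail$v)
  list(recording = raw_recording(pressure, flow, fs),
       cycles = cycles,
       boundaries = data.frame(start = starts, end = ends))
}
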