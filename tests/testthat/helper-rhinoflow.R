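# Shared fixture builders. Everything is generated in code; no stored data.

# A phase segment with explicit channels (positive magnitudes), bypassing
# split_phases, for direct calculator tests.
make_segment <- function(pressure, flow, dt = 0.01, phase = "inspiratory") {
  structure(list(phase = phase, pressure = pressure, flow = flow, dt = dt),
            class = "phase_segment")
}

# Noise-free one-cycle waveform: raised-sine half waves on flow, pressure
# from the quadratic orifice law p = k * v * |v| (the same construction the
# generator uses, rebuilt here so tests can pin exact amplitudes).
make_quadratic_cycle <- function(f = 0.3, k = 150 / 600^2, v_amp = 650,
                                 insp_fraction = 0.45, fs = 100) {
  n <- round(fs / f)
  ni <- round(insp_fraction * n)
  ne <- n - ni
  v <- c(v_amp * sin(pi * seq_len(ni) / (ni + 1)),
         -v_amp * sin(pi * seq_len(ne) / (ne + 1)))
  respiratory_cycle(k * v * abs(v), v, fs)
}

# Linear-law cycle p = k * v (vertex = effective = mean = broms = k when the
# Broms axis units are equal).
make_linear_cycle <- function(k, v_amp = 600, f = 0.3, fs = 100) {
  n <- round(fs / f)
  ni <- round(0.45 * n)
  ne <- n - ni
  v <- c(v_amp * sin(pi * seq_len(ni) / (ni + 1)),
         -v_amp * sin(pi * seq_len(ne) / (ne + 1)))
  respiratory_cycle(k * v, v, fs)
}

# Independent re-implementation of the classifier decision for oracle
# equivalence tests: dominant frequency by direct argmax over the tiled
# periodogram, VPP by max - min, four-clause conjunction.
oracle_classify <- function(cycle, ts) {
  domfreq <- function(x, fs) {
    x <- x - mean(x)
    if (max(abs(x)) == 0) return(NA_real_)
    n <- max(16384L, length(x))
    mag <- Mod(stats::fft(rep(x, length.out = n)))
    which.max(mag[2:(n %/% 2 + 1)]) * fs / n
  }
  fs <- cycle$sampling_rate_hz
  fp <- domfreq(cycle$pressure, fs)
  ff <- domfreq(cycle$flow, fs)
  vp <- max(cycle$pressure) - min(cycle$pressure)
  vf <- max(cycle$flow) - min(cycle$flow)
  isTRUE(fp >= ts$minft_hz && fp <= ts$maxft_hz &&
           ff >= ts$minft_hz && ff <= ts$maxft_hz &&
           vp >= ts$minpvt_pa && vp <= ts$maxpvt_pa &&
           vf >= ts$minfvt_cm3s && vf <= ts$maxfvt_cm3s)
}

# Effective/ineffective labeled corpus used by search and stability tests.
make_labeled_corpus <- function(n_eff, n_ineff, scenario, seed,
                                params = list()) {
  eff_seeds <- rhinoflow:::derive_seeds(seed, n_eff + n_ineff)
  c(
    lapply(seq_len(n_eff), function(i)
      generate_effective_cycle(synthetic_spec(seed = eff_seeds[i]))),
    lapply(seq_len(n_ineff), function(i)
      generate_ineffective_cycle(
        synthetic_spec(scenario = scenario, scenario_params = params,
                       seed = eff_seeds[n_eff + i])))
  )
}
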