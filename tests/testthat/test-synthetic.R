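test_that("effective cycles match their spec and pass validation", {
  lc <- generate_effective_cycle(synthetic_spec(0.3, 200, 500, seed = 1))
  expect_identical(lc$truth_label, "effective")
  expect_true(lc$cycle$Ln %in% c(333L, 334L))
  expect_gt(peak_to_peak(lc$cycle$pressure), 300)
  expect_lt(peak_to_peak(lc$cycle$pressure), 1000)
  expect_gt(peak_to_peak(lc$cycle$flow), 100)
  expect_lt(peak_to_peak(lc$cycle$flow), 1650)
  expect_true(classify_cycle(lc$cycle)$is_effective)

  # flow sign convention: positive inspiratory run first, negative tail
  expect_gt(lc$cycle$flow[1], 0)
  expect_lt(lc$cycle$flow[lc$cycle$Ln], 0)
})

test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(0.3, 200, 500, seed = 7)
  a <- generate_effective_cycle(spec)
  b <- generate_effective_cycle(spec)
  expect_identical(a$cycle$pressure, b$cycle$pressure)
  expect_identical(a$cycle$flow, b$cycle$flow)
  c <- generate_effective_cycle(synthetic_spec(0.3, 200, 500, seed = 8))
  expect_false(identical(a$cycle$flow, c$cycle$flow))

  # generation must not disturb the caller's RNG stream
  set.seed(123)
  before <- .Random.seed
  generate_effective_cycle(spec)
  expect_identical(.Random.seed, before)

  expect_error(generate_effective_cycle(synthetic_spec(0.3, 200, 500)),
               "seed")
})

test_that("noise-free cycles have their fundamental as dominant frequency", {
  lc <- generate_effective_cycle(
    synthetic_spec(0.25, 300, 500, noise_sigma_frac = 0, seed = 1))
  fs <- lc$cycle$sampling_rate_hz
  expect_equal(dominant_frequency(lc$cycle$flow, fs), 0.25,
               tolerance = 0.0062 / 0.25)
  expect_equal(dominant_frequency(lc$cycle$pressure, fs), 0.25,
               tolerance = 0.0062 / 0.25)
})

test_that("interference scenarios carry their diagnostic signatures", {
  # weak: pressure VPP below MINPVT -> rejected on vpp_pressure
  weak <- generate_ineffective_cycle(
    synthetic_spec(0.3, 400, 600, scenario = "saturated_or_weak",
                   scenario_params = list(variant = "weak"), seed = 2))
  expect_lt(peak_to_peak(weak$cycle$pressure), 300)
  res <- classify_cycle(weak$cycle)
  expect_false(res$is_effective)
  expect_true("vpp_pressure" %in% res$failed_criteria)

  # saturated: clipped pressure VPP above MAXPVT
  sat <- generate_ineffective_cycle(
    synthetic_spec(0.3, 400, 600, scenario = "saturated_or_weak",
                   scenario_params = list(variant = "saturated"), seed = 3))
  expect_gt(peak_to_peak(sat$cycle$pressure), 1000)
  expect_lte(max(abs(sat$cycle$pressure)), 600 + 50)  # clipped near full scale
  expect_false(classify_cycle(sat$cycle)$is_effective)

  # zeroed channel: near-zero VPP on the dead channel
  zer <- generate_ineffective_cycle(
    synthetic_spec(0.3, 400, 600, scenario = "not_worn_properly",
                   scenario_params = list(variant = "zeroed"), seed = 4))
  expect_lt(peak_to_peak(zer$cycle$pressure), 10)
  res <- classify_cycle(zer$cycle)
  expect_false(res$is_effective)
  expect_true("vpp_pressure" %in% res$failed_criteria)

  # drift: dominant frequency below the 0.12 Hz band edge
  dr <- generate_ineffective_cycle(
    synthetic_spec(0.3, 400, 600, scenario = "not_worn_properly",
                   scenario_params = list(variant = "drift"), seed = 5))
  expect_lt(dominant_frequency(dr$cycle$flow, 100), 0.12)
  expect_false(classify_cycle(dr$cycle)$is_effective)

  # multiple breaths: base period retained, spectral energy above 0.6 Hz
  mb <- generate_ineffective_cycle(
    synthetic_spec(0.3, 400, 600, scenario = "multiple_breaths",
                   scenario_params = list(burst_phase = "inspiratory",
                                          burst_amp_frac = 0.8),
                   seed = 6))
  v <- mb$cycle$flow - mean(mb$cycle$flow)
  mag <- Mod(stats::fft(rep(v, length.out = 16384)))[2:8193]
  freqs <- (1:8192) * 100 / 16384
  high_frac <- sum(mag[freqs > 0.6]^2) / sum(mag^2)
  expect_gt(high_frac, 0.1)
  expect_equal(dominant_frequency(mb$cycle$flow, 100), 0.3, tolerance = 0.05)

  expect_error(generate_ineffective_cycle(synthetic_spec(seed = 1)),
               "scenario")
})

test_that("generated effective cycles are accepted at high rate (invariant)", {
  seeds <- rhinoflow:::derive_seeds(97, 100)
  ok <- vapply(seeds, function(s)
    classify_cycle(generate_effective_cycle(synthetic_spec(seed = s))$cycle)$is_effective,
    logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("saturated/weak and zeroed/one-signed cycles are always rejected", {
  seeds <- rhinoflow:::derive_seeds(131, 40)
  for (args in list(list(scenario = "saturated_or_weak", params = list()),
                    list(scenario = "not_worn_properly",
                         params = list(variant = "zeroed")),
                    list(scenario = "not_worn_properly",
                         params = list(variant = "one_signed")))) {
    rejected <- vapply(seeds, function(s) {
      lc <- generate_ineffective_cycle(
        synthetic_spec(scenario = args$scenario,
                       scenario_params = args$params, seed = s))
      !classify_cycle(lc$cycle)$is_effective
    }, logical(1))
    expect_true(all(rejected), label = args$scenario)
  }
})

test_that("generate_recording bookkeeping, DC offset, and determinism", {
  specs <- lapply(1:3, function(i) synthetic_spec(0.3, 250, 500, seed = i))
  gen <- generate_recording(specs, gap_s = 0.2, seed = 1)
  cycle_len <- sum(vapply(gen$cycles, function(lc) lc$cycle$Ln, integer(1)))
  expect_equal(length(gen$recording$flow), cycle_len + 2 * 20)
  expect_equal(gen$boundaries$start,
               vapply(gen$cycles, function(lc) lc$cycle$start_index, integer(1)))

  # dc offset shifts the recording mean by exactly the offset
  specs_dc <- lapply(1:3, function(i)
    synthetic_spec(0.3, 250, 500, dc_offset_pa = 50, seed = i))
  gen_dc <- generate_recording(specs_dc, seed = 1)
  expect_equal(mean(gen_dc$recording$pressure) - mean(gen$recording$pressure),
               50, tolerance = 1e-6)
  # absolute mean is near 50 Pa up to the intrinsic (physical) nonzero mean
  # of the quadratic pressure waveform over asymmetric phases
  expect_equal(mean(gen_dc$recording$pressure), 50, tolerance = 0.3)

  gen2 <- generate_recording(specs, gap_s = 0.2, seed = 1)
  expect_identical(gen$recording$pressure, gen2$recording$pressure)
  expect_identical(gen$recording$flow, gen2$recording$flow)

  expect_error(generate_recording(list()), "non-empty")
})
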