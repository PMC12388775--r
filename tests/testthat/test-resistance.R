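test_that("split_phases separates the positive and negative flow runs", {
  cyc <- respiratory_cycle(c(20, 30, 10, -10, -20, -10),
                           c(2, 3, 1, -1, -2, -1), 100)
  ph <- split_phases(cyc)
  expect_equal(ph$inspiratory$flow, c(2, 3, 1))
  expect_equal(ph$expiratory$flow, c(1, 2, 1))      # negated magnitudes
  expect_equal(ph$expiratory$pressure, c(10, 20, 10))

  all_pos <- respiratory_cycle(1:6, rep(2, 6), 100)
  ph <- split_phases(all_pos)
  expect_null(ph$expiratory)
  expect_length(ph$inspiratory$flow, 6)

  # generator ground truth: inspiratory length ~ insp_fraction * Ln
  lc <- generate_effective_cycle(synthetic_spec(0.3, 250, 500,
                                                insp_fraction = 0.45,
                                                noise_sigma_frac = 0,
                                                seed = 1))
  ph <- split_phases(lc$cycle)
  expect_lte(abs(length(ph$inspiratory$flow) - round(0.45 * lc$cycle$Ln)), 2)
})

test_that("mean_resistance interpolates flow at the reference pressure", {
  seg <- make_segment(c(140, 160), c(560, 640))
  expect_equal(mean_resistance(seg), 150 / 600)

  exact <- make_segment(c(100, 150, 180), c(400, 500, 560))
  expect_equal(mean_resistance(exact), 0.30)

  low <- make_segment(c(80, 120, 90), c(300, 500, 350))
  r <- mean_resistance(low)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "not reached")
})

test_that("vertex_resistance picks the earliest maximal-flow sample", {
  expect_equal(vertex_resistance(make_segment(c(100, 144, 120),
                                              c(400, 600, 500))), 0.24)
  # proportional signals: ratio everywhere, peak location irrelevant
  v <- c(100, 400, 250)
  expect_equal(vertex_resistance(make_segment(0.5 * v, v)), 0.5)
  # tie in |flow|: earliest sample used
  expect_equal(vertex_resistance(make_segment(c(90, 150), c(600, 600))),
               90 / 600)
  expect_true(is.na(vertex_resistance(make_segment(c(0, 0), c(0, 0)))))
})

test_that("effective_resistance is the RMS ratio", {
  t <- seq(0, pi, length.out = 200)
  expect_equal(effective_resistance(make_segment(150 * sin(t), 500 * sin(t),
                                                 dt = 0.01)),
               0.30)
  expect_equal(effective_resistance(make_segment(rep(100, 50), rep(400, 50))),
               0.25)
  set.seed(8)
  v <- abs(rnorm(100, 300, 80))
  expect_equal(effective_resistance(make_segment(0.6 * v, v)), 0.6)
})

test_that("broms_resistance fits the polar angle law at radius 2", {
  # constant-angle ray y = x spanning the band: R = tan(pi/4) = 1
  r <- seq(1.6, 2.4, by = 0.1)
  x <- r / sqrt(2) * 100
  expect_equal(as.numeric(broms_resistance(make_segment(x, x))), 1,
               tolerance = 1e-9)

  # exact angle law v = 0.2 + 0.1 r: recovered coefficients and tan(0.4)
  r <- seq(1.75, 2.25, by = 0.05)
  ang <- 0.2 + 0.1 * r
  seg <- make_segment(100 * r * sin(ang), 100 * r * cos(ang))
  b <- broms_resistance(seg)
  fit <- attr(b, "fit")
  expect_equal(fit$v0, 0.2, tolerance = 1e-9)
  expect_equal(fit$c, 0.1, tolerance = 1e-9)
  expect_equal(as.numeric(b), tan(0.4), tolerance = 1e-9)
  expect_equal(as.numeric(b), 0.422793, tolerance = 1e-6)

  # curve never reaches the band
  far <- make_segment(c(30, 60, 90), c(40, 80, 120))
  expect_true(is.na(broms_resistance(far)))
  expect_match(attr(broms_resistance(far), "reason"), "radius")
})

test_that("compute_all routes per-cycle and averaged indicators correctly", {
  # k chosen so pressure crosses 150 Pa at exactly 600 cm3/s
  k <- 150 / 600^2
  cycles <- replicate(4, make_quadratic_cycle(k = k, v_amp = 650),
                      simplify = FALSE)
  res <- compute_all(cycles)
  expect_equal(unname(res$group[["mean_ins"]]), 0.25, tolerance = 1e-3)
  expect_true(all(abs(res$per_cycle$mean_ins - 0.25) < 1e-3))
  expect_true(all(res$status[c("mean_ins", "mean_exp", "vertex_ins",
                               "vertex_exp", "effective_ins",
                               "effective_exp")] == "ok"))

  # single cycle: group equals the cycle
  one <- compute_all(cycles[1])
  expect_equal(one$group[["vertex_ins"]], one$per_cycle$vertex_ins[1])

  # proportional cycles p = 0.5 v: vertex = effective = broms = 0.5
  lin <- replicate(3, make_linear_cycle(0.5), simplify = FALSE)
  resl <- compute_all(lin)
  expect_equal(unname(resl$group[["vertex_ins"]]), 0.5, tolerance = 1e-6)
  expect_equal(unname(resl$group[["vertex_exp"]]), 0.5, tolerance = 1e-6)
  expect_equal(unname(resl$group[["effective_ins"]]), 0.5, tolerance = 1e-6)
  expect_equal(unname(resl$group[["broms_ins"]]), 0.5, tolerance = 1e-3)

  expect_error(compute_all(list()), "no effective cycles")
})

test_that("flow rescaling divides the linear-path indicators by the factor", {
  k <- 150 / 600^2
  cyc <- make_quadratic_cycle(k = k, v_amp = 650)
  lam <- 2
  scaled <- respiratory_cycle(cyc$pressure, cyc$flow * lam, 100)
  a <- compute_all(list(cyc))$group
  b <- compute_all(list(scaled))$group
  for (ind in c("vertex_ins", "vertex_exp", "effective_ins", "effective_exp",
                "mean_ins", "mean_exp"))
    expect_equal(b[[ind]], a[[ind]] / lam, tolerance = 1e-6)
})

test_that("interpret_severity applies the 0.75 cutoff", {
  expect_identical(interpret_severity(0.74), "normal")
  expect_identical(interpret_severity(0.75), "obstructed")
  expect_identical(interpret_severity(0.791), "obstructed")
  expect_error(interpret_severity(-0.1), "non-negative")
})
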