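test_that("classification_metrics counts the 2x2 table", {
  m <- classification_metrics(c("effective", "effective", "ineffective",
                                "ineffective"),
                              c("effective", "effective", "effective",
                                "ineffective"))
  expect_equal(m$recall, 1.0)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$accuracy, 0.75)
  expect_equal(unname(m$counts), c(2, 1, 0, 1))   # tp fp fn tn
  expect_equal(unname(m$percentages), c(50, 25, 0, 25))

  perfect <- classification_metrics(c("effective", "ineffective"),
                                    c("effective", "ineffective"))
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$accuracy, 1)

  # all predicted ineffective: recall 0, precision undefined (not 0)
  none <- classification_metrics(c("effective", "ineffective"),
                                 c("ineffective", "ineffective"))
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))

  expect_error(classification_metrics(character(0), character(0)),
               "non-empty")
})

test_that("scenario_accuracy reports per-scenario rejection fractions", {
  weak <- make_labeled_corpus(0, 10, "saturated_or_weak", seed = 21,
                              params = list(variant = "weak"))
  acc <- scenario_accuracy(weak)
  expect_equal(unname(acc[["saturated_or_weak"]]), 1.0)

  eff_only <- make_labeled_corpus(5, 0, "none", seed = 22)
  expect_length(scenario_accuracy(eff_only), 0)
})

test_that("grid_search separates a toy corpus on pressure VPP", {
  # controlled features: noise-free quadratic cycles rescaled to exact VPPs;
  # frequency and flow VPP are inside every candidate interval
  base <- make_quadratic_cycle(f = 0.3, k = 400 / 600^2, v_amp = 600)
  with_vpp <- function(vpp_p) respiratory_cycle(
    base$pressure * (vpp_p / peak_to_peak(base$pressure)), base$flow, 100)
  labeled <- list(
    labeled_cycle(with_vpp(400), "effective"),
    labeled_cycle(with_vpp(500), "effective"),
    labeled_cycle(with_vpp(150), "ineffective", "saturated_or_weak"),
    labeled_cycle(with_vpp(1200), "ineffective", "saturated_or_weak"))
  grid <- grid_spec(fft_range_hz = c(0.1, 0.7, 0.3),
                    pvt_range_pa = c(100, 1300, 200),
                    fvt_range_cm3s = c(500, 1500, 500))
  res <- grid_search(labeled, grid)
  expect_equal(res$top_accuracy, 1.0)
  top <- res$ranking[1, ]
  expect_lte(top$minpvt_pa, 400)
  expect_gte(top$minpvt_pa, 200)       # must exclude the 150 Pa cycle
  expect_gte(top$maxpvt_pa, 500)
  expect_lte(top$maxpvt_pa, 1100)      # must exclude the 1200 Pa cycle

  expect_error(grid_search(labeled[1:2], grid), "degenerate labels")
})

test_that("cached-feature search equals naive per-combination classification", {
  labeled <- make_labeled_corpus(6, 6, "saturated_or_weak", seed = 31)
  grid <- grid_spec(fft_range_hz = c(0.1, 0.7, 0.2),
                    pvt_range_pa = c(100, 1100, 250),
                    fvt_range_cm3s = c(50, 1850, 450))
  res <- grid_search(labeled, grid, top_k = 1e6)

  vals <- function(r) seq(r[1], r[2] + 1e-9, by = r[3])
  truth <- vapply(labeled, `[[`, character(1), "truth_label")
  naive <- function(ts) {
    pred <- vapply(labeled, function(lc)
      if (classify_cycle(lc$cycle, ts)$is_effective) "effective"
      else "ineffective", character(1))
    mean(pred == truth)
  }
  # verify a sample of rows of the ranking against naive reclassification
  idx <- seq(1, nrow(res$ranking), length.out = 12)
  for (i in unique(round(idx))) {
    row <- res$ranking[i, ]
    ts <- threshold_set(row$minft_hz, row$maxft_hz, row$minpvt_pa,
                        row$maxpvt_pa, row$minfvt_cm3s, row$maxfvt_cm3s)
    expect_equal(row$accuracy, naive(ts))
  }
})

test_that("ties are broken by widest frequency, then VPP intervals", {
  r <- grid_search(make_labeled_corpus(4, 4, "saturated_or_weak", seed = 41),
                   grid_spec(fft_range_hz = c(0.1, 0.7, 0.2),
                             pvt_range_pa = c(100, 1100, 500),
                             fvt_range_cm3s = c(50, 1850, 900)),
                   top_k = 1e6)$ranking
  key <- order(-r$accuracy, -(r$maxft_hz - r$minft_hz),
               -(r$maxpvt_pa - r$minpvt_pa), -(r$maxfvt_cm3s - r$minfvt_cm3s))
  expect_identical(key, seq_len(nrow(r)))
  # among equal-accuracy rows the frequency interval is non-increasing
  top_acc <- r[r$accuracy == r$accuracy[1], ]
  expect_true(all(diff(top_acc$maxft_hz - top_acc$minft_hz) <= 0))
})

test_that("top accuracy is non-decreasing under grid refinement", {
  labeled <- make_labeled_corpus(5, 5, "saturated_or_weak", seed = 51)
  coarse <- grid_search(labeled, grid_spec(c(0.1, 0.7, 0.3),
                                           c(100, 1100, 500),
                                           c(50, 1850, 900)))
  fine <- grid_search(labeled, grid_spec(c(0.1, 0.7, 0.15),
                                         c(100, 1100, 250),
                                         c(50, 1850, 450)))
  expect_gte(fine$top_accuracy, coarse$top_accuracy)
})

test_that("the default thresholds achieve perfect accuracy on a clean corpus", {
  labeled <- c(make_labeled_corpus(10, 5, "saturated_or_weak", seed = 61),
               make_labeled_corpus(0, 5, "not_worn_properly", seed = 62,
                                   params = list(variant = "drift")))
  feat_acc <- grid_search(labeled,
                          grid_spec(fft_range_hz = c(0.12, 0.6, 0.48),
                                    pvt_range_pa = c(300, 1000, 700),
                                    fvt_range_cm3s = c(100, 1650, 1550)))
  expect_equal(feat_acc$top_accuracy, 1.0)
})
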