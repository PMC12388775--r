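# Exhaustive grid search over the six classifier thresholds, scored by
# classification accuracy against ground-truth labels. Per-cycle features
# (dominant frequencies and VPPs) are computed once and reused across the
# grid, which is what makes exhaustive search tractable.

#' Specify a threshold search grid
#'
#' Each axis is a `(lo, hi, step)` triple; candidate (min, max) threshold
#' pairs are all ordered pairs of distinct grid values on that axis.
#'
#' @param fft_range_hz frequency axis, default `c(0.05, 0.7, 0.01)` (the
#'   0.01 Hz step used when the optimal thresholds were tuned).
#' @param pvt_range_pa pressure-VPP axis, default `c(100, 1500, 50)`.
#' @param fvt_range_cm3s flow-VPP axis, default `c(50, 2000, 50)`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(fft_range_hz = c(0.05, 0.7, 0.01),
                      pvt_range_pa = c(100, 1500, 50),
                      fvt_range_cm3s = c(50, 2000, 50)) {
  check <- function(r, name) {
    if (length(r) != 3L || r[1] >= r[2] || r[3] <= 0)
      stop(name, " must be c(lo, hi, step) with lo < hi and step > 0")
    r
  }
  structure(list(fft_range_hz = check(fft_range_hz, "fft_range_hz"),
                 pvt_range_pa = check(pvt_range_pa, "pvt_range_pa"),
                 fvt_range_cm3s = check(fvt_range_cm3s, "fvt_range_cm3s")),
            class = "grid_spec")
}

#' Confusion-matrix metrics for the effective class
#'
#' @param truth,predicted equal-length character vectors of
#'   `"effective"` / `"ineffective"` labels.
#' @return List with the confusion `counts` (tp, fp, fn, tn), `percentages`
#'   (of the total), `recall`, `precision` (both for the effective class;
#'   `NA` when the denominator is zero), `accuracy`, and `n`.
#' @export
classification_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0L)
    stop("truth and predicted must be non-empty and of equal length")
  te <- truth == "effective"
  pe <- predicted == "effective"
  tp <- sum(te & pe); fp <- sum(!te & pe)
  fn <- sum(te & !pe); tn <- sum(!te & !pe)
  n <- length(truth)
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  list(counts = counts,
       percentages = 100 * counts / n,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       accuracy = (tp + tn) / n,
       n = n)
}

cycle_features <- function(cycles) {
  feat <- t(vapply(cycles, function(cyc) {
    fs <- cyc$sampling_rate_hz
    c(f_p = tryCatch(dominant_frequency(cyc$pressure, fs),
                     error = function(e) NA_real_),
      f_f = tryCatch(dominant_frequency(cyc$flow, fs),
                     error = function(e) NA_real_),
      vpp_p = peak_to_peak(cyc$pressure),
      vpp_f = peak_to_peak(cyc$flow))
  }, numeric(4)))
  as.data.frame(feat)
}

predict_from_features <- function(feat, ts) {
  ok <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  ok(feat$f_p, ts$minft_hz, ts$maxft_hz) &
    ok(feat$f_f, ts$minft_hz, ts$maxft_hz) &
    ok(feat$vpp_p, ts$minpvt_pa, ts$maxpvt_pa) &
    ok(feat$vpp_f, ts$minfvt_cm3s, ts$maxfvt_cm3s)
}

#' Per-scenario rejection accuracy
#'
#' For each interference scenario present in the labeled set, the fraction
#' of that scenario's cycles classified ineffective by the thresholds.
#'
#' @param labeled list of [labeled_cycle()] objects.
#' @param ts a [threshold_set()].
#' @return Named numeric vector over the scenarios present (excluding
#'   `"none"`); empty when the set has no ineffective cycles.
#' @export
scenario_accuracy <- function(labeled, ts = default_thresholds()) {
  scen <- vapply(labeled, `[[`, character(1), "scenario")
  keep <- scen != "none"
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  feat <- cycle_features(lapply(labeled[keep], `[[`, "cycle"))
  pred_eff <- predict_from_features(feat, ts)
  tapply(!pred_eff, scen[keep], mean)
}

#' Exhaustive threshold grid search
#'
#' Evaluates classification accuracy for every threshold combination on the
#' grid (per-cycle features computed once). Ties in accuracy are broken in
#' favor of the widest frequency interval, then the widest pressure-VPP
#' interval, then the widest flow-VPP interval, maximizing the admitted
#' range of effective breathing.
#'
#' @param labeled list of [labeled_cycle()] objects containing both classes.
#' @param grid a [grid_spec()]. The default full grid is large (~1e7
#'   combinations); narrow it for interactive use.
#' @param top_k number of top-ranked threshold sets to keep, default 1000.
#' @return An object of class `search_result`: `ranking` (data.frame of the
#'   six thresholds plus `accuracy`, sorted) and `top_accuracy`.
#' @export
grid_search <- function(labeled, grid = grid_spec(), top_k = 1000L) {
  stopifnot(inherits(grid, "grid_spec"))
  truth <- vapply(labeled, `[[`, character(1), "truth_label")
  if (length(unique(truth)) < 2L)
    stop("degenerate labels: need both effective and ineffective cycles")
  feat <- cycle_features(lapply(labeled, `[[`, "cycle"))
  te <- truth == "effective"

  vals <- function(r) seq(r[1], r[2] + 1e-9, by = r[3])
  pairs <- function(v) {
    i <- which(outer(v, v, `<`), arr.ind = TRUE)
    cbind(lo = v[i[, 1L]], hi = v[i[, 2L]])
  }
  fp_ <- pairs(vals(grid$fft_range_hz))
  pp_ <- pairs(vals(grid$pvt_range_pa))
  vp_ <- pairs(vals(grid$fvt_range_cm3s))
  in_rng <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

  rows <- vector("list", nrow(fp_) * nrow(pp_) * nrow(vp_))
  r <- 0L
  n <- length(te)
  for (i in seq_len(nrow(fp_))) {
    f_ok <- in_rng(feat$f_p, fp_[i, 1L], fp_[i, 2L]) &
      in_rng(feat$f_f, fp_[i, 1L], fp_[i, 2L])
    for (j in seq_len(nrow(pp_))) {
      fp_ok <- f_ok & in_rng(feat$vpp_p, pp_[j, 1L], pp_[j, 2L])
      for (k in seq_len(nrow(vp_))) {
        pred <- fp_ok & in_rng(feat$vpp_f, vp_[k, 1L], vp_[k, 2L])
        r <- r + 1L
        rows[[r]] <- c(fp_[i, ], pp_[j, ], vp_[k, ],
                       sum(pred == te) / n)
      }
    }
  }
  ranking <- as.data.frame(do.call(rbind, rows))
  names(ranking) <- c("minft_hz", "maxft_hz", "minpvt_pa", "maxpvt_pa",
                      "minfvt_cm3s", "maxfvt_cm3s", "accuracy")
  ord <- order(-ranking$accuracy,
               -(ranking$maxft_hz - ranking$minft_hz),
               -(ranking$maxpvt_pa - ranking$minpvt_pa),
               -(ranking$maxfvt_cm3s - ranking$minfvt_cm3s))
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = utils::head(ranking, top_k),
                 top_accuracy = ranking$accuracy[1L],
                 n_combinations = nrow(ranking)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d combination(s), top accuracy %.4f\n",
              x$n_combinations, x$top_accuracy))
  print(utils::head(x$ranking, 5))
  invisible(x)
}
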