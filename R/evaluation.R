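# Stability analysis: how much does cycle filtering reduce the within-group
# spread of each resistance indicator? Groups emulate repeated measurement
# sessions of one subject; the spread statistic is the sample (n-1) standard
# deviation, summarized across groups by median and IQR (linear-interpolation
# quantiles, R type 7).

INDICATORS <- c("mean_ins", "mean_exp", "broms_ins", "broms_exp",
                "vertex_ins", "vertex_exp", "effective_ins", "effective_exp")

#' Within-group standard deviation of the resistance indicators
#'
#' For each group of cycles, computes all four indicators per cycle (gated by
#' the thresholds in `"filtered"` mode, ungated in `"unfiltered"` mode) and
#' takes the sample standard deviation per indicator; the SD distribution
#' across groups is summarized by median and IQR. Groups with fewer than 2
#' usable cycles in a mode are excluded with a warning.
#'
#' @param groups list of groups, each a list of [respiratory_cycle()]
#'   objects.
#' @param ts a [threshold_set()] (used in filtered mode).
#' @param mode `"filtered"` or `"unfiltered"`.
#' @param config resistance configuration, see [resistance_config()].
#' @return An object of class `stability_summary`: `mode`, `group_sds`
#'   (matrix, groups x indicators), and `summary` (data.frame with
#'   `median_sd`, `q1`, `q3`, `iqr_sd`, `n_groups` per indicator;
#'   quantile rule: linear interpolation, R type 7).
#' @export
within_group_sd <- function(groups, ts = default_thresholds(),
                            mode = c("filtered", "unfiltered"),
                            config = resistance_config()) {
  mode <- match.arg(mode)
  sds <- matrix(NA_real_, length(groups), length(INDICATORS),
                dimnames = list(NULL, INDICATORS))
  dropped <- 0L
  for (g in seq_along(groups)) {
    cycles <- groups[[g]]
    if (mode == "filtered")
      cycles <- filter_effective(cycles, ts)$effective
    if (length(cycles) < 2L) {
      dropped <- dropped + 1L
      next
    }
    per <- compute_all(cycles, config)$per_cycle
    sds[g, ] <- vapply(INDICATORS, function(ind) {
      x <- per[[ind]]
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else stats::sd(x)
    }, numeric(1))
  }
  if (dropped > 0L)
    warning(sprintf("%d group(s) with < 2 usable cycles excluded (%s mode)",
                    dropped, mode))
  summ <- do.call(rbind, lapply(INDICATORS, function(ind) {
    x <- sds[, ind]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(data.frame(indicator = ind, median_sd = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, iqr_sd = NA_real_, n_groups = 0L))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(indicator = ind, median_sd = q[2L], q1 = q[1L], q3 = q[3L],
               iqr_sd = q[3L] - q[1L], n_groups = length(x))
  }))
  rownames(summ) <- NULL
  structure(list(mode = mode, group_sds = sds, summary = summ,
                 quantile_rule = "linear interpolation (R type 7)"),
            class = "stability_summary")
}

#' Filtering-vs-no-filtering stability report
#'
#' Per indicator, the ratio of the unfiltered to the filtered median
#' within-group SD (how many times filtering shrinks the spread).
#'
#' @param summary_filtered,summary_unfiltered `stability_summary` objects
#'   from [within_group_sd()] for the same groups.
#' @return Data frame with one row per indicator: the two medians and IQRs,
#'   `ratio` (`Inf` flagged via `ratio_infinite` when the filtered median is
#'   0), of class `stability_report`.
#' @export
stability_report <- function(summary_filtered, summary_unfiltered) {
  stopifnot(inherits(summary_filtered, "stability_summary"),
            inherits(summary_unfiltered, "stability_summary"))
  f <- summary_filtered$summary
  u <- summary_unfiltered$summary
  stopifnot(identical(f$indicator, u$indicator))
  ratio <- ifelse(f$median_sd == 0, Inf, u$median_sd / f$median_sd)
  out <- data.frame(indicator = f$indicator,
                    unfiltered_median_sd = u$median_sd,
                    filtered_median_sd = f$median_sd,
                    unfiltered_iqr = u$iqr_sd,
                    filtered_iqr = f$iqr_sd,
                    ratio = ratio,
                    ratio_infinite = f$median_sd == 0)
  class(out) <- c("stability_report", "data.frame")
  out
}
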