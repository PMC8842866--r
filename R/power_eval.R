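#' Label intervals and markers against simulated truth
#'
#' An interval is a *true positive* iff its `[start, end]` range contains a
#' true (major) QTL position on the same chromosome. All markers of a
#' true-positive interval are true-positive markers; significant markers in
#' other intervals are false positives; isolated significant markers are
#' ignored for precision. For the false-positive *rate*, true negatives `N`
#' are all scanned loci outside every `+/- window` cM band around the true
#' positions, and FP counts significant loci outside those bands.
#'
#' @param intervals a [call_intervals()] result.
#' @param truth data.frame with `chromosome` and `position_cM` of the true
#'   (major) QTLs, or a [qtl_spec()].
#' @param window half-width of the true-QTL band in cM (5 by default,
#'   i.e. a 10 cM interval).
#' @return List with interval labels, marker classifications and the counts
#'   used by the power metrics.
#' @export
classify <- function(intervals, truth, window = 5) {
  if (inherits(truth, "qtl_spec")) truth <- truth$major
  truth$chromosome <- as.character(truth$chromosome)
  scan <- intervals$scan
  ivs <- intervals$intervals

  iv_tp <- vapply(ivs, function(iv) {
    any(truth$chromosome == iv$chromosome &
          truth$position_cM >= iv$start & truth$position_cM <= iv$end)
  }, logical(1))

  qtl_covered <- vapply(seq_len(nrow(truth)), function(q) {
    any(vapply(ivs, function(iv)
      iv$chromosome == truth$chromosome[q] &&
        truth$position_cM[q] >= iv$start && truth$position_cM[q] <= iv$end,
      logical(1)))
  }, logical(1))

  sig <- scan$neglog10p > intervals$threshold
  in_window <- rep(FALSE, nrow(scan))
  for (q in seq_len(nrow(truth))) {
    in_window <- in_window |
      (scan$chromosome == truth$chromosome[q] &
         abs(scan$position_cM - truth$position_cM[q]) <= window)
  }

  tp_markers <- unlist(lapply(ivs[iv_tp], `[[`, "members"))
  all_iv_markers <- unlist(lapply(ivs, `[[`, "members"))

  list(interval_tp = iv_tp, qtl_covered = qtl_covered,
       n_intervals = length(ivs), n_tp_intervals = sum(iv_tp),
       tp_markers = tp_markers, all_iv_markers = all_iv_markers,
       n_true_negative = sum(!in_window),
       n_fp_rate = sum(sig & !in_window),
       truth = truth, window = window)
}

#' QTL detection power
#'
#' Proportion of true QTLs covered by at least one true-positive interval;
#' a QTL covered by several intervals counts once.
#'
#' @param cls a [classify()] result.
#' @return Proportion in `[0, 1]`.
#' @export
detection_power <- function(cls) mean(cls$qtl_covered)

#' False-positive rate FP/N
#'
#' Significant loci outside the true-QTL bands divided by all loci outside
#' the bands. `NA` (absent, with a warning) when no locus lies outside the
#' bands.
#'
#' @param cls a [classify()] result.
#' @return Rate in `[0, 1]`, or `NA`.
#' @export
false_positive_rate <- function(cls) {
  if (cls$n_true_negative == 0) {
    warning("no true-negative markers: FP rate undefined")
    return(NA_real_)
  }
  cls$n_fp_rate / cls$n_true_negative
}

#' QTL-level and marker-level precision
#'
#' `qtl_precision` = true-positive intervals / detected intervals;
#' `marker_precision` = markers in true-positive intervals / markers in all
#' intervals. Both are `NA` (absent) when no interval was detected, never 0,
#' so averages stay honest.
#'
#' @param cls a [classify()] result.
#' @return Named numeric vector `c(qtl_precision=, marker_precision=)`.
#' @export
precisions <- function(cls) {
  if (cls$n_intervals == 0)
    return(c(qtl_precision = NA_real_, marker_precision = NA_real_))
  c(qtl_precision = cls$n_tp_intervals / cls$n_intervals,
    marker_precision = length(cls$tp_markers) / length(cls$all_iv_markers))
}

#' Peak accuracy
#'
#' Mean distance (cM) between the peak of each true-positive interval and
#' the nearest true QTL position it contains. `NA` when there is no
#' true-positive interval.
#'
#' @param intervals a [call_intervals()] result.
#' @param cls the matching [classify()] result.
#' @return Mean distance in cM, or `NA`.
#' @export
peak_accuracy <- function(intervals, cls) {
  tp <- which(cls$interval_tp)
  if (length(tp) == 0) return(NA_real_)
  scan <- intervals$scan
  d <- vapply(tp, function(i) {
    iv <- intervals$intervals[[i]]
    inside <- cls$truth$chromosome == iv$chromosome &
      cls$truth$position_cM >= iv$start & cls$truth$position_cM <= iv$end
    min(abs(scan$position_cM[iv$peak] - cls$truth$position_cM[inside]))
  }, numeric(1))
  mean(d)
}

#' All power metrics for one scan at one linking distance
#'
#' @param scan a `qtl_scan`.
#' @param threshold significance cutoff (`-log10 p`).
#' @param truth true major-QTL positions ([qtl_spec()] or data.frame).
#' @param l linking distance in cM.
#' @param window half-width of the true-QTL band in cM.
#' @return One-row data.frame with the five power metrics plus provenance
#'   columns.
#' @export
power_report <- function(scan, threshold, truth, l, window = 5) {
  ivs <- call_intervals(scan, threshold, l)
  cls <- classify(ivs, truth, window)
  pr <- precisions(cls)
  fpr <- if (cls$n_true_negative == 0) NA_real_ else
    cls$n_fp_rate / cls$n_true_negative
  data.frame(model = scan$model[1], l = l, threshold = threshold,
             detection_power = detection_power(cls),
             false_positive_rate = fpr,
             qtl_precision = unname(pr["qtl_precision"]),
             marker_precision = unname(pr["marker_precision"]),
             peak_accuracy_cM = peak_accuracy(ivs, cls),
             n_intervals = cls$n_intervals,
             n_tp_intervals = cls$n_tp_intervals,
             stringsAsFactors = FALSE)
}
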