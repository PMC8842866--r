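#' Call QTL intervals by the linking-distance chain rule
#'
#' Significant markers (`-log10 p` above `threshold`) are partitioned, per
#' chromosome, into maximal chains in which every pair of *adjacent
#' significant* markers is separated by strictly less than `l` cM
#' (non-significant markers in between do not break a chain). Chains of a
#' single marker are ignored; each surviving chain becomes a QTL interval
#' whose peak is its most significant member (leftmost on ties). With
#' `l = 0` no pair can chain and no intervals are produced.
#'
#' @param scan a `qtl_scan` from [scan_qtl()].
#' @param threshold significance cutoff on the `-log10 p` scale.
#' @param l linking distance in cM (`>= 0`).
#' @return A `qtl_intervals` list: `intervals` (each with `chromosome`,
#'   `members` = scan row indices, `start`, `end`, `peak` = scan row index),
#'   a summary `table`, `l`, `threshold`.
#' @export
call_intervals <- function(scan, threshold, l) {
  if (l < 0) stop("linking distance l must be >= 0")
  stopifnot(inherits(scan, "qtl_scan"))
  sig <- which(scan$neglog10p > threshold)
  intervals <- list()
  for (ch in unique(scan$chromosome[sig])) {
    s <- sig[scan$chromosome[sig] == ch]
    s <- s[order(scan$position_cM[s])]
    if (length(s) == 0) next
    gap_new <- c(TRUE, diff(scan$position_cM[s]) >= l)
    chain_id <- cumsum(gap_new)
    for (members in split(s, chain_id)) {
      if (length(members) < 2) next  # isolated significant markers ignored
      pk <- members[which.max(scan$neglog10p[members])]
      intervals[[length(intervals) + 1L]] <- list(
        chromosome = ch, members = members,
        start = scan$position_cM[members[1]],
        end = scan$position_cM[members[length(members)]],
        peak = pk)
    }
  }
  table <- if (length(intervals)) do.call(rbind, lapply(intervals, function(iv)
    data.frame(chromosome = iv$chromosome, start_cM = iv$start,
               end_cM = iv$end, n_markers = length(iv$members),
               peak_marker = scan$locus[iv$peak],
               peak_cM = scan$position_cM[iv$peak],
               peak_neglog10p = scan$neglog10p[iv$peak],
               l = l, threshold = threshold, stringsAsFactors = FALSE)))
  else data.frame(chromosome = character(0), start_cM = numeric(0),
                  end_cM = numeric(0), n_markers = integer(0),
                  peak_marker = character(0), peak_cM = numeric(0),
                  peak_neglog10p = numeric(0), l = numeric(0),
                  threshold = numeric(0), stringsAsFactors = FALSE)
  structure(list(intervals = intervals, table = table, l = l,
                 threshold = threshold, scan = scan),
            class = "qtl_intervals")
}

#' @export
print.qtl_intervals <- function(x, ...) {
  cat(sprintf("%d QTL interval(s) at l = %g cM, threshold %.3f\n",
              length(x$intervals), x$l, x$threshold))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Peak of a QTL interval
#'
#' The most significant member marker (leftmost on ties).
#'
#' @param intervals a `qtl_intervals`.
#' @param i interval index.
#' @return List: `marker`, `position_cM`, `neglog10p`.
#' @export
peak_of <- function(intervals, i = 1) {
  iv <- intervals$intervals[[i]]
  list(marker = intervals$scan$locus[iv$peak],
       position_cM = intervals$scan$position_cM[iv$peak],
       neglog10p = intervals$scan$neglog10p[iv$peak])
}
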