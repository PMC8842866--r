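#' Plot a genome scan
#'
#' Simple unsmoothed `-log10 p` profile against cumulative map position,
#' chromosomes alternating in shade, with an optional threshold line.
#'
#' @param scan a `qtl_scan`.
#' @param threshold optional `-log10 p` cutoff drawn as a dashed line.
#' @param ... passed to [graphics::plot()].
#' @export
plot_scan <- function(scan, threshold = NULL, ...) {
  chroms <- unique(scan$chromosome)
  offs <- 0; xpos <- numeric(nrow(scan)); col <- integer(nrow(scan))
  for (i in seq_along(chroms)) {
    rows <- scan$chromosome == chroms[i]
    xpos[rows] <- scan$position_cM[rows] + offs
    col[rows] <- 1 + i %% 2
    offs <- max(xpos[rows]) + 5
  }
  graphics::plot(xpos, scan$neglog10p, pch = 20, cex = 0.4,
                 col = c("grey30", "steelblue")[col],
                 xlab = "cumulative position (cM)",
                 ylab = expression(-log[10] ~ p),
                 main = paste(scan$model[1], "model"), ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
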