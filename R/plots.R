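#' Manhattan-style plot of a window statistic
#'
#' Base-graphics plot of one window statistic along the genome, chromosomes
#' concatenated and alternately shaded, with optional highlighting of
#' selected windows.
#'
#' @param stats window table from [window_stats].
#' @param statistic column to plot (default `"fst"`).
#' @param highlight optional window subset (e.g. the scan selection) drawn
#'   in red.
#' @param ... passed to [graphics::plot].
#' @export
plot_manhattan <- function(stats, statistic = "fst", highlight = NULL, ...) {
  chroms <- unique(stats$chrom)
  offs <- setNames(cumsum(c(0, vapply(chroms, function(ch) {
    max(stats$end[stats$chrom == ch])
  }, numeric(1))))[seq_along(chroms)], chroms)
  x <- offs[stats$chrom] + (stats$start + stats$end) / 2
  y <- stats[[statistic]]
  col <- c("grey30", "grey60")[(match(stats$chrom, chroms) %% 2) + 1]
  graphics::plot(x, y, pch = 16, cex = 0.4, col = col, xaxt = "n",
                 xlab = "genome position", ylab = statistic, ...)
  graphics::axis(1, at = offs + vapply(chroms, function(ch) {
    max(stats$end[stats$chrom == ch])
  }, numeric(1)) / 2, labels = chroms)
  if (!is.null(highlight) && nrow(highlight) > 0) {
    hx <- offs[highlight$chrom] + (highlight$start + highlight$end) / 2
    graphics::points(hx, highlight[[statistic]], pch = 16, cex = 0.5, col = "red")
  }
  invisible(NULL)
}

#' Scatter plot of the leading principal components
#'
#' @param pca a [grm_pca] result.
#' @param components which two PCs to draw (default 1 and 2).
#' @export
plot_pca <- function(pca, components = c(1, 2)) {
  sc <- pca$scores
  cols <- c(HL = "#D55E00", LL = "#0072B2")
  xy <- sc[, paste0("PC", components)]
  graphics::plot(xy[[1]], xy[[2]], col = cols[sc$group], pch = 16,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * pca$varexp[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * pca$varexp[components[2]]))
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(NULL)
}
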