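#' Histographic biomarkers of a pooled pixel sample
#'
#' Computes the mean and the 25th, 50th, 75th and 90th percentiles of the
#' pooled subchondral pixel values — the quantitative imaging biomarkers
#' ADC_25/median/75/90 and PDFF_25/median/75/90 plus the means. Percentiles
#' use linear interpolation between order statistics (the usual "type 7"
#' empirical quantile); this matters on small samples and can be changed via
#' `quantile_type`.
#'
#' @param sample a [pixel_sample()] with at least one pixel.
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return An object of class `hist_metrics`: list with `mean`, `p25`, `p50`,
#'   `p75`, `p90`, `n_pixels`, `kind`.
#' @export
compute_metrics <- function(sample, quantile_type = 7) {
  stopifnot(inherits(sample, "pixel_sample"))
  if (sample$n_pixels < 1L) stop("empty pixel sample")
  q <- stats::quantile(sample$values, probs = c(0.25, 0.5, 0.75, 0.9),
                       type = quantile_type, names = FALSE)
  structure(list(mean = mean(sample$values),
                 p25 = q[1], p50 = q[2], p75 = q[3], p90 = q[4],
                 n_pixels = sample$n_pixels, kind = sample$kind),
            class = "hist_metrics")
}

#' @export
print.hist_metrics <- function(x, ...) {
  cat(sprintf("<hist_metrics> %s over %d pixels\n", x$kind, x$n_pixels))
  cat(sprintf("  mean %.4g | p25 %.4g | median %.4g | p75 %.4g | p90 %.4g\n",
              x$mean, x$p25, x$p50, x$p75, x$p90))
  invisible(x)
}

#' @export
as.data.frame.hist_metrics <- function(x, ...) {
  data.frame(kind = x$kind, mean = x$mean, p25 = x$p25, p50 = x$p50,
             p75 = x$p75, p90 = x$p90, n_pixels = x$n_pixels)
}

#' Export a histogram of a pixel sample
#'
#' Uniform binning over `range`; values falling outside the range are counted
#' in the first or last bin, so counts always sum to the sample size.
#' Defaults cover the working range of each map kind: `[0, 1200]` for ADC
#' (1e-6 mm^2/s) and `[0, 100]` for PDFF (%), with 64 bins.
#'
#' @param sample a [pixel_sample()].
#' @param n_bins number of bins (>= 1).
#' @param range numeric `(low, high)`; defaults by map kind.
#' @return `data.frame` with `bin_low`, `bin_high`, `count`.
#' @export
export_histogram <- function(sample, n_bins = 64,
                             range = if (sample$kind == "ADC") c(0, 1200)
                                     else c(0, 100)) {
  stopifnot(inherits(sample, "pixel_sample"))
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  if (diff(range) <= 0) stop("histogram range must have positive width")
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(sample$values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)            # out-of-range -> end bins
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_low = edges[-(n_bins + 1L)], bin_high = edges[-1L],
             count = counts)
}

#' Plot a pixel-sample histogram
#' @param x a [pixel_sample()].
#' @param n_bins,range passed to [export_histogram()].
#' @param ... further arguments for [graphics::barplot()].
#' @return The histogram table, invisibly.
#' @export
plot.pixel_sample <- function(x, n_bins = 64,
                              range = if (x$kind == "ADC") c(0, 1200)
                                      else c(0, 100), ...) {
  h <- export_histogram(x, n_bins = n_bins, range = range)
  mids <- (h$bin_low + h$bin_high) / 2
  graphics::barplot(h$count, names.arg = signif(mids, 3), space = 0,
                    xlab = if (x$kind == "ADC") "ADC (1e-6 mm²/s)"
                           else "PDFF (%)",
                    ylab = "pixel count", ...)
  invisible(h)
}
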