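# Base-graphics companions to the three sensitivity layers.

#' Tornado diagram
#'
#' Horizontal bars from the ICER at the low to the ICER at the high end of
#' each parameter's deterministic range, widest spread on top.
#'
#' @param x A `pa_tornado` data frame from [tornado()].
#' @param top Number of parameters to display.
#' @param base_icer Optional vertical reference line (the point-estimate
#'   ICER).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_tornado <- function(x, top = 15, base_icer = NULL, ...) {
  stopifnot(inherits(x, "pa_tornado"))
  d <- utils::head(x, top)
  d <- d[rev(seq_len(nrow(d))), ]
  lo <- pmin(d$icer_at_low, d$icer_at_high)
  hi <- pmax(d$icer_at_low, d$icer_at_high)
  op <- graphics::par(mar = c(5, 12, 2, 2))
  on.exit(graphics::par(op))
  graphics::plot(range(c(lo, hi, base_icer)), c(0.5, nrow(d) + 0.5),
                 type = "n", yaxt = "n", xlab = "ICER (JPY per QALY)",
                 ylab = "", ...)
  graphics::segments(lo, seq_len(nrow(d)), hi, seq_len(nrow(d)),
                     lwd = 8, col = "steelblue", lend = 1)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$param, las = 1,
                 cex.axis = 0.7)
  if (!is.null(base_icer)) graphics::abline(v = base_icer, lty = 2)
  invisible(x)
}

#' ICER versus model horizon
#'
#' @param x A `pa_sweep` object from [cycle_sweep()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_sweep <- function(x, ...) {
  stopifnot(inherits(x, "pa_sweep"))
  g <- x$grid
  graphics::plot(g$horizon, g$icer, type = "l", lwd = 2,
                 xlab = "life expectancy (years)",
                 ylab = "ICER (JPY per QALY)", ...)
  graphics::abline(h = x$wtp, lty = 2, col = "red")
  if (!is.na(x$threshold)) graphics::abline(v = x$threshold, lty = 3)
  invisible(x)
}

#' Cost-effectiveness plane of PSA draws
#'
#' Scatter of incremental QALYs against incremental costs with the
#' willingness-to-pay line.
#'
#' @param x A `pa_psa` object from [psa()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_ce_plane <- function(x, ...) {
  stopifnot(inherits(x, "pa_psa"))
  d <- x$draws
  graphics::plot(d$incr_qaly, d$incr_cost, pch = ".", col = "grey40",
                 xlab = "incremental QALYs", ylab = "incremental cost (JPY)",
                 ...)
  graphics::abline(a = 0, b = x$wtp, col = "red", lwd = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}
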