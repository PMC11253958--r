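# Base-graphics diagnostic plots for method comparison.

#' Bland-Altman plot
#'
#' @param pairs A [paired_gfr()].
#' @param scale `"percent"` (default) or `"absolute"`.
#' @param main Plot title.
#' @return Invisibly, the [bland_altman()] summary plotted.
#' @export
plot_bland_altman <- function(pairs, scale = c("percent", "absolute"),
                              main = "Bland-Altman") {
  scale <- match.arg(scale)
  ba <- bland_altman(pairs, scale)
  ylab <- if (scale == "percent") "difference (% of reference)" else {
    "difference (mL/min/1.73 m^2)"
  }
  graphics::plot(ba$means, ba$differences, pch = 19, cex = 0.7,
                 xlab = "mean of methods (mL/min/1.73 m^2)", ylab = ylab,
                 main = main)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2)
  invisible(ba)
}

#' Mountain (folded percentile) plot
#'
#' @param pairs A [paired_gfr()].
#' @param scale `"absolute"` (default) or `"percent"`.
#' @param orientation Difference orientation; see [mountain_curve()].
#' @param main Plot title.
#' @return Invisibly, the [mountain_curve()] plotted.
#' @export
plot_mountain <- function(pairs, scale = c("absolute", "percent"),
                          orientation = "ref_minus_test",
                          main = "Mountain plot") {
  scale <- match.arg(scale)
  mc <- mountain_curve(pairs, scale, orientation)
  xlab <- if (scale == "percent") "reference - test (%)" else {
    "reference - test (mL/min/1.73 m^2)"
  }
  graphics::plot(mc$difference, mc$folded, type = "l",
                 xlab = xlab, ylab = "folded percentile", main = main)
  graphics::points(mc$difference, mc$folded, pch = 19, cex = 0.5)
  graphics::abline(v = 0, lty = 2)
  invisible(mc)
}
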