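#' Diagnostic plots
#'
#' `plot_hanes_woolf()` draws the `s0/v` vs `s0` linearization with the
#' fitted line; at large conversion the chord-rate points show the
#' characteristic upward curvature. `plot_integrated()` draws `p/t`
#' against `(1/t) * log(s0/(s0 - p))`, on which model-conforming data are
#' exactly linear with intercept `V` and slope `-Km`.
#'
#' @param rates An `mm_rates` data.frame (see [chord_rate()]).
#' @param fit Optional `mm_fit` whose line is overlaid.
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted coordinates.
#' @export
plot_hanes_woolf <- function(rates, fit = NULL, ...) {
  x <- rates$s0; y <- rates$s0 / rates$v_hat
  plot(x, y, xlab = "[S]0", ylab = "[S]0 / v",
       main = "Hanes-Woolf plot", ...)
  if (!is.null(fit)) graphics::abline(fit$Km / fit$V, 1 / fit$V, lty = 2)
  invisible(data.frame(x = x, y = y))
}

#' @rdname plot_hanes_woolf
#' @param m An `mm_measurements` table.
#' @export
plot_integrated <- function(m, fit = NULL, ...) {
  d <- m[m$p > 0, , drop = FALSE]
  x <- (1 / d$t) * log(d$s0 / (d$s0 - d$p))
  y <- d$p / d$t
  plot(x, y, xlab = "(1/t) ln([S]0 / ([S]0 - [P]))", ylab = "[P] / t",
       main = "Integrated-equation plot", ...)
  if (!is.null(fit)) graphics::abline(fit$V, -fit$Km, lty = 2)
  invisible(data.frame(x = x, y = y))
}
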