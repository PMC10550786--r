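#' @export
plot.ps_trajectory <- function(x, ...) {
  rec <- x$records
  oldpar <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(oldpar))
  graphics::plot(rec$t, rec$p, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "time step", ylab = "strong frequency p / gamma",
                 main = "Evolution of group composition", ...)
  graphics::lines(rec$t, rec$gamma, lty = 2, col = "red")
  graphics::legend("right", legend = c("p", expression(gamma)),
                   lty = c(1, 2), col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
plot.ps_sweep <- function(x, ...) {
  graphics::plot(x$value, x$x_star, pch = 16, col = "grey50", ylim = c(0, 1),
                 xlab = unique(x$param), ylab = "producer frequency / gamma",
                 main = sprintf("Sweep over %s (%s)", unique(x$param),
                                unique(x$mode)), ...)
  graphics::points(x$value, x$y_star, pch = 16, col = "black")
  graphics::points(x$value, x$gamma, pch = 1, col = "red")
  graphics::legend("topright", legend = c("x* (strong)", "y* (weak)",
                                          expression(gamma)),
                   pch = c(16, 16, 1), col = c("grey50", "black", "red"),
                   bty = "n")
  invisible(x)
}
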