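#' Plot fitted class mean trajectories
#'
#' @param x an `lcga_fit`.
#' @param t_max right end of the time axis (weeks).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lcga_fit <- function(x, t_max = 350, ...) {
  tt <- seq(0, t_max, length.out = 200)
  cc <- class_curves(x, tt)
  graphics::matplot(tt, cc, type = "l", lty = 1, lwd = 2,
                    xlab = "Weeks from diagnosis", ylab = "HbA1c (%)",
                    main = sprintf("Class mean trajectories (%s, k = %d)",
                                   x$basis$shape, x$params$k), ...)
  graphics::legend("topright",
                   legend = sprintf("Class %d (%.1f%%)", seq_len(x$params$k),
                                    100 * x$class_proportions),
                   col = seq_len(x$params$k), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Plot a Kaplan-Meier curve (or several)
#'
#' @param x a [km_curve()] or a list of them.
#' @param xlim,... passed to plotting functions.
#' @export
plot.km_curve <- function(x, xlim = NULL, ...) {
  plot_km_list(list(x), xlim = xlim, ...)
}

#' @rdname plot.km_curve
#' @param curves named list of `km_curve`s.
#' @export
plot_km_list <- function(curves, xlim = NULL, ...) {
  curves <- Filter(Negate(is.null), curves)
  if (is.null(xlim)) xlim <- c(0, max(vapply(curves, function(cu) {
    if (nrow(cu)) max(cu$time) else 1
  }, 0)))
  ymin <- min(vapply(curves, function(cu) if (nrow(cu)) min(cu$survival) else 1, 0))
  graphics::plot(NA, xlim = xlim, ylim = c(min(ymin, 0.95), 1),
                 xlab = "Weeks from diagnosis", ylab = "HHF-free survival", ...)
  for (i in seq_along(curves)) {
    cu <- curves[[i]]
    if (!nrow(cu)) next
    graphics::lines(stats::stepfun(cu$time, c(1, cu$survival)), col = i,
                    do.points = FALSE)
  }
  if (!is.null(names(curves))) {
    graphics::legend("bottomleft", legend = names(curves),
                     col = seq_along(curves), lty = 1, bty = "n")
  }
  invisible(curves)
}
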