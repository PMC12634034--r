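#' Quiver plot of a projected velocity field
#'
#' Draws each observation's arrow at its embedding position. Arrow lengths
#' are rescaled so the median arrow spans about 3% of the coordinate range
#' (display only; magnitudes are available in `field$arrows`).
#'
#' @param object a `velocity_field` from [project_velocity()]
#' @param color optional vector (e.g. cell-type labels or pseudotime) to
#'   color points by
#' @param arrow_scale multiplier on the display length of arrows
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.velocity_field <- function(object, color = NULL, arrow_scale = 1, ...) {
  E <- object$embedding
  A <- object$arrows
  span <- max(apply(E, 2, function(v) diff(range(v))))
  med <- median(sqrt(rowSums(A^2))[rowSums(A^2) > 0])
  fac <- if (is.finite(med) && med > 0) arrow_scale * 0.03 * span / med else 1
  df <- tibble(x = E[, 1], y = E[, 2],
               xend = E[, 1] + fac * A[, 1], yend = E[, 2] + fac * A[, 2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (!is.null(color)) {
    p + ggplot2::geom_point(ggplot2::aes(color = color), size = 0.8)
  } else {
    p + ggplot2::geom_point(size = 0.8, color = "grey60")
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.velocity_field
#' @param field a `velocity_field`
#' @export
plot_velocity_arrows <- function(field, color = NULL, arrow_scale = 1) {
  autoplot.velocity_field(field, color = color, arrow_scale = arrow_scale)
}

#' Plot a spatiotemporal profile
#'
#' Per-bin distance variance (and, when present, the percentile band)
#' against bin median pseudotime, with the fitted cubic overlaid.
#'
#' @param object a `spatiotemporal_profile`
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.spatiotemporal_profile <- function(object, ...) {
  ok <- is.finite(object$variances)
  df <- tibble(t = object$bin_median_times[ok], variance = object$variances[ok])
  cc <- object$cubic_coeffs_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$variance)) +
    ggplot2::geom_point()
  if (all(is.finite(cc))) {
    ts <- seq(min(df$t), max(df$t), length.out = 100)
    fit <- tibble(t = ts, variance = cc[1] * ts^3 + cc[2] * ts^2 + cc[3] * ts + cc[4])
    p <- p + ggplot2::geom_line(data = fit, color = "steelblue")
  }
  if (!is.null(object$p_lo)) {
    band <- tibble(t = object$bin_median_times[ok],
                   lo = object$p_lo[ok], hi = object$p_hi[ok])
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$t, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.15)
  }
  p + ggplot2::labs(x = "pseudotime (bin median)",
                    y = "distance variance") +
    ggplot2::theme_minimal()
}

#' Plot per-type omega estimates
#'
#' @param object an `omega_estimates` tibble from [estimate_omega()]
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.omega_estimates <- function(object, ...) {
  df <- object[!is.na(object$omega), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$type, .data$omega),
                                   y = .data$omega)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(omega ~ "(time weight)")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
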