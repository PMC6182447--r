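#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a normality report
#'
#' Two panels: the empirical CDF of the standardized statistics against
#' the standard normal CDF, and the normal QQ-plot with the identity
#' reference line.
#'
#' @param object A `normality_report`.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @method autoplot normality_report
#' @export
autoplot.normality_report <- function(object, ...) {
  ec <- object$ecdf
  xs <- seq(min(ec$x, -3), max(ec$x, 3), length.out = 200)
  ref <- tibble::tibble(x = xs, F_hat = stats::pnorm(xs))
  p1 <- ggplot2::ggplot(ec, ggplot2::aes(x = .data$x, y = .data$F_hat)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_line(data = ref, linetype = "dashed") +
    ggplot2::labs(
      x = object$statistic, y = "CDF",
      title = sprintf("ECDF vs N(0,1), KS = %.3f", object$ks_stat)
    )
  p2 <- ggplot2::ggplot(object$qq,
                        ggplot2::aes(x = .data$theoretical,
                                     y = .data$empirical)) +
    ggplot2::geom_point(size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = "N(0,1) quantiles", y = "Empirical quantiles",
                  title = "QQ-plot")
  p1 + p2
}

#' Plot a nonparametric fit
#'
#' The estimated curve \eqn{\hat f_n(t)}, with boundary-flagged grid
#' points (where the kernel translate sum is truncated) drawn dashed.
#'
#' @param object A `plm_smooth`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plm_smooth
#' @export
autoplot.plm_smooth <- function(object, ...) {
  est <- object$estimate
  ggplot2::ggplot(est, ggplot2::aes(x = .data$t, y = .data$f_hat)) +
    ggplot2::geom_line(data = est[!est$boundary, ], colour = "steelblue") +
    ggplot2::geom_line(data = est[est$boundary & est$t <= min(est$t[!est$boundary]), ],
                       colour = "steelblue", linetype = "dotted") +
    ggplot2::geom_line(data = est[est$boundary & est$t >= max(est$t[!est$boundary]), ],
                       colour = "steelblue", linetype = "dotted") +
    ggplot2::labs(x = "t", y = expression(hat(f)(t)))
}

#' Plot the residual series of a DOLS fit
#'
#' Differenced residuals against index; under the model these behave like
#' the differenced error process (moving-average of order `m`).
#'
#' @param object A `dols_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dols_fit
#' @export
autoplot.dols_fit <- function(object, ...) {
  d <- tibble::tibble(index = seq_along(object$residuals),
                      residual = object$residuals)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$residual)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "i", y = "differenced residual")
}
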