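# ggplot2 front-ends for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.smoothed_prc <- function(object, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$phi, y = .data$z))
  if (all(c("ci_lo", "ci_hi") %in% names(object))) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25)
  }
  p +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = expression(phi), y = expression(Z(phi) ~ "(1/pC)"),
         title = sprintf("Smoothed PRC (h = %.3g, n = %d)",
                         attr(object, "bandwidth"), attr(object, "n_samples")),
         subtitle = if (!is.null(attr(object, "rate_hz"))) {
           sprintf("firing rate %.1f Hz", attr(object, "rate_hz"))
         } else NULL) +
    theme_minimal()
}

#' @export
autoplot.raw_prc <- function(object, alpha = 0.3, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$phi, y = .data$z, colour = factor(.data$order))) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point(alpha = alpha, size = 0.7) +
    labs(x = expression(phi), y = expression(Z(phi) ~ "(1/pC)"),
         colour = "order",
         title = sprintf("Raw PRC samples (%d trials, %.1f Hz)",
                         attr(object, "n_trials"), attr(object, "rate_hz"))) +
    theme_minimal()
}

#' @export
autoplot.wsta_prc <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$phi, y = .data$z)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = expression(phi), y = expression(Z(phi) ~ "(1/pC)"),
         title = sprintf("WSTA PRC (%d ISIs, %.1f Hz)",
                         attr(object, "n_isi_used"), attr(object, "rate_hz"))) +
    theme_minimal()
}

#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble(f = seq(min(object$data$f), max(object$data$f),
                         length.out = 200))
  grid$r <- predict_sigmoid(object, grid$f)
  ggplot(object$data, aes(x = .data$f, y = .data$r)) +
    geom_point() +
    geom_line(data = grid) +
    labs(x = "firing rate (Hz)", y = "peak-to-baseline ratio r",
         title = sprintf("r(F) sigmoid fit: a = %.1f Hz, b = %.1f Hz",
                         object$a, object$b)) +
    theme_minimal()
}

#' @export
autoplot.clamp_session <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$log[, c("t_s", "f_hat_hz", "i_holding_pA")],
    cols = c("f_hat_hz", "i_holding_pA"),
    names_to = "signal", values_to = "value")
  ggplot(d, aes(x = .data$t_s, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    geom_hline(data = tibble(signal = "f_hat_hz",
                             value = object$config$f_target),
               aes(yintercept = .data$value),
               linetype = "dashed", colour = "red") +
    labs(x = "time (s)", y = NULL,
         title = sprintf("Frequency-clamp session (target %.0f Hz)",
                         object$config$f_target)) +
    theme_minimal()
}

#' Quick-look plot of a rate sweep
#'
#' @param object A `rate_sweep`.
#' @param ... Unused.
#' @export
autoplot.rate_sweep <- function(object, ...) {
  p <- ggplot(object$summary, aes(x = .data$rate_hz, y = .data$r)) +
    geom_point()
  if (!is.null(object$fit)) {
    grid <- tibble(rate_hz = seq(min(object$summary$rate_hz),
                                 max(object$summary$rate_hz),
                                 length.out = 200))
    grid$r <- predict_sigmoid(object$fit, grid$rate_hz)
    p <- p + geom_line(data = grid)
  }
  p + labs(x = "firing rate (Hz)", y = "peak-to-baseline ratio r") +
    theme_minimal()
}
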