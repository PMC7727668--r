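#' Plot a decay series
#'
#' Points for the simulated (or measured) intensities, with the fitted
#' mono-exponential overlaid when a [fit_decay()] result is supplied.
#'
#' @param object a `decay_series`.
#' @param fit optional `decay_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decay_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "sustain delay (s)", y = "integrated intensity") +
    ggplot2::theme_minimal()
  ns <- attr(object, "noise_sigma") %||% 0
  if (ns > 0) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$intensity - ns, ymax = .data$intensity + ns),
      width = 0)
  }
  if (!is.null(fit)) {
    grid <- tibble::tibble(time = seq(min(object$time), max(object$time),
                                      length.out = 100))
    grid$intensity <- fit$i0 * exp(-grid$time / fit$t_lls)
    p <- p + ggplot2::geom_line(data = grid, linetype = 2) +
      ggplot2::labs(subtitle = sprintf("T_LLS = %.3g +/- %.2g s",
                                       fit$t_lls, fit$t_err))
  }
  p
}

#' Plot a field sweep
#'
#' @param object a `spinlls_sweep` tibble from [field_sweep()].
#' @param ... unused.
#' @return a ggplot of T_LLS against the static field.
#' @export
autoplot.spinlls_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$b0, y = .data$t_lls)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$composition_changed), size = 2) +
    ggplot2::labs(x = "static field (T)", y = "T_LLS (s)",
                  shape = "LLS composition\nchanged") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
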