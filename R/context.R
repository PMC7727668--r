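#' Simulation context
#'
#' Collects the physical and experimental settings shared by all engine
#' calls: static field, rotational correlation time, rotating-frame carrier,
#' continuous-wave RF amplitude, whether chemical-shift evolution is
#' retained, and the seed for stochastic steps.
#'
#' `shift_mode = "suppressed"` models ideal sustaining (the shift
#' differences are masked, only J couplings evolve), `"retained"` models
#' free or low-field evolution with offsets relative to `carrier`.
#'
#' @param b0 static field in tesla (> 0).
#' @param tau_c rotational correlation time in seconds (> 0). The default
#'   50 ps is the value calibrated from glycine T1 used for all simulations.
#' @param carrier rotating-frame carrier in ppm; required when
#'   `shift_mode = "retained"`.
#' @param rf_amplitude CW nutation frequency in Hz (>= 0; 0 = free evolution).
#' @param shift_mode `"suppressed"` or `"retained"`.
#' @param seed integer seed for stochastic steps, or `NULL`.
#' @return an object of class `sim_context`.
#' @examples
#' sim_context(b0 = 9.36)
#' sim_context(b0 = 1, shift_mode = "retained", carrier = 3.9)
#' @export
sim_context <- function(b0 = 9.36, tau_c = 50e-12, carrier = NULL,
                        rf_amplitude = 0,
                        shift_mode = c("suppressed", "retained"),
                        seed = NULL) {
  shift_mode <- rlang::arg_match(shift_mode)
  if (!is.numeric(b0) || length(b0) != 1 || !is.finite(b0) || b0 <= 0) {
    abort_schema("b0 must be a positive number (tesla)")
  }
  if (!is.numeric(tau_c) || length(tau_c) != 1 || !is.finite(tau_c) || tau_c <= 0) {
    abort_schema("tau_c must be a positive number (seconds)")
  }
  if (!is.numeric(rf_amplitude) || length(rf_amplitude) != 1 ||
      !is.finite(rf_amplitude) || rf_amplitude < 0) {
    abort_schema("rf_amplitude must be >= 0 (Hz)")
  }
  if (!is.null(carrier) && (!is.numeric(carrier) || !is.finite(carrier))) {
    abort_schema("carrier must be a finite number (ppm) or NULL")
  }
  structure(
    list(b0 = b0, tau_c = tau_c, carrier = carrier,
         rf_amplitude = rf_amplitude, shift_mode = shift_mode,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_context"
  )
}

#' @export
print.sim_context <- function(x, ...) {
  cat(sprintf(
    "<sim_context> B0 = %g T (1H %.2f MHz), tau_c = %g ps, shifts %s%s%s\n",
    x$b0, larmor_frequency(x$b0) / 1e6, x$tau_c * 1e12, x$shift_mode,
    if (!is.null(x$carrier)) sprintf(", carrier %g ppm", x$carrier) else "",
    if (x$rf_amplitude > 0) sprintf(", CW %g Hz", x$rf_amplitude) else ""))
  invisible(x)
}
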