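#' Physical constants and conventions
#'
#' CODATA-2018 values used throughout the package, plus the convention
#' factors that fix the dipolar relaxation normalization. All rates are
#' in rad/s unless stated otherwise.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{gamma_1H}{proton gyromagnetic ratio, rad s^-1 T^-1}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{mu0_over_4pi}{magnetic constant over 4 pi, T m A^-1}
#'   \item{larmor_MHz_per_T}{proton Larmor frequency per tesla, MHz/T}
#'   \item{t1_extreme_narrowing_factor}{the factor f in R1 = f * b^2 * tau_c
#'     for a like-spin pair in extreme narrowing (3/2); this is the
#'     closed-form limit of the Redfield engine and the convention used to
#'     calibrate tau_c from a reference T1}
#' }
#' @export
spinlls_constants <- list(
  gamma_1H       = 2.6752218744e8,
  hbar           = 1.054571817e-34,
  mu0_over_4pi   = 1e-7,
  larmor_MHz_per_T = 42.577478518,
  t1_extreme_narrowing_factor = 3 / 2
)

#' Proton Larmor frequency
#'
#' @param b0 static field in tesla.
#' @return Larmor frequency in Hz.
#' @export
larmor_frequency <- function(b0) {
  spinlls_constants$larmor_MHz_per_T * 1e6 * b0
}

# default cap on spin count (Liouville dimension 4^cap)
.spinlls_cap <- function() {
  getOption("spinlls.cap", 6L)
}
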