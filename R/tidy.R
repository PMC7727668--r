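#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an LLS eigenmode
#'
#' @param x an `lls_mode` from [find_lls()].
#' @param ... unused.
#' @return a tibble of leading product-operator coefficients.
#' @export
tidy.lls_mode <- function(x, ...) x$overlaps

#' @rdname tidy.lls_mode
#' @export
glance.lls_mode <- function(x, ...) {
  tibble::tibble(rate = x$rate, frequency = x$frequency,
                 lifetime = x$lifetime, singlet_overlap = x$singlet_overlap)
}

#' Tidy a lifetime report
#'
#' @param x an `lls_report` from [lls_report()].
#' @param ... unused.
#' @return one row per site with its T1 plus the shared T_LLS.
#' @export
tidy.lls_report <- function(x, ...) {
  tibble::tibble(molecule = x$molecule, b0 = x$b0, site = names(x$t1),
                 t1_s = unname(x$t1), t_lls_s = x$t_lls)
}

#' @rdname tidy.lls_report
#' @export
glance.lls_report <- function(x, ...) {
  tibble::tibble(molecule = x$molecule, b0 = x$b0, tau_c = x$tau_c,
                 shift_mode = x$shift_mode, t_lls_s = x$t_lls)
}

#' Tidy a Q_ISR optimization result
#'
#' @param x a `qisr_result` from [qisr_optimize()].
#' @param ... unused.
#' @return one row per lambda coefficient.
#' @export
tidy.qisr_result <- function(x, ...) {
  tibble::tibble(
    term = c("lambda_IS", "lambda_IR", "lambda_SR"),
    estimate = c(x$lambda_is, x$lambda_ir, x$lambda_sr),
    j_hz = c(x$j_is, x$j_ir, x$j_sr))
}

#' @rdname tidy.qisr_result
#' @export
glance.qisr_result <- function(x, ...) {
  tibble::tibble(molecule = x$molecule, field = x$field,
                 lambda_is = x$lambda_is, lambda_ir = x$lambda_ir,
                 lambda_sr = x$lambda_sr, t_qisr_s = x$lifetime)
}

#' Tidy a decay fit
#'
#' @param x a `decay_fit` from [fit_decay()].
#' @param ... unused.
#' @return parameter estimates with the Monte-Carlo standard error.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("i0", "t_lls"),
                 estimate = c(x$i0, x$t_lls),
                 std.error = c(NA_real_, x$t_err))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(i0 = x$i0, t_lls = x$t_lls, t_err = x$t_err,
                 n_mc = x$n_mc, seed = x$seed)
}
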