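# header comment lines echoing constants and conventions into every report,
# so the numeric provenance of the tables is auditable
.report_header <- function(extra = character()) {
  cst <- spinlls_constants
  c("# spinlls report",
    sprintf("# gamma_1H_rad_s_T = %.10g", cst$gamma_1H),
    sprintf("# mu0_over_4pi = %.3g", cst$mu0_over_4pi),
    sprintf("# hbar_J_s = %.10g", cst$hbar),
    sprintf("# larmor_MHz_per_T = %.9f", cst$larmor_MHz_per_T),
    sprintf("# t1_extreme_narrowing_factor = %g", cst$t1_extreme_narrowing_factor),
    "# lls_freq_tol_rad_s = 1e-6",
    extra)
}

#' Write a tibble as a TSV report
#'
#' Tab-separated, `.` decimal, header row, preceded by `#` comment lines
#' echoing the physical constants and convention factors. Byte-identical
#' across reruns of the same input.
#'
#' @param df a data frame.
#' @param path output path, or `""` for standard output.
#' @param extra_header additional `# key = value` lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, extra_header = character()) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(.report_header(extra_header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble lifetime results into table-shaped reports
#'
#' Collects [lls_report()] and [qisr_optimize()] results into the two
#' standard layouts: a per-molecule T1/T_LLS table (with a separate column
#' for low-field lifetimes when reports at more than one field are given)
#' and a Q_ISR table carrying the lambda coefficients and J couplings.
#' Row order follows input order.
#'
#' @param results a list of `lls_report` and/or `qisr_result` objects.
#' @return a list with tibbles `table1` and `table2` (either may have zero
#'   rows).
#' @export
report_tables <- function(results) {
  if (!is.list(results)) abort_schema("results must be a list")
  bad <- !vapply(results, function(x)
    inherits(x, "lls_report") || inherits(x, "qisr_result"), logical(1))
  if (any(bad)) {
    abort_schema("results must contain only lls_report / qisr_result objects")
  }
  llr <- purrr::keep(results, inherits, "lls_report")
  qis <- purrr::keep(results, inherits, "qisr_result")

  t1_rows <- list()
  for (x in llr) {
    hb <- grep("^Hb", names(x$t1), value = TRUE)
    site <- if (length(hb)) hb[1] else names(x$t1)[1]
    t1_rows[[length(t1_rows) + 1L]] <- tibble::tibble(
      molecule = x$molecule, B0_T = x$b0, tau_c_s = x$tau_c,
      site = site, T1_s = unname(x$t1[site]), T_LLS_s = x$t_lls,
      shift_mode = x$shift_mode)
  }
  raw1 <- if (length(t1_rows)) dplyr::bind_rows(t1_rows) else
    tibble::tibble(molecule = character(), B0_T = double(), tau_c_s = double(),
                   site = character(), T1_s = double(), T_LLS_s = double(),
                   shift_mode = character())
  # one row per molecule: the highest-field report carries T1/T_LLS, the
  # lowest-field one (if distinct) fills the low-field column
  table1 <- dplyr::bind_rows(lapply(unique(raw1$molecule), function(mol) {
    rows <- raw1[raw1$molecule == mol, ]
    hi <- rows[which.max(rows$B0_T), ]
    lo_t <- if (nrow(rows) > 1) rows$T_LLS_s[which.min(rows$B0_T)] else NA_real_
    tibble::tibble(molecule = mol, B0_T = hi$B0_T, tau_c_s = hi$tau_c_s,
                   site = hi$site, T1_s = hi$T1_s, T_LLS_s = hi$T_LLS_s,
                   T_LLS_lowfield_s = lo_t)
  }))
  if (!nrow(raw1)) {
    table1 <- tibble::tibble(molecule = character(), B0_T = double(),
                             tau_c_s = double(), site = character(),
                             T1_s = double(), T_LLS_s = double(),
                             T_LLS_lowfield_s = double())
  }

  table2 <- if (length(qis)) {
    dplyr::bind_rows(lapply(qis, function(q) tibble::tibble(
      molecule = q$molecule, B0_T = q$field, T_QISR_s = q$lifetime,
      lambda_IS = q$lambda_is, lambda_IR = q$lambda_ir,
      lambda_SR = q$lambda_sr,
      J_IS_Hz = q$j_is, J_IR_Hz = q$j_ir, J_SR_Hz = q$j_sr)))
  } else {
    tibble::tibble(molecule = character(), B0_T = double(),
                   T_QISR_s = double(), lambda_IS = double(),
                   lambda_IR = double(), lambda_SR = double(),
                   J_IS_Hz = double(), J_IR_Hz = double(), J_SR_Hz = double())
  }
  list(table1 = table1, table2 = table2)
}
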