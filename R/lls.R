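#' Assemble the full Liouvillian
#'
#' Total generator `L = -i[H, .] + R`: the coherent commutation
#' superoperator of the rotating-frame Hamiltonian plus the dipolar
#' Redfield relaxation superoperator. `d rho / dt = L rho` on the
#' product-operator basis.
#'
#' @param sys a [spin_system()].
#' @param ctx a [sim_context()].
#' @param basis optional [product_basis()].
#' @param include_relaxation set `FALSE` for a coherent-only Liouvillian.
#' @param rf_amplitude,rf_phase optional RF override passed to
#'   [coherent_hamiltonian()].
#' @return a `superoperator` of kind `"total"` (or `"coherent"`).
#' @export
assemble_liouvillian <- function(sys, ctx, basis = NULL,
                                 include_relaxation = TRUE,
                                 rf_amplitude = NULL, rf_phase = 0) {
  basis <- basis %||% product_basis(n_spins(sys))
  h <- coherent_hamiltonian(sys, ctx, rf_amplitude = rf_amplitude,
                            rf_phase = rf_phase)
  lc <- commutation_superoperator(h, basis)
  if (!include_relaxation) return(lc)
  r <- redfield_superoperator(sys, ctx, basis)
  .new_superoperator(lc$matrix + r$matrix, "total", basis)
}

# eigendecomposition of the Liouvillian with the identity deflated exactly
# (the identity basis element is a two-sided null vector by construction)
.liouvillian_eigen <- function(l) {
  m <- l$matrix
  eg <- eigen(m[-1, -1, drop = FALSE])
  vecs <- rbind(0i, eg$vectors)         # re-insert zero identity component
  list(values = eg$values, vectors = vecs)
}

# fix the arbitrary global phase of an eigenvector: largest-magnitude
# component made real and positive
.phase_fix <- function(v) {
  k <- which.max(Mod(v))
  ph <- v[k] / Mod(v[k])
  v / ph
}

#' Tabulate the eigenmodes of a Liouvillian
#'
#' @param l a `superoperator` (normally kind `"total"`).
#' @param top how many product-operator components to name per mode.
#' @return a tibble with one row per non-identity eigenmode: `rate` (s^-1,
#'   `-Re` eigenvalue), `frequency` (rad/s, `Im` eigenvalue), `lifetime`,
#'   `top_ops` (largest components, text), sorted by rate.
#' @export
liouvillian_modes <- function(l, top = 3) {
  eg <- .liouvillian_eigen(l)
  labs <- l$labels
  rows <- purrr::map(seq_along(eg$values), function(k) {
    v <- .phase_fix(eg$vectors[, k])
    v <- v / sqrt(sum(Mod(v)^2))
    ord <- order(Mod(v), decreasing = TRUE)[seq_len(top)]
    rate_k <- -Re(eg$values[k])
    tibble::tibble(
      rate = rate_k, frequency = Im(eg$values[k]),
      lifetime = 1 / rate_k,
      top_ops = paste(sprintf("%s (%.2f)", labs[ord], Re(v[ord])),
                      collapse = ", "))
  })
  dplyr::arrange(dplyr::bind_rows(rows), rate)
}

# squared-norm overlaps of a Liouville vector with every pair's normalized
# singlet-order operator; used for deterministic tie-breaking and reporting
.singlet_overlaps <- function(v, basis) {
  n <- basis$n
  out <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        q <- state_from_operator(.op_singlet_projector(n, i, j), basis)$amplitudes
        q[1] <- 0                      # remove identity part: singlet order
        q <- q / sqrt(sum(Mod(q)^2))
        out <- c(out, Mod(sum(Conj(q) * v)))
      }
    }
  }
  out
}

#' Identify the long-lived state of a Liouvillian
#'
#' The long-lived state is the eigenmode whose eigenvalue has the smallest
#' real-part magnitude among all modes except the identity, and no
#' imaginary component: the slowest-decaying zero-frequency mode. The
#' identity (rate 0, frequency 0) is excluded exactly by deflation. Ties
#' are broken deterministically: largest singlet-order overlap first, then
#' basis order.
#'
#' @param l a `superoperator` of kind `"total"` (relaxation included).
#' @param freq_tol zero-frequency tolerance in rad/s. Default: `1e-6`, or,
#'   when the spectrum contains genuinely oscillating modes, up to
#'   `1e-3` times the smallest nonzero frequency magnitude.
#' @return an object of class `lls_mode` with fields `rate` (s^-1),
#'   `frequency` (rad/s), `lifetime` (s), `vector` (normalized
#'   `state_vector`), `overlaps` (tibble of leading product-operator
#'   coefficients), `singlet_overlap`.
#' @export
find_lls <- function(l, freq_tol = NULL) {
  if (!identical(l$kind, "total") && !identical(l$kind, "relaxation")) {
    rlang::abort(
      "no LLS found: Liouvillian contains no relaxation, all non-identity modes are persistent",
      class = "spinlls_no_lls_error")
  }
  eg <- .liouvillian_eigen(l)
  freqs <- Im(eg$values)
  if (is.null(freq_tol)) {
    nz <- abs(freqs)[abs(freqs) > 1e-6]
    freq_tol <- max(1e-6, if (length(nz)) 1e-3 * min(nz) else 0)
  }
  cand <- which(abs(freqs) <= freq_tol)
  if (!length(cand)) {
    rlang::abort("no LLS found: no zero-frequency non-identity eigenmode",
                 class = "spinlls_no_lls_error")
  }
  basis <- product_basis(l$n)
  rates <- -Re(eg$values[cand])
  best_rate <- min(rates)
  tied <- cand[rates <= best_rate + 1e-9 * max(abs(best_rate), 1e-12)]
  if (length(tied) > 1 && l$n > 1) {
    so <- vapply(tied, function(k) {
      v <- eg$vectors[, k]
      max(.singlet_overlaps(v / sqrt(sum(Mod(v)^2)), basis))
    }, numeric(1))
    pick <- tied[which.max(so)]
  } else {
    pick <- tied[1]
  }
  v <- .phase_fix(eg$vectors[, pick])
  v <- v / sqrt(sum(Mod(v)^2))
  rate <- -Re(eg$values[pick])
  ord <- order(Mod(v), decreasing = TRUE)
  ord <- ord[Mod(v)[ord] > 1e-3][seq_len(min(8, sum(Mod(v) > 1e-3)))]
  structure(list(
    rate = rate, frequency = Im(eg$values[pick]),
    # immune states come out with rate ~ 0 to roundoff; clamp so the
    # reported lifetime is a large positive number rather than +/-Inf
    lifetime = 1 / max(rate, .Machine$double.eps),
    vector = structure(list(amplitudes = v, n = l$n), class = "state_vector"),
    overlaps = tibble::tibble(operator = l$labels[ord],
                              coefficient = Re(v[ord])),
    singlet_overlap = if (l$n > 1) max(.singlet_overlaps(v, basis)) else 0
  ), class = "lls_mode")
}

#' @export
print.lls_mode <- function(x, ...) {
  cat(sprintf("<lls_mode> rate %.6g s^-1, lifetime %.6g s, |frequency| %.3g rad/s\n",
              x$rate, x$lifetime, abs(x$frequency)))
  cat("leading components:\n")
  print(x$overlaps)
  invisible(x)
}

#' Predict a site's longitudinal relaxation time
#'
#' Simulates a nonselective inversion recovery (all longitudinal terms
#' inverted) under the full Liouvillian, then collapses the generally
#' multi-exponential recovery of the requested site's longitudinal
#' amplitude to a single time constant with a three-parameter
#' mono-exponential fit over a grid spanning about five expected T1 --
#' the same way an experimental inversion-recovery series is reduced.
#'
#' @param sys a [spin_system()] with coordinates.
#' @param ctx a [sim_context()]; in retained mode a missing carrier
#'   defaults to the mean chemical shift.
#' @param site site label to monitor.
#' @param n_points grid size for the recovery curve.
#' @return fitted T1 in seconds, with the recovery curve attached as
#'   attribute `"recovery"`.
#' @export
predict_t1 <- function(sys, ctx, site, n_points = 40) {
  n <- n_spins(sys)
  if (!site %in% sys$labels) {
    abort_schema(sprintf("unknown site '%s'", site))
  }
  if (n < 2) {
    rlang::abort("no relaxation pathway: site has no dipolar partners",
                 class = "spinlls_numeric_error")
  }
  if (ctx$shift_mode == "retained" && is.null(ctx$carrier)) {
    ctx$carrier <- mean(sys$shifts)
  }
  basis <- product_basis(n)
  l <- assemble_liouvillian(sys, ctx, basis)
  k <- which(sys$labels == site)
  idx <- match(paste0("z", k), basis$labels)
  rate0 <- -Re(l$matrix[idx, idx])
  if (!is.finite(rate0) || rate0 <= 0) {
    rlang::abort("no relaxation pathway: vanishing longitudinal rate",
                 class = "spinlls_numeric_error")
  }
  t0 <- 1 / rate0
  times <- seq(0, 5 * t0, length.out = n_points)

  s0 <- state_from_operator(-.op_total(n, "z"), basis)$amplitudes
  eg <- eigen(l$matrix)
  c0 <- solve(eg$vectors, s0)
  a_row <- eg$vectors[idx, ] * c0
  y <- vapply(times, function(t) Re(sum(a_row * exp(eg$values * t))), numeric(1))

  df <- data.frame(t = times, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / T) + c, data = df,
                      start = list(a = y[1], T = t0, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      rlang::abort(sprintf(
        "inversion-recovery fit failed for site '%s': %s", site,
        conditionMessage(e)),
        class = "spinlls_numeric_error", recovery = df)
    })
  t1 <- unname(stats::coef(fit)[["T"]])
  attr(t1, "recovery") <- tibble::as_tibble(df)
  t1
}

#' Long-lived-state lifetimes across magnetic fields
#'
#' Re-assembles the Liouvillian at each field (offsets scale with the
#' field in retained mode, and the relaxation spectral densities follow
#' each field's Larmor frequency) and reports the long-lived state found
#' at each, flagging changes in the state's dominant operator composition
#' between consecutive fields.
#'
#' @param sys a [spin_system()] with coordinates.
#' @param ctx a [sim_context()] (its `b0` is overridden per row).
#' @param fields numeric vector of static fields in tesla.
#' @return a tibble with columns `b0`, `t_lls`, `rate`, `top_ops`,
#'   `composition_changed`, in input field order; class `spinlls_sweep`.
#' @export
field_sweep <- function(sys, ctx, fields) {
  if (!length(fields)) abort_schema("field list must be non-empty")
  if (any(!is.finite(fields)) || any(fields <= 0)) {
    abort_schema("all fields must be positive (tesla)")
  }
  basis <- product_basis(n_spins(sys))
  rows <- purrr::map(fields, function(b0) {
    cx <- ctx
    cx$b0 <- b0
    mode <- find_lls(assemble_liouvillian(sys, cx, basis))
    comp <- paste(utils::head(mode$overlaps$operator, 3), collapse = "+")
    tibble::tibble(b0 = b0, t_lls = mode$lifetime, rate = mode$rate,
                   top_ops = comp)
  })
  out <- dplyr::bind_rows(rows)
  out$composition_changed <- c(FALSE, utils::head(out$top_ops, -1) !=
                                 utils::tail(out$top_ops, -1))
  class(out) <- c("spinlls_sweep", class(out))
  out
}

#' Optimize the bilinear three-spin long-lived state
#'
#' For a three-spin system `(I, S, R)` -- `I, S` being the
#' strongest-coupled pair -- the bilinear ansatz
#' `Q = (1/3)(lambda_IS I.S + lambda_IR I.R + lambda_SR S.R)` is an exact
#' eigenstate only when Zeeman evolution is suppressed. This routine
#' computes the Liouvillian eigenmodes with a J-coupling-only coherent
#' Hamiltonian (relaxation evaluated at `ctx$b0`), selects the slowest
#' zero-frequency mode most similar to the ansatz (largest summed squared
#' projection on the three normalized two-spin scalar products), and
#' reports the projections together with the mode's lifetime. Signs are
#' fixed so that `lambda_IS > 0`.
#'
#' The reported `lambda` coefficients use the population-state convention:
#' the traceless eigenmode `m` is dressed with its unit-trace background,
#' `Q = (1/2) E_hat + (sqrt(3)/2) m`, so that a pure two-spin singlet
#' imbalance reports `|lambda_IS| = sqrt(3)/2 ~ 0.866` (the normalized
#' singlet-population projector's overlap with the normalized scalar
#' product), and `lambda_IS^2 + lambda_IR^2 + lambda_SR^2 <= 3/4`. The raw
#' traceless-mode projections are kept in `$projections`.
#'
#' @param sys a three-spin [spin_system()] with coordinates.
#' @param ctx a [sim_context()]; lifetimes are conventionally quoted at
#'   `b0 = 1` tesla.
#' @return an object of class `qisr_result` with fields `lambda_is`,
#'   `lambda_ir`, `lambda_sr`, `lifetime`, `rate`, `field`, `pair`
#'   (labels of I and S), `mode`.
#' @export
qisr_optimize <- function(sys, ctx = sim_context(b0 = 1)) {
  n <- n_spins(sys)
  if (n != 3) {
    abort_schema(sprintf("Q_ISR optimization requires exactly 3 spins, got %d", n))
  }
  basis <- product_basis(3)
  jm <- abs(sys$j_matrix)
  pick <- which(jm == max(jm), arr.ind = TRUE)[1, ]
  i_s <- sort(pick)
  r_site <- setdiff(1:3, i_s)
  cx <- ctx
  cx$shift_mode <- "suppressed"     # Zeeman evolution suppressed
  cx$rf_amplitude <- 0
  l <- assemble_liouvillian(sys, cx, basis)
  eg <- .liouvillian_eigen(l)

  proj_vec <- function(i, j) {
    v <- state_from_operator(.op_scalar_product(3, i, j), basis)$amplitudes
    v / sqrt(sum(Mod(v)^2))
  }
  v_is <- proj_vec(i_s[1], i_s[2])
  v_ir <- proj_vec(i_s[1], r_site)
  v_sr <- proj_vec(i_s[2], r_site)

  cand <- which(abs(Im(eg$values)) <= 1e-6)
  if (!length(cand)) {
    rlang::abort("no zero-frequency eigenmode found",
                 class = "spinlls_no_lls_error")
  }
  rates <- -Re(eg$values[cand])
  # group near-degenerate modes: inside a rate cluster the eigenvector
  # basis is arbitrary, so the ansatz-like direction is found by SVD of
  # the Eq-ansatz subspace against the cluster span
  ord_r <- order(rates)
  cluster_id <- integer(length(cand))
  cid <- 0L
  last_rate <- -Inf
  for (k in ord_r) {
    if (rates[k] - last_rate > 1e-9 + 1e-6 * abs(rates[k])) cid <- cid + 1L
    cluster_id[k] <- cid
    last_rate <- rates[k]
  }
  targets <- rbind(Conj(v_is), Conj(v_ir), Conj(v_sr))
  best <- NULL
  for (cl in seq_len(cid)) {
    idx <- cand[cluster_id == cl]
    cb <- qr.Q(qr(eg$vectors[, idx, drop = FALSE]))
    sv <- svd(targets %*% cb)
    vec <- as.vector(cb %*% sv$v[, 1])
    score <- sv$d[1]^2
    rate_cl <- -Re(sum(Conj(vec) * (l$matrix %*% vec)))
    if (is.null(best) || score > best$score + 1e-9 ||
        (abs(score - best$score) <= 1e-9 && rate_cl < best$rate)) {
      best <- list(vec = vec, score = score, rate = rate_cl)
    }
  }
  v <- best$vec / sqrt(sum(Mod(best$vec)^2))
  proj <- c(is = Re(sum(Conj(v_is) * v)), ir = Re(sum(Conj(v_ir) * v)),
            sr = Re(sum(Conj(v_sr) * v)))
  if (proj[["is"]] < 0) {
    v <- -v
    proj <- -proj
  }
  lam <- proj * sqrt(3) / 2           # population-state convention
  rate <- best$rate
  structure(list(
    lambda_is = lam[["is"]], lambda_ir = lam[["ir"]], lambda_sr = lam[["sr"]],
    projections = proj,
    lifetime = 1 / max(rate, .Machine$double.eps), rate = rate,
    field = ctx$b0,
    pair = sys$labels[i_s], third = sys$labels[r_site],
    molecule = sys$name,
    j_is = sys$j_matrix[i_s[1], i_s[2]],
    j_ir = sys$j_matrix[i_s[1], r_site],
    j_sr = sys$j_matrix[i_s[2], r_site],
    mode = structure(list(amplitudes = v, n = 3), class = "state_vector")
  ), class = "qisr_result")
}

#' @export
print.qisr_result <- function(x, ...) {
  cat(sprintf(
    "<qisr_result> I,S = (%s, %s); lambda_IS %.3f, lambda_IR %.3f, lambda_SR %.3f; lifetime %.4g s at %g T\n",
    x$pair[1], x$pair[2], x$lambda_is, x$lambda_ir, x$lambda_sr,
    x$lifetime, x$field))
  invisible(x)
}

#' Full lifetime report for a spin system
#'
#' Bundles [find_lls()] and per-site [predict_t1()] into one result.
#'
#' @param sys a [spin_system()] with coordinates.
#' @param ctx a [sim_context()].
#' @param sites site labels for T1 prediction; default all sites.
#' @return an object of class `lls_report` with fields `molecule`,
#'   `t_lls`, `t1` (named vector), `mode`, `b0`, `tau_c`, `shift_mode`.
#' @export
lls_report <- function(sys, ctx, sites = sys$labels) {
  mode <- find_lls(assemble_liouvillian(sys, ctx))
  t1 <- vapply(sites, function(s) as.numeric(predict_t1(sys, ctx, s)),
               numeric(1))
  structure(list(molecule = sys$name, t_lls = mode$lifetime, t1 = t1,
                 mode = mode, b0 = ctx$b0, tau_c = ctx$tau_c,
                 shift_mode = ctx$shift_mode),
            class = "lls_report")
}

#' @export
print.lls_report <- function(x, ...) {
  cat(sprintf("<lls_report> %s at %g T (%s shifts): T_LLS = %.4g s\n",
              x$molecule, x$b0, x$shift_mode, x$t_lls))
  print(tibble::tibble(site = names(x$t1), t1_s = unname(x$t1)))
  invisible(x)
}
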