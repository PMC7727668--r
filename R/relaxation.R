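#' Dipolar coupling constant
#'
#' `b = -(mu0/4pi) gamma_H^2 hbar / r^3`, the through-space coupling
#' strength of two protons at distance `r`, negative by convention.
#'
#' @param r interproton distance in angstrom (> 0).
#' @return coupling in rad/s.
#' @examples
#' abs(dipolar_constant(1.77)) / (2 * pi)   # ~ 2.17e4 Hz
#' @export
dipolar_constant <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort_schema("distance r must be positive (angstrom)")
  }
  cst <- spinlls_constants
  -cst$mu0_over_4pi * cst$gamma_1H^2 * cst$hbar / (r * 1e-10)^3
}

#' Lorentzian spectral density
#'
#' `j(omega) = tau_c / (1 + omega^2 tau_c^2)` for isotropic rotational
#' diffusion. Rank-2 multiplicity factors live in the superoperator
#' assembly, not here.
#'
#' @param omega angular frequency, rad/s (any real).
#' @param tau_c rotational correlation time, s (> 0).
#' @return spectral density in seconds.
#' @export
spectral_density <- function(omega, tau_c) {
  if (!is.numeric(tau_c) || any(tau_c <= 0)) abort_schema("tau_c must be positive")
  tau_c / (1 + (omega * tau_c)^2)
}

#' Intramolecular dipolar network of a spin system
#'
#' @param sys a [spin_system()] with coordinates.
#' @param tau_c correlation time in seconds.
#' @return a tibble with one row per proton pair: `site_i`, `site_j`,
#'   `r_angstrom`, `b_rad_s`, and the internuclear unit vector columns
#'   `ux`, `uy`, `uz`; `tau_c` is carried as an attribute.
#' @export
dipolar_network <- function(sys, tau_c = 50e-12) {
  if (is.null(sys$coords)) {
    abort_schema("coordinates required to build the dipolar network")
  }
  n <- n_spins(sys)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        v <- sys$coords[j, ] - sys$coords[i, ]
        r <- sqrt(sum(v^2))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          i = i, j = j, site_i = sys$labels[i], site_j = sys$labels[j],
          r_angstrom = r, b_rad_s = dipolar_constant(r),
          ux = v[1] / r, uy = v[2] / r, uz = v[3] / r)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(i = integer(), j = integer(), site_i = character(),
                   site_j = character(), r_angstrom = double(),
                   b_rad_s = double(), ux = double(), uy = double(),
                   uz = double())
  attr(out, "tau_c") <- tau_c
  out
}

# rank-2 spherical tensor operators of pair (i, j), lab spin frame:
#   T20   = (1/sqrt(6)) (3 Iz Sz - I.S)
#   T2+-1 = -/+ (1/2)(I+- Sz + Iz S+-)
#   T2+-2 = (1/2) I+- S+-
# returned in m order (-2, -1, 0, +1, +2)
.pair_tensors <- function(n, i, j) {
  iz <- spin_op(n, i, "z"); jz <- spin_op(n, j, "z")
  ip <- spin_op(n, i, "p"); jp <- spin_op(n, j, "p")
  im <- spin_op(n, i, "m"); jm <- spin_op(n, j, "m")
  t20 <- (3 * iz %*% jz - .op_scalar_product(n, i, j)) / sqrt(6)
  list(
    `-2` = 0.5 * im %*% jm,
    `-1` = 0.5 * (im %*% jz + iz %*% jm),
    `0`  = t20,
    `1`  = -0.5 * (ip %*% jz + iz %*% jp),
    `2`  = 0.5 * ip %*% jp
  )
}

# lab-frame Hamiltonian used for the Redfield eigenfrequencies: full Zeeman
# (including chemical shifts) plus the J network, in rad/s
.lab_hamiltonian <- function(sys, ctx) {
  n <- n_spins(sys)
  w0 <- 2 * pi * larmor_frequency(ctx$b0)
  h <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) {
    h <- h + w0 * (1 + sys$shifts[i] * 1e-6) * spin_op(n, i, "z")
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sys$j_matrix[i, j] != 0) {
        h <- h + 2 * pi * sys$j_matrix[i, j] * .op_scalar_product(n, i, j)
      }
    }
  }
  h
}

#' Dipolar Redfield relaxation superoperator
#'
#' Assembles the Bloch-Redfield-Wangsness relaxation superoperator for
#' intramolecular proton-proton dipolar couplings under isotropic rotational
#' diffusion, in the full spherical-tensor formalism:
#'
#' `R rho = - sum_(p,q,m) (6/5) b_p b_q P2(cos theta_pq)
#'          [T2m(p)^H, [K2m(q), rho]]`
#'
#' where the sum runs over ordered pairs of proton-proton interactions
#' (including cross-correlated terms between distinct pairs, weighted by the
#' second Legendre polynomial of the angle between the internuclear
#' vectors), `T2m` are the rank-2 pair tensors and `K2m` carries the
#' Lorentzian spectral density evaluated at every eigenfrequency difference
#' of the lab-frame coherent Hamiltonian (so the treatment is non-secular).
#' Dynamic frequency shifts (the imaginary part of the resolvent) are
#' dropped, which leaves `R` real on the product-operator basis. The
#' high-temperature form is used: `R` drives the density operator to zero,
#' which leaves all decay time constants unchanged.
#'
#' @param sys a [spin_system()] with coordinates for every site.
#' @param ctx a [sim_context()] providing `b0` and `tau_c`.
#' @param basis optional [product_basis()] for `n_spins(sys)`.
#' @return a `superoperator` of kind `"relaxation"` (real matrix, all
#'   eigenvalue real parts <= 0 to tolerance, identity annihilated).
#' @export
redfield_superoperator <- function(sys, ctx, basis = NULL) {
  n <- n_spins(sys)
  basis <- basis %||% product_basis(n)
  size <- basis$size
  if (n == 1) {
    return(.new_superoperator(matrix(0, size, size), "relaxation", basis))
  }
  net <- dipolar_network(sys, ctx$tau_c)
  npair <- nrow(net)

  h0 <- .lab_hamiltonian(sys, ctx)
  eg <- eigen(Re(h0), symmetric = TRUE)
  v <- eg$vectors
  lam <- eg$values
  jmat <- spectral_density(outer(lam, lam, "-"), ctx$tau_c)

  tens <- vector("list", npair)   # pair tensors, Hilbert space
  kten <- vector("list", npair)   # resolvent-weighted tensors
  cdag <- vector("list", npair)   # commutator superops of T2m^H
  ck   <- vector("list", npair)   # commutator superops of K2m
  for (p in seq_len(npair)) {
    tp <- .pair_tensors(n, net$i[p], net$j[p])
    tens[[p]] <- tp
    kten[[p]] <- lapply(tp, function(tm) {
      v %*% ((Conj(t(v)) %*% tm %*% v) * jmat) %*% Conj(t(v))
    })
    cdag[[p]] <- lapply(tp, function(tm) .comm_vec(Conj(t(tm))))
    ck[[p]]   <- lapply(kten[[p]], .comm_vec)
  }

  u <- as.matrix(net[, c("ux", "uy", "uz")])
  rvec <- matrix(0i, size, size)
  for (p in seq_len(npair)) {
    for (q in seq_len(npair)) {
      cosang <- sum(u[p, ] * u[q, ])
      p2 <- (3 * cosang^2 - 1) / 2
      coef <- (6 / 5) * net$b_rad_s[p] * net$b_rad_s[q] * p2
      if (abs(coef) < .Machine$double.eps) next
      for (m in 1:5) {
        rvec <- rvec - coef * (cdag[[p]][[m]] %*% ck[[q]][[m]])
      }
    }
  }

  rpo <- Conj(t(basis$B)) %*% rvec %*% basis$B
  im_max <- max(abs(Im(rpo)))
  scale <- max(abs(Re(rpo)), 1e-300)
  if (im_max > 1e-8 * scale) {
    rlang::abort(sprintf(
      "Redfield assembly produced unexpected imaginary parts (%.3g relative)",
      im_max / scale), class = "spinlls_numeric_error")
  }
  .new_superoperator(Re(rpo), "relaxation", basis)
}

#' Calibrate the rotational correlation time from a reference T1
#'
#' Inverts the extreme-narrowing like-spin pair relation
#' `1/T1 = (3/2) b^2 tau_c` (the closed-form limit of the Redfield engine;
#' see `spinlls_constants$t1_extreme_narrowing_factor`) for a proton pair at
#' distance `r_ref`. Because `tau_c` is calibrated and consumed under one
#' and the same convention, downstream lifetime predictions are
#' self-consistent.
#'
#' @param t1_ref measured longitudinal relaxation time, s (> 0).
#' @param r_ref interproton distance of the reference pair, angstrom.
#' @return correlation time in seconds.
#' @examples
#' calibrate_tau_c(t1_ref = 0.72, r_ref = 1.77)   # ~ 50 ps
#' @export
calibrate_tau_c <- function(t1_ref, r_ref = 1.77) {
  if (!is.numeric(t1_ref) || t1_ref <= 0) abort_schema("t1_ref must be positive")
  b <- dipolar_constant(r_ref)
  f <- spinlls_constants$t1_extreme_narrowing_factor
  1 / (t1_ref * f * b^2)
}

#' Extreme-narrowing T1 of an isolated like-spin pair
#'
#' The closed-form companion of [calibrate_tau_c()]:
#' `T1 = 1 / ((3/2) b^2 tau_c)`.
#'
#' @param tau_c correlation time, s.
#' @param r interproton distance, angstrom.
#' @return T1 in seconds.
#' @export
pair_t1_extreme_narrowing <- function(tau_c, r = 1.77) {
  if (!is.numeric(tau_c) || tau_c <= 0) abort_schema("tau_c must be positive")
  b <- dipolar_constant(r)
  f <- spinlls_constants$t1_extreme_narrowing_factor
  1 / (f * b^2 * tau_c)
}
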