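# single spin-1/2 operator matrices
.pauli <- local({
  E <- diag(2) + 0i
  x <- matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i
  y <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)   # column-major: Iy = [[0,-i/2],[i/2,0]]
  z <- matrix(c(0.5, 0, 0, -0.5), 2, 2) + 0i
  list(E = E, x = x, y = y, z = z)
})

#' Single-site spin operator on the full Hilbert space
#'
#' @param n number of spins.
#' @param site site index (1-based; site 1 is the leftmost Kronecker factor).
#' @param op one of `"x"`, `"y"`, `"z"`, `"p"`, `"m"` (raising/lowering), `"E"`.
#' @return a `2^n x 2^n` complex matrix.
#' @export
spin_op <- function(n, site, op) {
  m <- switch(op,
    x = .pauli$x, y = .pauli$y, z = .pauli$z, E = .pauli$E,
    p = .pauli$x + 1i * .pauli$y,
    m = .pauli$x - 1i * .pauli$y,
    stop("unknown operator code: ", op))
  facs <- rep(list(.pauli$E), n)
  facs[[site]] <- m
  Reduce(kronecker, facs)
}

# sum over sites of one Cartesian component, e.g. total Iz
.op_total <- function(n, op, sites = seq_len(n)) {
  out <- matrix(0i, 2^n, 2^n)
  for (s in sites) out <- out + spin_op(n, s, op)
  out
}

# scalar product I_i . I_j
.op_scalar_product <- function(n, i, j) {
  spin_op(n, i, "x") %*% spin_op(n, j, "x") +
  spin_op(n, i, "y") %*% spin_op(n, j, "y") +
  spin_op(n, i, "z") %*% spin_op(n, j, "z")
}

# singlet-state projector of pair (i, j): P_S = E/4 - I_i . I_j
.op_singlet_projector <- function(n, i, j) {
  diag(2^n) / 4 - .op_scalar_product(n, i, j)
}

.basis_cache <- new.env(parent = emptyenv())

#' Orthonormal product-operator basis
#'
#' Builds the `4^n`-element basis of Kronecker products of
#' `{E/sqrt(2), sqrt(2) Ix, sqrt(2) Iy, sqrt(2) Iz}` per site. Every element
#' has unit Frobenius norm and the set is orthonormal under the trace inner
#' product `<A, B> = Tr(A^H B)`. Ordering is deterministic: the normalized
#' identity first, then single-spin x/y/z terms in site order, then
#' higher products in lexicographic site order.
#'
#' @param n spin count (1 to the cap, default cap 6).
#' @return an object of class `po_basis` with fields `n`, `dim` (`2^n`),
#'   `size` (`4^n`), `codes` (size x n matrix over 0:3 = E/x/y/z),
#'   `labels`, and `B`, the `4^n x 4^n` complex matrix whose columns are the
#'   vectorized basis operators.
#' @examples
#' b <- product_basis(2)
#' b$labels[1:6]
#' @export
product_basis <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort_schema("spin count n must be a positive integer")
  }
  n <- as.integer(n)
  if (n > .spinlls_cap()) {
    abort_schema(sprintf("n = %d exceeds the spin-count cap %d", n, .spinlls_cap()))
  }
  key <- as.character(n)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])

  codes <- as.matrix(expand.grid(rep(list(0:3), n))[, n:1, drop = FALSE])
  colnames(codes) <- NULL
  weight <- rowSums(codes > 0)
  site_key <- apply(codes, 1, function(r) paste(sprintf("%02d", which(r > 0)), collapse = ""))
  op_key <- apply(codes, 1, function(r) paste(r[r > 0], collapse = ""))
  ord <- order(weight, site_key, op_key)
  codes <- codes[ord, , drop = FALSE]

  letters4 <- c("E", "x", "y", "z")
  norm1 <- list(.pauli$E / sqrt(2), sqrt(2) * .pauli$x,
                sqrt(2) * .pauli$y, sqrt(2) * .pauli$z)
  dim_h <- 2^n
  size <- 4^n
  B <- matrix(0i, dim_h^2, size)
  labels <- character(size)
  for (k in seq_len(size)) {
    cd <- codes[k, ]
    op <- Reduce(kronecker, norm1[cd + 1L])
    B[, k] <- as.vector(op)
    labels[k] <- if (all(cd == 0)) "E" else {
      idx <- which(cd > 0)
      paste0(letters4[cd[idx] + 1L], idx, collapse = "")
    }
  }
  out <- structure(list(n = n, dim = dim_h, size = size, codes = codes,
                        labels = labels, B = B),
                   class = "po_basis")
  .basis_cache[[key]] <- out
  out
}

#' @export
print.po_basis <- function(x, ...) {
  cat(sprintf("<po_basis> %d spin(s): %d orthonormal product operators\n",
              x$n, x$size))
  invisible(x)
}

#' Expand an operator in the product basis
#'
#' @param op a `2^n x 2^n` matrix.
#' @param basis a [product_basis()].
#' @return a `state_vector`: the complex coefficient vector under the trace
#'   inner product.
#' @export
state_from_operator <- function(op, basis) {
  amp <- as.vector(Conj(t(basis$B)) %*% as.vector(op))
  structure(list(amplitudes = amp, n = basis$n), class = "state_vector")
}

#' Reassemble the operator encoded by a state vector
#' @param state a `state_vector` (or bare coefficient vector).
#' @param basis a [product_basis()].
#' @return a `2^n x 2^n` complex matrix.
#' @export
operator_from_state <- function(state, basis) {
  amp <- if (inherits(state, "state_vector")) state$amplitudes else state
  matrix(basis$B %*% amp, basis$dim, basis$dim)
}

#' @export
print.state_vector <- function(x, ...) {
  cat(sprintf("<state_vector> %d spin(s), norm %.6g\n",
              x$n, sqrt(sum(Mod(x$amplitudes)^2))))
  invisible(x)
}

#' Rotating-frame coherent Hamiltonian
#'
#' Assembles `H = sum_i 2 pi Omega_i I_iz + sum_(i<j) 2 pi J_ij I_i.I_j +
#' 2 pi nu_1 sum_i (cos(phi) I_ix + sin(phi) I_iy)` in rad/s, where the
#' offsets `Omega_i = (delta_i - carrier) * nu_ref * 1e-6` are retained or
#' zeroed according to `ctx$shift_mode` and `nu_ref` is the proton Larmor
#' frequency at `ctx$b0`.
#'
#' @param sys a [spin_system()].
#' @param ctx a [sim_context()]; `carrier` is required in retained mode.
#' @param rf_amplitude CW amplitude in Hz; defaults to `ctx$rf_amplitude`.
#' @param rf_phase RF phase in radians (0 = x).
#' @return a `2^n x 2^n` Hermitian complex matrix (rad/s).
#' @export
coherent_hamiltonian <- function(sys, ctx, rf_amplitude = NULL, rf_phase = 0) {
  n <- n_spins(sys)
  nu1 <- rf_amplitude %||% ctx$rf_amplitude
  h <- matrix(0i, 2^n, 2^n)
  if (ctx$shift_mode == "retained") {
    if (is.null(ctx$carrier)) {
      abort_schema("shift_mode = 'retained' requires ctx$carrier (ppm)")
    }
    offs_hz <- (sys$shifts - ctx$carrier) * larmor_frequency(ctx$b0) * 1e-6
    for (i in seq_len(n)) h <- h + 2 * pi * offs_hz[i] * spin_op(n, i, "z")
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sys$j_matrix[i, j] != 0) {
        h <- h + 2 * pi * sys$j_matrix[i, j] * .op_scalar_product(n, i, j)
      }
    }
  }
  if (nu1 > 0) {
    h <- h + 2 * pi * nu1 * (cos(rf_phase) * .op_total(n, "x") +
                             sin(rf_phase) * .op_total(n, "y"))
  }
  h
}

# plain commutator superoperator [X, .] in the vec representation
.comm_vec <- function(x) {
  d <- nrow(x)
  id <- diag(d)
  kronecker(id, x) - kronecker(t(x), id)
}

.new_superoperator <- function(matrix, kind, basis) {
  structure(list(matrix = matrix, kind = kind, n = basis$n,
                 labels = basis$labels),
            class = "superoperator")
}

#' @export
print.superoperator <- function(x, ...) {
  cat(sprintf("<superoperator> kind '%s', %d spin(s), dimension %d\n",
              x$kind, x$n, nrow(x$matrix)))
  invisible(x)
}

#' Commutation superoperator of a Hamiltonian
#'
#' Realizes the coherent Liouvillian `L0 rho = -i (H rho - rho H)` as a
#' matrix on the product-operator basis. Its spectrum is purely imaginary
#' and the identity is a two-sided null vector (trace preservation).
#'
#' @param h Hermitian `2^n x 2^n` matrix in rad/s.
#' @param basis a [product_basis()] for the same `n`; built if missing.
#' @return a `superoperator` of kind `"coherent"`.
#' @export
commutation_superoperator <- function(h, basis = NULL) {
  h <- as.matrix(h)
  scale <- max(1, max(Mod(h)))
  if (max(Mod(h - Conj(t(h)))) > 1e-9 * scale) {
    rlang::abort("Hamiltonian is not Hermitian to tolerance",
                 class = "spinlls_numeric_error")
  }
  n <- as.integer(round(log2(nrow(h))))
  basis <- basis %||% product_basis(n)
  lvec <- -1i * .comm_vec(h)
  lpo <- Conj(t(basis$B)) %*% lvec %*% basis$B
  .new_superoperator(lpo, "coherent", basis)
}

#' Propagate a state vector
#'
#' Returns `exp(L t) v` by scaling-and-squaring of the (generally
#' non-normal, complex) Liouvillian; piecewise-constant segments compose by
#' repeated calls.
#'
#' @param state a `state_vector` or bare coefficient vector.
#' @param l a `superoperator` (units rad/s and 1/s).
#' @param t duration in seconds (>= 0).
#' @return a `state_vector`.
#' @export
propagate <- function(state, l, t) {
  amp <- if (inherits(state, "state_vector")) state$amplitudes else state
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    rlang::abort("propagation time must be a single finite value >= 0",
                 class = "spinlls_numeric_error")
  }
  if (length(amp) != nrow(l$matrix)) {
    rlang::abort("state/superoperator dimension mismatch",
                 class = "spinlls_numeric_error")
  }
  out <- if (t == 0) amp else as.vector(expm_complex(l$matrix * t) %*% amp)
  structure(list(amplitudes = out, n = l$n), class = "state_vector")
}
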