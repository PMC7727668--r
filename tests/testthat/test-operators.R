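test_that("product basis is orthonormal with the documented ordering", {
  b1 <- product_basis(1)
  expect_equal(b1$size, 4)
  expect_equal(b1$labels, c("E", "x1", "y1", "z1"))

  for (n in 2:3) {
    b <- product_basis(n)
    gram <- Conj(t(b$B)) %*% b$B
    expect_lt(max(Mod(gram - diag(b$size))), 1e-12)
    expect_equal(b$labels[1], "E")
    # single-spin terms come right after the identity, in site order
    expect_equal(b$labels[2:4], c("x1", "y1", "z1"))
  }
  expect_error(product_basis(0), class = "spinlls_schema_error")
  expect_error(product_basis(9), "cap", class = "spinlls_schema_error")
})

test_that("the two-spin singlet projector has unit norm in the basis", {
  b <- product_basis(2)
  ps <- diag(4) / 4 - (spin_op(2, 1, "x") %*% spin_op(2, 2, "x") +
                       spin_op(2, 1, "y") %*% spin_op(2, 2, "y") +
                       spin_op(2, 1, "z") %*% spin_op(2, 2, "z"))
  v <- state_from_operator(ps, b)
  expect_equal(sum(Mod(v$amplitudes)^2), 1, tolerance = 1e-12)
  # and the expansion reassembles the operator exactly
  expect_lt(max(Mod(operator_from_state(v, b) - ps)), 1e-12)
})

test_that("coherent Hamiltonian reproduces closed-form spectra", {
  # on-resonance, uncoupled, no RF: the zero operator
  sys0 <- make_fixture("pair", delta_ppm = 0, j_hz = 0)
  ctx0 <- sim_context(b0 = 9.36, shift_mode = "retained", carrier = 4)
  expect_lt(max(Mod(coherent_hamiltonian(sys0, ctx0))), 1e-12)

  # isolated pair, J = 10 Hz, suppressed shifts: singlet and central
  # triplet split by exactly 2 pi J
  sysj <- make_fixture("pair", delta_ppm = 0.2, j_hz = 10)
  h <- coherent_hamiltonian(sysj, sim_context(shift_mode = "suppressed"))
  ev <- sort(Re(eigen(h, symmetric = TRUE)$values))
  expect_equal(ev[2] - ev[1], 2 * pi * 10, tolerance = 1e-9)

  # retained shifts without a carrier is an error
  expect_error(
    coherent_hamiltonian(sysj, sim_context(shift_mode = "retained")),
    "carrier", class = "spinlls_schema_error")
})

test_that("commutation superoperator is trace-preserving with imaginary spectrum", {
  b <- product_basis(2)
  expect_lt(max(Mod(commutation_superoperator(diag(4), b)$matrix)), 1e-12)

  sysj <- make_fixture("pair", delta_ppm = 0.1, j_hz = 12)
  h <- coherent_hamiltonian(sysj, sim_context(b0 = 9.36, shift_mode = "retained",
                                              carrier = 4))
  l <- commutation_superoperator(h, b)
  expect_lt(max(Mod(l$matrix[, 1])), 1e-12)   # identity: right null vector
  expect_lt(max(Mod(l$matrix[1, ])), 1e-12)   # identity: left null vector
  ev <- eigen(l$matrix, only.values = TRUE)$values
  expect_lt(max(abs(Re(ev))), 1e-9 * max(abs(ev), 1))

  # J Hamiltonian commutes with the singlet population
  hj <- coherent_hamiltonian(sysj, sim_context(shift_mode = "suppressed"))
  lj <- commutation_superoperator(hj, b)
  ps <- diag(4) / 4 - (spin_op(2, 1, "x") %*% spin_op(2, 2, "x") +
                       spin_op(2, 1, "y") %*% spin_op(2, 2, "y") +
                       spin_op(2, 1, "z") %*% spin_op(2, 2, "z"))
  v <- state_from_operator(ps, b)$amplitudes
  expect_lt(max(Mod(lj$matrix %*% v)), 1e-9)

  expect_error(commutation_superoperator(matrix(c(0, 1, 0, 0), 2), product_basis(1)),
               "Hermitian", class = "spinlls_numeric_error")
})

test_that("propagation is unitary, composable, and matches closed-form rotation", {
  sysj <- make_fixture("pair", delta_ppm = 0.1, j_hz = 12)
  b <- product_basis(2)
  ctx <- sim_context(b0 = 9.36, shift_mode = "retained", carrier = 4)
  l <- commutation_superoperator(coherent_hamiltonian(sysj, ctx), b)
  v0 <- state_from_operator(spin_op(2, 1, "z") + 0.3 * spin_op(2, 2, "x"), b)

  expect_equal(propagate(v0, l, 0)$amplitudes, v0$amplitudes)
  v1 <- propagate(v0, l, 0.123)
  expect_equal(sum(Mod(v1$amplitudes)^2), sum(Mod(v0$amplitudes)^2),
               tolerance = 1e-9)
  v2a <- propagate(propagate(v0, l, 0.05), l, 0.075)
  v2b <- propagate(v0, l, 0.125)
  expect_equal(v2a$amplitudes, v2b$amplitudes, tolerance = 1e-9)

  # 90-degree RF segment: nu1 * t = 1/4 turns z into transverse, amplitude
  # preserved
  sys1 <- make_fixture("pair", delta_ppm = 0, j_hz = 0)
  hrf <- coherent_hamiltonian(sys1, sim_context(shift_mode = "suppressed"),
                              rf_amplitude = 25, rf_phase = pi / 2)
  lrf <- commutation_superoperator(hrf, b)
  vz <- state_from_operator(spin_op(2, 1, "z") + spin_op(2, 2, "z"), b)
  vx <- propagate(vz, lrf, 1 / (4 * 25))
  target <- state_from_operator(spin_op(2, 1, "x") + spin_op(2, 2, "x"), b)
  expect_equal(vx$amplitudes, target$amplitudes, tolerance = 1e-9)

  expect_error(propagate(v0, l, -1), class = "spinlls_numeric_error")
  expect_error(propagate(v0$amplitudes[1:3], l, 1), "mismatch",
               class = "spinlls_numeric_error")
})

test_that("triplet and singlet populations sum to the conserved identity component", {
  sysj <- make_fixture("pair", delta_ppm = 0.05, j_hz = 8)
  ctx <- sim_context(b0 = 9.36)
  b <- product_basis(2)
  l <- assemble_liouvillian(sysj, ctx, b)
  # sum of all four state populations is the identity, whose coefficient is
  # untouched by any trace-preserving generator
  v0 <- state_from_operator(diag(4) / 2 +
                              0.4 * spin_op(2, 1, "z") %*% spin_op(2, 2, "z"), b)
  v1 <- propagate(v0, l, 2.5)
  expect_equal(v1$amplitudes[1], v0$amplitudes[1], tolerance = 1e-12)
})
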