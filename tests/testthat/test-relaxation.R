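test_that("dipolar constant has the right magnitude and r^-3 scaling", {
  b <- dipolar_constant(1.77)
  expect_lt(b, 0)
  expect_equal(abs(b) / (2 * pi), 2.17e4, tolerance = 0.005)
  expect_equal(dipolar_constant(2 * 1.77) / b, 1 / 8, tolerance = 1e-12)
  expect_lt(abs(dipolar_constant(500)), 0.01)  # ~6e-3 rad/s at 500 A
  expect_error(dipolar_constant(0), class = "spinlls_schema_error")
  expect_error(dipolar_constant(-1), class = "spinlls_schema_error")
})

test_that("spectral density is the Lorentzian of isotropic tumbling", {
  tc <- 50e-12
  expect_equal(spectral_density(0, tc), tc)
  expect_equal(spectral_density(1 / tc, tc), tc / 2)
  w400 <- 2 * pi * larmor_frequency(9.36)
  expect_equal(spectral_density(w400, tc) / tc, 1, tolerance = 0.016)
  expect_error(spectral_density(1, -1), class = "spinlls_schema_error")
})

test_that("relaxation superoperator has the structural invariants", {
  sys <- make_fixture("named_metabolite", name = "Ser")
  ctx <- sim_context(b0 = 9.36, tau_c = 50e-12)
  r <- redfield_superoperator(sys, ctx)
  m <- r$matrix
  expect_true(is.double(m))                     # real on the product basis
  expect_lt(max(abs(m[, 1])), 1e-12)            # annihilates the identity
  expect_lt(max(abs(m[1, ])), 1e-12)
  ev <- eigen(m, only.values = TRUE)$values
  expect_lt(max(Re(ev)), 1e-9)                  # purely dissipative

  lone <- spin_system("lone", "H1", 4.0, coords = matrix(c(0, 0, 0), 1))
  expect_equal(max(abs(redfield_superoperator(lone, ctx)$matrix)), 0)

  nocoord <- spin_system("nc", c("a", "b"), c(4, 3.9),
                         matrix(c(0, 5, 5, 0), 2))
  expect_error(redfield_superoperator(nocoord, ctx), "coordinates",
               class = "spinlls_schema_error")
})

test_that("intra-pair dipolar coupling cannot relax the singlet", {
  sys <- make_fixture("equivalent_pair", r = 1.77)
  ctx <- sim_context(b0 = 9.36, tau_c = 50e-12)
  b <- product_basis(2)
  r <- redfield_superoperator(sys, ctx, b)
  ps <- diag(4) / 4 - (spin_op(2, 1, "x") %*% spin_op(2, 2, "x") +
                       spin_op(2, 1, "y") %*% spin_op(2, 2, "y") +
                       spin_op(2, 1, "z") %*% spin_op(2, 2, "z"))
  v <- state_from_operator(ps, b)$amplitudes
  expect_lt(max(abs(r$matrix %*% v)), 1e-9)
})

test_that("numeric pair rate matches the closed-form oracle", {
  ctx <- sim_context(b0 = 9.36, tau_c = 50e-12)
  for (r_ang in c(1.77, 2.5)) {
    sys <- make_fixture("equivalent_pair", r = r_ang)
    expect_equal(numeric_pair_r1(sys, ctx),
                 oracle_pair_r1(r_ang, ctx$tau_c, ctx$b0),
                 tolerance = 1e-5)
  }
  # outside extreme narrowing the frequency dependence must follow too
  slow <- sim_context(b0 = 9.36, tau_c = 2e-9)
  sys <- make_fixture("equivalent_pair", r = 1.77)
  expect_equal(numeric_pair_r1(sys, slow),
               oracle_pair_r1(1.77, 2e-9, 9.36), tolerance = 1e-5)
})

test_that("distant partners contribute negligibly; removing them restores immunity", {
  ctx <- sim_context(b0 = 9.36, tau_c = 50e-12)
  # pair separated by 100 A: longitudinal rate far below 1e-4 s^-1
  far <- make_fixture("pair", delta_ppm = 0, j_hz = 0, r = 100)
  expect_lt(numeric_pair_r1(far, ctx), 1e-4)

  # triad with Ha moved 100 A away: the Ha dipolar channel is gone, but the
  # coherent J leakage into the pair's own dipolar relaxation remains, so
  # the LLS rate drops well below the full-triad value without vanishing
  tri <- make_fixture("named_metabolite", name = "Ser")
  full_rate <- find_lls(assemble_liouvillian(tri, ctx))$rate
  tri$coords["Ha", ] <- c(100, 0, 0)
  far_rate <- find_lls(assemble_liouvillian(tri, ctx))$rate
  expect_lt(far_rate, full_rate / 3)

  # removing the J couplings as well restores true isolated-pair immunity
  tri$j_matrix["Ha", c("Hb2", "Hb3")] <- 0
  tri$j_matrix[c("Hb2", "Hb3"), "Ha"] <- 0
  iso_rate <- find_lls(assemble_liouvillian(tri, ctx))$rate
  expect_lt(iso_rate, 1e-6)
})

test_that("relaxation is invariant under site relabeling", {
  ctx <- sim_context(b0 = 9.36, tau_c = 50e-12)
  sys <- make_fixture("named_metabolite", name = "Ser")
  perm <- c(3, 1, 2)
  sys2 <- spin_system(sys$name, sys$labels[perm], sys$shifts[perm],
                      sys$j_matrix[perm, perm], sys$coords[perm, ])
  r1 <- sort(Re(eigen(redfield_superoperator(sys, ctx)$matrix,
                      only.values = TRUE)$values))
  r2 <- sort(Re(eigen(redfield_superoperator(sys2, ctx)$matrix,
                      only.values = TRUE)$values))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("tau_c calibration inverts the extreme-narrowing pair relation", {
  t1 <- pair_t1_extreme_narrowing(50e-12, 1.77)
  expect_equal(t1, 0.72, tolerance = 0.01)
  expect_equal(calibrate_tau_c(t1, 1.77), 50e-12, tolerance = 1e-10)
  expect_error(calibrate_tau_c(0), class = "spinlls_schema_error")
  expect_error(calibrate_tau_c(-1), class = "spinlls_schema_error")
})
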