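ctx_hi <- sim_context(b0 = 9.36, tau_c = 50e-12, shift_mode = "suppressed")

test_that("assembled Liouvillian has the right structure", {
  ser <- make_fixture("named_metabolite", name = "Ser")
  l <- assemble_liouvillian(ser, ctx_hi)
  expect_equal(nrow(l$matrix), 64)
  expect_identical(l$kind, "total")
  expect_lt(max(Mod(l$matrix[, 1])), 1e-12)

  # with no couplings and suppressed shifts the total generator is pure
  # relaxation
  eqp <- make_fixture("equivalent_pair", j_hz = 0)
  l0 <- assemble_liouvillian(eqp, ctx_hi)
  r0 <- redfield_superoperator(eqp, ctx_hi)
  expect_lt(max(Mod(l0$matrix - r0$matrix)), 1e-12)
})

test_that("all Liouvillian eigenvalues are dissipative on random fixtures", {
  set.seed(42)
  for (k in 1:5) {
    sys <- make_fixture("geminal_triad",
                        j_is = -runif(1, 8, 16), j_ir = runif(1, 0, 7),
                        j_sr = runif(1, 0, 7), r = runif(1, 1.6, 1.9),
                        shifts = 3.9 + runif(3, -0.3, 0.3))
    cx <- sim_context(b0 = runif(1, 1, 12), tau_c = runif(1, 20, 200) * 1e-12,
                      shift_mode = "retained", carrier = 3.9)
    ev <- eigen(assemble_liouvillian(sys, cx)$matrix, only.values = TRUE)$values
    expect_lt(max(Re(ev)), 1e-9)
  }
})

test_that("the equivalent pair supports an effectively immune singlet state", {
  fum <- make_fixture("named_metabolite", name = "fumarate")
  mode <- find_lls(assemble_liouvillian(fum, ctx_hi))
  expect_lt(mode$rate, 1e-4)
  expect_gt(mode$lifetime, 100)
  expect_gt(mode$singlet_overlap, 0.99)
})

test_that("a relaxation-free Liouvillian yields the no-LLS error", {
  ser <- make_fixture("named_metabolite", name = "Ser")
  lc <- assemble_liouvillian(ser, ctx_hi, include_relaxation = FALSE)
  expect_error(find_lls(lc), "no LLS", class = "spinlls_no_lls_error")
})

test_that("inversion-recovery T1 of an isolated pair matches the oracle", {
  sys <- make_fixture("equivalent_pair", r = 1.77)
  t1 <- as.numeric(predict_t1(sys, ctx_hi, "H1"))
  expect_equal(t1, 1 / oracle_pair_r1(1.77, 50e-12, 9.36), tolerance = 0.02)

  lone <- spin_system("lone", "H1", 4.0, coords = matrix(c(0, 0, 0), 1))
  expect_error(predict_t1(lone, ctx_hi, "H1"), "no relaxation pathway",
               class = "spinlls_numeric_error")
  expect_error(predict_t1(sys, ctx_hi, "Hx"), "unknown site",
               class = "spinlls_schema_error")
})

test_that("field sweep reports per-field lifetimes and composition changes", {
  ser <- make_fixture("named_metabolite", name = "Ser")
  one <- field_sweep(ser, ctx_hi, 9.36)
  expect_equal(nrow(one), 1)

  # suppressed shifts in extreme narrowing: the field only enters through
  # tiny w^2 tau_c^2 corrections (at 3 T and below these are < 1 percent)
  sw <- field_sweep(ser, ctx_hi, c(3, 1))
  expect_equal(sw$t_lls[1], sw$t_lls[2], tolerance = 0.02)

  # retained shifts at low field: serine's lifetime exceeds the high-field
  # sustained value
  cx <- sim_context(tau_c = 50e-12, shift_mode = "retained",
                    carrier = mean(ser$shifts))
  swr <- field_sweep(ser, cx, c(9.36, 1))
  expect_gt(swr$t_lls[2], swr$t_lls[1])

  expect_error(field_sweep(ser, ctx_hi, numeric(0)),
               class = "spinlls_schema_error")
  expect_error(field_sweep(ser, ctx_hi, c(1, -2)),
               class = "spinlls_schema_error")
})

test_that("reported lifetimes are invariant under site permutation", {
  ser <- make_fixture("named_metabolite", name = "Ser")
  perm <- c(2, 3, 1)
  ser2 <- spin_system(ser$name, ser$labels[perm], ser$shifts[perm],
                      ser$j_matrix[perm, perm], ser$coords[perm, ])
  t1 <- find_lls(assemble_liouvillian(ser, ctx_hi))$lifetime
  t2 <- find_lls(assemble_liouvillian(ser2, ctx_hi))$lifetime
  expect_equal(t1, t2, tolerance = 1e-6)
})

test_that("Q_ISR optimization reduces to a pure singlet in the isolated-pair limit", {
  tri <- make_fixture("geminal_triad", j_is = -12, j_ir = 0, j_sr = 0)
  tri$coords["Ha", ] <- c(100, 0, 0)
  q <- qisr_optimize(tri, sim_context(b0 = 1, tau_c = 50e-12))
  expect_equal(q$lambda_is, sqrt(3) / 2, tolerance = 1e-3)
  expect_lt(abs(q$lambda_ir), 1e-3)
  expect_lt(abs(q$lambda_sr), 1e-3)

  pair <- make_fixture("pair")
  expect_error(qisr_optimize(pair), "3 spins", class = "spinlls_schema_error")
})

test_that("lambda dominance holds for all tabulated triads", {
  for (nm in c("Ser", "Asn", "Asp", "His")) {
    q <- qisr_optimize(make_fixture("named_metabolite", name = nm),
                       sim_context(b0 = 1, tau_c = 50e-12))
    expect_gt(abs(q$lambda_is), abs(q$lambda_ir))
    expect_gt(abs(q$lambda_is), abs(q$lambda_sr))
    expect_lte(q$lambda_is^2 + q$lambda_ir^2 + q$lambda_sr^2, 1)
  }
})

test_that("the Q_ISR mode cannot outlive the slowest eigenmode", {
  ser <- make_fixture("named_metabolite", name = "Ser")
  cx <- sim_context(b0 = 1, tau_c = 50e-12)
  q <- qisr_optimize(ser, cx)
  slowest <- find_lls(assemble_liouvillian(ser, cx))
  expect_lte(q$lifetime, slowest$lifetime * (1 + 1e-9))
})

test_that("tidy and glance methods expose the fitted quantities", {
  ser <- make_fixture("named_metabolite", name = "Ser")
  rep <- lls_report(ser, ctx_hi)
  td <- tidy(rep)
  expect_equal(nrow(td), 3)
  expect_true(all(c("site", "t1_s", "t_lls_s") %in% names(td)))
  expect_equal(glance(rep)$t_lls_s, rep$t_lls)

  q <- qisr_optimize(ser, sim_context(b0 = 1))
  expect_equal(tidy(q)$estimate[1], q$lambda_is)
  expect_equal(glance(q)$t_qisr_s, q$lifetime)
})
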