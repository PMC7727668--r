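# Closed-form oracle for the longitudinal relaxation of an isolated pair of
# like spins under intramolecular dipolar coupling and isotropic tumbling:
#   R1 = (3/10) b^2 [ j(w0) + 4 j(2 w0) ],  j(w) = tau_c / (1 + w^2 tau_c^2)
# derived by hand from the double-commutator Redfield integral with rank-2
# spherical tensors (extreme-narrowing limit (3/2) b^2 tau_c). Constants are
# inlined so the oracle shares no code with the relaxation engine.
oracle_pair_r1 <- function(r_angstrom, tau_c, b0) {
  gamma <- 2.6752218744e8
  hbar <- 1.054571817e-34
  b <- -1e-7 * gamma^2 * hbar / (r_angstrom * 1e-10)^3
  w0 <- gamma * b0
  j <- function(w) tau_c / (1 + (w * tau_c)^2)
  (3 / 10) * b^2 * (j(w0) + 4 * j(2 * w0))
}

# nonselective longitudinal rate extracted from a relaxation superoperator:
# the decay rate of total Iz (an eigenvector of R for an equivalent pair)
numeric_pair_r1 <- function(sys, ctx) {
  n <- n_spins(sys)
  basis <- product_basis(n)
  r <- redfield_superoperator(sys, ctx, basis)
  nz <- Reduce(`+`, lapply(seq_len(n), function(k) spin_op(n, k, "z")))
  v <- state_from_operator(nz, basis)$amplitudes
  -Re(sum(Conj(v) * (r$matrix %*% v))) / sum(Mod(v)^2)
}
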