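# spinlls

A-priori prediction of nuclear magnetization lifetimes in small
metabolites from their proton spin systems.

Hyperpolarized magnetic resonance (dissolution DNP) can follow metabolite
ratios through live biochemistry — but only for as long as the enhanced
magnetization survives. Pairs and triads of coupled protons support
*long-lived states* (LLS), archetypally the singlet–triplet population
imbalance, whose decay constant T<sub>LLS</sub> can exceed T<sub>1</sub>
many times because the dominant relaxation mechanism, intramolecular
dipole–dipole coupling, is symmetric under spin permutation and cannot
connect the antisymmetric singlet to the symmetric triplets. `spinlls` is
for spectroscopists screening candidate biomarker molecules: it predicts
T<sub>1</sub> and T<sub>LLS</sub> before any spectrometer time is spent,
and simulates the SLIC experiment used to measure them.

## The model

For a declared spin system (shifts δᵢ in ppm, couplings J<sub>ij</sub> in
Hz, proton coordinates in Å) the package builds, on the orthonormal
product-operator basis, the Liouvillian

  𝓛 = −i[𝓗, ·] + 𝓡,  𝓗 = Σᵢ 2πΩᵢ I<sub>iz</sub> + Σ<sub>i&lt;j</sub> 2πJ<sub>ij</sub> **I**ᵢ·**I**ⱼ + 2πν₁ Σᵢ I<sub>ix</sub>

with 𝓡 the full (non-secular) Bloch–Redfield–Wangsness dipolar
relaxation superoperator for isotropic tumbling: rank-2 spherical tensors
for every proton pair, cross-correlated terms weighted by
P₂(cos θ<sub>pq</sub>), Lorentzian spectral densities
j(ω) = τ<sub>c</sub>/(1+ω²τ<sub>c</sub>²) at the lab-frame
eigenfrequencies, and b = −(μ₀/4π)γ²ħ r⁻³. The convention is pinned by the
like-spin closed form R₁ = (3/10)b²[j(ω₀)+4j(2ω₀)] → (3/2)b²τ<sub>c</sub>,
which is also what the τ<sub>c</sub> calibration inverts (τ<sub>c</sub> =
50 ps throughout, calibrated on glycine). The LLS is the slowest
zero-frequency non-identity eigenmode of 𝓛; T<sub>1</sub> comes from a
simulated nonselective inversion recovery collapsed with a
mono-exponential fit, exactly as the experiment is analyzed.

## Worked example

```r
library(spinlls)

ser <- make_fixture("named_metabolite", name = "Ser")   # vendored shifts, J's, idealized geometry
ctx <- sim_context(b0 = 9.36, tau_c = 50e-12, shift_mode = "suppressed")

find_lls(assemble_liouvillian(ser, ctx))
#> <lls_mode> rate 0.118434 s^-1, lifetime 8.44353 s, |frequency| 1.52e-13 rad/s

predict_t1(ser, ctx, "Hb2")
#> [1] 0.9102584

series <- simulate_slic(ser, ctx)                        # SLIC sequence, delays 5/10/15/20 s
fit_decay(series, n_mc = 200, seed = 1,
          noise_sigma = 0.02 * max(series$intensity))
#> <decay_fit> T_LLS = 6.39 +/- 0.27 s (I0 = 0.244, 200 MC replicates, seed 1)
```

Read: at 9.36 T with ideal sustaining, serine's Hβ pair stores
magnetization for 8.4 s — nine times its Hβ T<sub>1</sub> of 0.91 s. The
SLIC-accessible singlet-order channel decays slightly faster (6.4 s) than
the slowest eigenmode, which is a three-spin correlated state. Sweeping
the field with chemical shifts retained shows the low-field enhancement
and the change in the nature of the state:

```r
cx <- sim_context(tau_c = 50e-12, shift_mode = "retained",
                  carrier = mean(ser$shifts))
field_sweep(ser, cx, c(9.36, 4, 2, 1))
#>      b0 t_lls  rate top_ops              composition_changed
#> 1  9.36  6.41 0.156 z3+z1+z1z2z3         FALSE
#> 2  4     5.70 0.175 z3+z1z2+z1z2z3       TRUE
#> 3  2     8.99 0.111 z1z2z3+y1y2z3+x1x2z3 TRUE
#> 4  1     9.70 0.103 z1z2z3+x1x2z3+y1y2z3 TRUE
```

Three-spin bilinear states (`qisr_optimize`), spin-system I/O
(YAML/JSON/XYZ via `load_spin_system`), tabular reports
(`report_tables`, `write_report_tsv`), broom-style `tidy()`/`glance()`
and `autoplot()` methods round out the surface. A command-line wrapper
lives at `inst/cli/spinlls.R`:

```sh
Rscript inst/cli/spinlls.R lls --system inst/extdata/serine.yaml --b0 9.36 --out report.tsv
```

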