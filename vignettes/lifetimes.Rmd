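---
title: "Predicting long-lived spin-state lifetimes in metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long-lived spin-state lifetimes in metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinlls)
```

## The problem

Hyperpolarization techniques such as dissolution DNP can boost nuclear
magnetization in metabolites by four orders of magnitude, but the enhanced
magnetization survives only as long as the spin order it is stored in.
Longitudinal magnetization decays with $T_1$, a second or so for aliphatic
protons of small molecules in solution. Pairs of coupled protons support a
*long-lived state* (LLS): the imbalance between the singlet population and
the mean triplet population. Because intramolecular dipole-dipole coupling —
the dominant proton relaxation mechanism — is symmetric under permutation of
the pair, it cannot connect the antisymmetric singlet to the symmetric
triplets, and the LLS can outlive $T_1$ many times over. `spinlls` predicts,
*a priori*, how long such states live in a given molecule, and simulates
the experiment used to measure them.

## The model

A molecule is declared as a proton spin system: site labels, chemical
shifts $\delta_i$ (ppm), scalar couplings $J_{ij}$ (Hz) and Cartesian
coordinates (Å). Only non-exchangeable (aliphatic) protons belong in the
system: N–H and O–H protons exchange with deuterated solvent and carry no
dipolar relaxation burden.

Everything happens in Liouville space on the orthonormal product-operator
basis (dimension $4^n$; identity first, then single-spin terms, then
products). The generator of motion has two parts,
$\dot\rho = \mathcal{L}\rho$ with
$\mathcal{L} = -i[\mathcal{H},\cdot\,] + \mathcal{R}$:

* **Coherent part.** The rotating-frame Hamiltonian
  $\mathcal{H} = \sum_i 2\pi\Omega_i I_{iz} + \sum_{i<j} 2\pi J_{ij}
  \mathbf{I}_i\cdot\mathbf{I}_j + 2\pi\nu_1\sum_i I_{ix}$, with offsets
  $\Omega_i$ either retained (free or low-field evolution) or suppressed
  (ideal RF sustaining, which masks the shift differences).

* **Relaxation.** A full (non-secular) Bloch–Redfield–Wangsness
  superoperator for intramolecular dipolar couplings under isotropic
  rotational diffusion. Each proton pair $p$ carries a coupling
  $b_p = -(\mu_0/4\pi)\gamma_H^2\hbar\, r_p^{-3}$; rank-2 spherical-tensor
  operators are combined as
  $$\mathcal{R}\rho = -\sum_{p,q,m}\tfrac{6}{5}\,b_p b_q\,
    P_2(\cos\theta_{pq})\,[T_{2m}^{(p)\dagger},[K_{2m}^{(q)},\rho]],$$
  where $\theta_{pq}$ is the angle between the internuclear vectors (the
  $P_2$ factor is the isotropic-tumbling cross-correlation amplitude from
  the spherical-harmonic addition theorem) and $K_{2m}$ carries the
  Lorentzian spectral density $j(\omega)=\tau_c/(1+\omega^2\tau_c^2)$
  evaluated at every eigenfrequency difference of the lab-frame
  Hamiltonian. Dynamic frequency shifts are dropped, leaving $\mathcal{R}$
  real on the product basis. The high-temperature homogeneous form is used
  for eigenanalysis (decay constants are unchanged by the equilibrium
  offset); the SLIC simulator adds the inhomogeneous recovery term so the
  phase cycle behaves as in the experiment.

The normalization of $\mathcal{R}$ is pinned, not trusted from any single
textbook: the engine must reproduce the hand-derived closed form for a
like-spin pair,
$$R_1 = \tfrac{3}{10} b^2\left[j(\omega_0) + 4 j(2\omega_0)\right]
\;\xrightarrow{\ \omega_0\tau_c\ll 1\ }\; \tfrac{3}{2} b^2\tau_c,$$
to 1 % across distances and correlation times (it matches to $4\times
10^{-7}$), and the isolated-pair singlet rate must vanish identically. The
same extreme-narrowing form is what `calibrate_tau_c()` inverts, so the
correlation-time calibration and the relaxation engine share one
convention by construction; $\tau_c$ = 50 ps (calibrated on glycine,
geminal distance 1.77 Å, reference $T_1 \approx 0.72$ s) is the default
for every molecule.

## What the package computes

**Long-lived states** (`find_lls`): the eigenmode of $\mathcal{L}$ with the
smallest decay rate among zero-frequency, non-identity modes; its inverse
rate is $T_\mathrm{LLS}$. The identity is removed exactly by deflation
(it is a two-sided null vector of $\mathcal{L}$), the zero-frequency
tolerance is $10^{-6}$ rad/s (relaxed adaptively when the spectrum
contains genuine oscillations), and rate ties are broken by singlet-order
overlap, then basis order.

**$T_1$** (`predict_t1`): a simulated nonselective inversion recovery —
all longitudinal terms inverted, evolution under the full $\mathcal{L}$,
and a three-parameter mono-exponential fit of the site's longitudinal
amplitude over a grid spanning five expected $T_1$. Cross-relaxation makes
the true recovery multi-exponential; the fit collapses it exactly the way
the experimental analysis does, which is why the fitted value can exceed
the naive inverse initial rate by 20 % or more in coupled networks.

**Bilinear three-spin states** (`qisr_optimize`): for a triad $(I,S,R)$
with $I,S$ the strongest-coupled pair, the ansatz
$Q = \tfrac{1}{3}(\lambda_{IS}\,\mathbf{I}\cdot\mathbf{S} +
\lambda_{IR}\,\mathbf{I}\cdot\mathbf{R} +
\lambda_{SR}\,\mathbf{S}\cdot\mathbf{R})$ is an exact eigenstate only when
Zeeman evolution is suppressed. The eigenmodes of the J-only Liouvillian
are computed, near-degenerate rate clusters are resolved by SVD against
the span of the three scalar products (inside a degenerate cluster the
numerical eigenbasis is arbitrary), and the most ansatz-like slow mode is
reported. The $\lambda$ coefficients use the *population-state*
convention: the traceless mode $\hat m$ is dressed with its unit-trace
background, $\hat Q = \tfrac12\hat E + \tfrac{\sqrt3}{2}\hat m$, so a pure
pair-singlet imbalance reports $|\lambda_{IS}| = \sqrt3/2 \approx 0.866$
and $\sum\lambda^2 \le 3/4$. This is the convention under which published
$\lambda$ tables for these systems are internally consistent (their
$\sum\lambda^2$ is constant at $3/4$ across molecules); the raw traceless
projections are kept in the result object.

**SLIC** (`slic_params`, `simulate_slic`, `fit_decay`): the spin-lock
induced crossover sequence with parameters derived from the molecule —
$\nu_\mathrm{exc} = \max|J_{ij}|$,
$\tau_\mathrm{exc} = 0.707/\Delta\nu_{IS}$,
$\nu_1 = 5\Delta\nu_{IS}$, carrier at the pair's mean shift, and a
$(y,-y)$ phase cycle. Hard pulses are ideal rotations; spin-lock and
sustain segments propagate the affine master equation with the matrix
exponential. Two modelling choices matter:

* *Sustain convention.* By default the sustain period applies ideal shift
  masking (the pair is "rendered magnetically equivalent"), matching the
  convention of the tabulated lifetimes. Finite-CW sustaining at
  $5\Delta\nu$ is available (`sustain_mode = "cw"`) and is genuinely
  lossier: on serine it shortens the fitted lifetime by about a quarter.
* *Inhomogeneity dephasing.* Components of the sustained state that
  oscillate under the sustain Hamiltonian are projected out at the start
  of the sustain period (the projector is built on the coherent
  superoperator's kernel, an orthonormal eigenspace). In a real sample
  these coherences dephase within milliseconds through B$_0$/B$_1$
  inhomogeneity; without the projection the relaxation-free limit would
  oscillate with delay instead of being constant.

Decay series are fitted with $I(t) = I_0 e^{-t/T}$ (log-linear start,
Levenberg–Marquardt refinement), and the error bar is the standard
deviation of the fitted $T$ over seeded Monte-Carlo replicates with
per-point Gaussian noise.

## Fixtures and geometry

The paper-grade inputs are vendored as fixtures: shifts are literature
values for the zwitterions in D$_2$O near neutral pH, J couplings are the
published three-spin values (serine: $-10.52$, $4.81$, $1.32$ Hz), and
geometries are idealized templates, *not* quantum-chemistry structures:

* geminal H–H distance 1.77 Å (the glycine value used for calibration);
* tetrahedral carbons with standard bond lengths;
* named amino-acid triads use the staggered rotamer with H$\alpha$ *anti*
  to one H$\beta$ (vicinal distances 2.47 and 3.04 Å) — the generic
  DFT energy minimum of $\alpha$-amino acids, where the heavy side-chain
  substituent sits gauche to the backbone. The plain `geminal_triad`
  fixture instead places H$\alpha$ symmetrically (both gauche, 2.47 Å),
  which keeps it exactly symmetric under H$\beta$ exchange;
* fumarate is a planar trans-olefinic fragment with textbook sp$^2$
  parameters (C=C 1.33 Å, C–H 1.085 Å, H–C=C 123°), giving a trans H–H
  distance of 3.10 Å.

Because low-field and three-spin lifetimes are dominated by the vicinal
dipolar couplings and their cross-correlation, they are very sensitive to
this geometry choice ($r^{-6}$): predictions made with one shared
idealized template reproduce high-field lifetimes and the low-field
enhancement mechanism, but *not* fine per-molecule orderings that
originate in conformer differences. This is the main known limitation,
and it is why the package accepts XYZ files: users with optimized
structures should supply them.

Methyl-bearing and aromatic systems (Thr, Val, Met, Phe) are outside the
fixture set: internal rotation averaging is not modeled and a static
three-proton methyl would overestimate its dipolar field. The spin-count
cap is 6 (Liouville dimension 4096) for dense superoperators; larger
networks are rejected with a suggestion to select a subsystem.

## Numerical choices

* Matrix exponentials: scaling-and-squaring with a degree-13 Padé
  approximant on complex matrices (the Liouvillian is complex and
  non-normal; the installed real-matrix routines do not apply).
* Eigenanalysis: LAPACK non-symmetric solver on the deflated Liouvillian;
  Hermitian solvers wherever the operator is Hermitian.
* Degenerate eigenspaces (equivalent pairs, decoupled spins) are never
  disambiguated by numerical accident: selections project onto the
  physically meaningful subspace (singlet overlap, ansatz span).
* Lifetimes of immune states are reported as $1/\max(\mathrm{rate},
  \varepsilon)$ so that roundoff-negative rates yield a large positive
  number rather than $\pm\infty$.
* All randomness (Monte-Carlo refits, noise injection) is seeded
  explicitly; identical configurations produce byte-identical reports.

## A worked example

```{r example}
ser <- make_fixture("named_metabolite", name = "Ser")
ctx <- sim_context(b0 = 9.36, tau_c = 50e-12, shift_mode = "suppressed")

mode <- find_lls(assemble_liouvillian(ser, ctx))
mode

predict_t1(ser, ctx, "Hb2")

series <- simulate_slic(ser, ctx)
fit_decay(series, n_mc = 200, seed = 1,
          noise_sigma = 0.02 * max(series$intensity))
```

At 9.36 T with ideal sustaining, the serine H$\beta$ pair stores
magnetization roughly nine times longer than its $T_1$. Sweeping the field
with retained shifts shows the low-field enhancement — at 1 T the
H$\alpha$ offset decouples part of the leakage pathway and the state
composition changes:

```{r sweep}
cx <- sim_context(tau_c = 50e-12, shift_mode = "retained",
                  carrier = mean(ser$shifts))
field_sweep(ser, cx, c(9.36, 4, 2, 1))
```

## What the tests do and do not show

The test suite validates the engine against independent closed forms
(like-spin pair rates at arbitrary $\omega_0\tau_c$, singlet immunity,
rotation closed forms), internal consistency (permutation invariance,
propagator composition, trace preservation), and the published computed
values for the fixture systems at their stated tolerances. Passing tests
demonstrate the spin dynamics is right *for the declared model*:
intramolecular dipolar relaxation of rigid, isotropically tumbling proton
networks at one correlation time. Real samples add intermolecular dipolar
coupling, paramagnetic oxygen, chemical-shift anisotropy and
conformational dynamics, all of which shorten real lifetimes relative to
these predictions — fumarate's "immune" singlet is the extreme case, where
the predicted lifetime is effectively infinite and entirely
mechanism-limited in practice.
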