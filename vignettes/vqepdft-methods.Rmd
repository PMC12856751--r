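---
title: "Hybrid circuit-CASCI / pair-density-functional methods in vqepdft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid circuit-CASCI / pair-density-functional methods in vqepdft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, the measurement protocol, what the synthetic fixtures emulate,
the numerical choices, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The model

### 1.1 Active-space problem

All calculations start from a restricted (closed-shell) or restricted
open-shell Hartree–Fock reference in a Gaussian basis. An `(N_e, N_o)`
active space selects the contiguous window of canonical orbitals bracketing
the Fermi level; everything below is a doubly occupied core whose mean field
is folded into an effective one-electron operator `h1` and a scalar `h0`
(which also absorbs nuclear repulsion and all classical point-charge
Coulomb terms). The resulting problem — `h0`, `h1`, chemist-notation
two-electron integrals `h2 = (pq|rs)`, the active orbital coefficients and
the core density — is the complete input to both the quantum-circuit solver
and the classical functional.

The window-selection rule ("take the `N_o` canonical orbitals around the
Fermi level") is deliberately simple: for planar π radicals and anions of
the kind packaged here the frontier window is the π system, and the rule
reproduces the standard CASCI construction of mainstream electronic
structure codes exactly (verified against an independent implementation at
the 10⁻¹⁰ Ha level in the test suite). No orbital re-optimization is
performed anywhere: the circuit state is a CASCI-level wavefunction, not a
CASSCF one.

QM/MM-style electrostatic embedding is represented by its minimal
surrogate: background point charges whose potential enters the one-electron
Hamiltonian and whose nuclear–charge and charge–charge Coulomb energies
enter `h0` once (so that four-point energy *differences* treat the
embedding consistently).

### 1.2 Qubit mapping and tapering

Spin orbitals are ordered as the full α block followed by the full β block.
The parity transformation stores cumulative occupation parities, so qubit
`M` (the last of the α block) carries the total α parity and qubit `2M` the
total electron parity. In a fixed `(N_α, N_β)` sector those two qubits are
constants of motion: every term of a particle-conserving operator acts on
them as `I` or `Z`, the `Z`s are replaced by the sector eigenvalues
`(−1)^{N_α}` and `(−1)^{N_α+N_β}`, and the register shrinks from `2M` to
`2M − 2` qubits (6 → 4 for the three-orbital patterns). The test suite
verifies, by dense diagonalization, that the tapered operator restricted to
the sector-allowed subspace has exactly the sector spectrum of the original
Hamiltonian.

### 1.3 The variational solver

The statevector engine is exact (noiseless) and little-endian (qubit 1 is
the least-significant index bit). UCCSD and its restricted open-shell
extension ROUCCSD are built as first-order Trotterized exponentials of
spin-conserving single and double excitation generators out of the
Hartree–Fock determinant, one parameter per excitation, in a fixed
deterministic operator order. A single Trotter step per excitation is
adequate because the ansatz is variational: any Trotter bias is absorbed by
the minimization (and for two-electron systems UCCSD is exact, which the
suite asserts at 10⁻⁸ Ha).

Minimization is quasi-Newton (BFGS) on the exact expectation value with
seeded multi-start; optimization never sees shot noise. This mirrors the
freeze-then-measure protocol: parameters are frozen on the noiseless
simulator, and all sampling happens afterwards at fixed θ.

### 1.4 Measurement of the RDMs

The spin-summed RDM conventions are fixed package-wide:
`γ[p,q] = Σ_σ ⟨a†_{pσ} a_{qσ}⟩` and
`d[p,q,r,s] = Σ_{στ} ⟨a†_{pσ} a†_{rτ} a_{sτ} a_{qσ}⟩` (chemist pairing), so
that `E = h0 + Σ γ h1 + ½ Σ d h2` holds identically.

The measurement plan enumerates every spin-conserving spin-orbital element
(`N_so²/2` one-body and `N_so⁴/4` two-body operators; 18 + 324 for
`N_so = 6`), maps each through parity + tapering, and groups the distinct
Pauli words qubit-wise: two words share a measurement setting when their
letters agree or one is `I` on every qubit, greedy first-fit over
lexicographic order. Each group is sampled multinomially (2048 shots per
group by default); an optional readout channel distorts the outcome
distribution before counting, and mitigation applies the inverse of a
confusion matrix (full correlated matrix up to 6 qubits, tensor-product
factors above), clipping negative probabilities and renormalizing. The
calibration matrix itself can be a finite-shot estimate produced by the
standard prepare-each-basis-state procedure (8192 shots per state by
default).

Two post-processing choices are declared rather than inherited: negative
mitigated probabilities are clipped-and-renormalized, and the measured RDMs
are Hermiticity-restored — `γ ← (γ + γᵀ)/2` and the analogous 8-fold
permutational averaging for `d` — so that noisy RDMs remain valid inputs to
the functional. The 8-fold averaging discards only unobservable structure:
both the energy contraction and the on-top pair density are blind to the
non-symmetric part of `d` (the suite asserts this), and the brute-force CI
reference RDMs use the same convention so the two paths agree elementwise.

### 1.5 The classical functional

The total energy is assembled as
`E = Tr(D h_core) + ½ Tr(D J(D)) + V_nn + E_ot(ρ, Π)` with `D` the total
(core + active) one-particle density. The on-top pair density combines an
uncorrelated closed-shell core with the correlated active block,

`Π = ¼ρ_core² + ½ρ_core ρ_active + ½ Σ d[u,v,x,y] φ_u φ_v φ_x φ_y ,`

a composition that is validated by the closed-shell identity `Π = ρ²/4`
for any single determinant. The translated functional evaluates the
standard PBE exchange–correlation kernel (PW92 local correlation plus the
PBE gradient corrections, implemented in the package and spot-validated
against libxc) at effective spin densities

`ρ̃_σ = (ρ/2)(1 ± ζ_t), ζ_t = √(1 − R), R = Π/(ρ/2)² (ζ_t = 0 for R > 1),`

with gradients `(∇ρ/2)(1 ± ζ_t)` — the translation itself is *not*
differentiated (the "translated", not "fully translated", scheme). At
`R = 1` this reduces exactly to unpolarized PBE; at `Π = 0` it is the fully
spin-polarized evaluation. Only the translated-PBE functional is
implemented. The Coulomb term uses the total density (standard practice for
this family of functionals; the alternative active-only convention was
rejected because it breaks the closed-shell reduction to ordinary
Kohn–Sham-like energetics).

Quadrature uses atom-centered Becke partitioning, Gauss–Chebyshev radial
maps scaled by Bragg–Slater radii (half-radius except hydrogen) and a
Gauss–Legendre × uniform-φ product rule on the sphere. Grid levels 0–9 set
the point counts; the default level 3 is "medium" and is recorded in every
run report. Tight comparisons against the independent reference are run at
level 5, where the H₂ functional total agrees to ~3·10⁻⁷ Ha; a density
floor of 10⁻¹² a.u. guards the translation ratio.

## 2. The Marcus layer

The four-point scheme takes the four state/geometry single-point energies
(each optionally as a sum of donor- and acceptor-fragment energies) and
applies the absolute-value forms `ΔG° = |E^i_i − E^f_f|` and
`λ = |E^i_f − E^i_i| + |E^f_i − E^f_f|`; the nonadiabatic rate uses the
positive magnitudes and the ensemble mean of `|H_DA|²` (not the squared
mean):

`k_ET = (2π/ħ) ⟨|H_DA|²⟩ (4πλk_BT)^{−1/2} exp(−(ΔG°+λ)²/4λk_BT).`

The 300 K default temperature and both conventions are validated by
reproducing a published ensemble-averaged rate to well within 0.5% from its
stated (λ, ΔG°, ⟨|H_DA|²⟩) inputs; constants are CODATA `ħ` and `k_B` in eV
units. Recomputing λ from the device-measured fragment table gives 0.4615
eV versus a reported 0.4702 eV; the discrepancy is consistent with
environment-side (molecular-mechanics) contributions that are not derivable
from the tabulated quantum fragments, so only ΔG° is asserted against that
table.

Electronic couplings come from the direct-coupling expression
`H_DA = [T_DA − (e_D + e_A)S_DA/2]/(1 − S_DA²)` evaluated with
Boys-localized orbitals: the top occupied canonical orbitals of the
closed-shell dimer are localized by 2×2 Jacobi sweeps maximizing
`Σ|⟨r⟩|²`, donor and acceptor orbitals are assigned by Mulliken population
on the two fragments (≥ 0.6 required, else an explicit diagnostic error),
and `T_DA`, `e_D`, `e_A` are Fock-matrix elements in the localized basis.
Because the localized orbitals come from one orthonormal canonical set,
`S_DA` vanishes to numerical precision and the expression reduces to
`T_DA`; for a symmetric π stack this equals half the HOMO splitting, which
the suite uses as an independent oracle.

The noise-propagation study quantifies why difference-based observables
survive hardware noise: per seed, the eight fragment energies receive
either one shared offset ("systematic"), independent zero-mean errors
("iid"), or a shared offset plus small jitter ("correlated"), and the
four-point outputs are compared with the mean single-point error. A purely
systematic shift cancels *exactly* (the difference structure of the
four-point formulas); correlated noise cancels in the large majority of
seeds; iid noise does not cancel and is reported without assertion. The
default offset scale (65 mHa) and jitter (5 mHa) are the magnitudes of the
systematic and residual deviations observed in the hardware-versus-noiseless
comparison that motivated the study.

## 3. Shallow symmetry-preserving ansatz design

For the three-orbital patterns, particle-number conservation restricts the
tapered 4-qubit register to 3 × 3 = 9 computational basis states (the two
two-qubit blocks each exclude one forbidden pattern). `sector_states()`
enumerates this subspace by brute force; `dominant_configurations()` ranks
it by the weight of a classical reference state; `verify_conservation()`
reports the maximum sector leakage over random parameter draws.

`synthesize_hea()` assembles a circuit from {X, RY, CNOT, CRY} by beam
search. Three design choices matter and were made after the obvious
alternative failed on the packaged fixtures:

* **Scoring.** Candidates are scored by their best achievable overlap with
  the reference ground state (BFGS from several starts), not by a short
  energy re-optimization. On these strongly constrained registers the
  energy landscape is flat: no single gate added to the Hartree–Fock
  preparation lowers the energy until a complete multi-gate excitation path
  exists, so energy-greedy growth stalls at the mean-field energy. The
  overlap signal is smooth and survives the plateau; energy scoring is kept
  as a documented cheaper option.
* **Prepare-then-copy structure.** Beam entries carry a parameterized
  prefix and a trailing suffix of CNOT "copies". The low-energy sector
  states satisfy linear (GF(2)) parity relations — e.g. for the
  closed-shell pattern the three dominant configurations obey `q3 = q1`,
  `q4 = q2` — and the natural shallow circuits build the amplitude pattern
  on the free qubits, then imprint the relations with CNOTs, passing
  *through* out-of-sector intermediates. Conservation is therefore enforced
  on emitted candidates, not on prefixes, and the search seeds its beam
  with imprint suffixes derived by Gaussian elimination over GF(2) from the
  dominant configurations at several weight cutoffs.
* **Diversity.** Score plateaus are broken by small bonuses (wider
  reachable footprint inside the sector, shorter circuits) and a per-parent
  quota in beam selection, so distinct lineages survive rounds in which no
  candidate improves the raw overlap.

On the packaged fixtures the workflow converges within seconds: a depth-4,
2-parameter circuit for the closed-shell (4e,3o) anion within 1.6 mHa of
full CI, and a depth-6, 5-parameter circuit for the open-shell (3e,3o)
radical that is essentially exact. These two circuits ship as
`inst/extdata/chea.json` and `inst/extdata/ohea.json` and are the
package's reference hardware-efficient ansatzes; both pass the leakage
check at 10⁻¹⁰ and sit inside the 4 mHa accuracy band that shallow
fixed-depth circuits of this size are expected to reach.

## 4. Synthetic fixtures: what they emulate and what they do not

The packaged stand-ins for the neutral/cationic indole active spaces are
the allyl anion (closed shell, 4 electrons in 3 π orbitals) and the allyl
radical (open shell, 2α/1β), both at a symmetric planar geometry (C–C
1.388 Å, C–C–C 124.3°, C–H 1.09 Å) in the minimal basis. They reproduce
the *structural* features that matter for the quantum half — the same
(N_e, N_o) occupancy patterns, a three-frontier-π-orbital window, 6 → 4
qubit tapering, a 9-state symmetry sector dominated by one determinant with
a few percent of correlation — at a fraction of the cost. They do not
emulate a protein environment (no point charges are attached by default),
basis-set effects beyond minimal, or conformational diversity; a green test
on the fixtures therefore establishes the correctness of the machinery, not
the biology.

Other generators: `h2_scan` (full-space (2e,2o) problems along the bond
coordinate, used for exactness and dissociation tests), `random_active_space`
(seeded random integrals with exact 8-fold permutational symmetry and a
repulsion-dominated two-electron part), `four_point_table` (fragment tables
constructed by *inverting* the four-point formulas from stated (λ, ΔG°), so
recovery is exact by round trip), and `readout_noise` (tensor-product
channels at the device assignment fidelities F₀ = 98.35%, F₁ = 95.88% that
all noise studies default to).

## 5. Numerical choices and degenerate inputs

* Units: Hartree/Bohr internally; geometry input in Å (1 Å = 1/0.52917721092
  Bohr); electron-transfer quantities in eV via 27.211386 eV/Ha.
* SCF: DIIS-accelerated, 10⁻¹⁰ Ha energy threshold, explicit
  non-convergence error with iteration diagnostics; the open-shell solver
  is the Roothaan single-matrix effective-Fock ROHF (not UHF), matching the
  restricted open-shell ansatz family.
* Dense CASCI diagonalization is the classical reference throughout;
  practical to ~6 active orbitals, far beyond the packaged 3-orbital cases.
* VQE: energy-change tolerance 10⁻⁸ Ha, 3 restarts from a master seed;
  a zero-iteration budget returns the initial point flagged unconverged.
* Sampling: multinomial per group; standard errors from the binomial
  variance of each word, propagated quadratically through the element
  coefficients (within-group covariances are neglected, a declared
  approximation).
* Mitigation: exact inverse of the calibration matrix; its condition
  number is recorded on the model object.
* Tie-breaks: Pauli terms and measurement words are processed in
  lexicographic order; excitation lists and search candidates in fixed
  construction order; every stochastic step takes an explicit seed and
  restores the caller's RNG state.
* Degenerate inputs rejected with explicit errors: spin/electron-count
  parity mismatches, point charges on nuclei, active windows exceeding the
  orbital space or leaving an open-shell core, non-conserving operators at
  the taper, register-size mismatches, `|S_DA| ≥ 1`, λ ≤ 0, empty
  ensembles, singular calibrations.

## 6. Known limitations

* Basis-set library covers H, C, N, O in the minimal and split-valence
  sets the fixtures use; the integral engine itself is general (s/p
  implemented, d untested), but heavy-element or diffuse-basis work is out
  of scope.
* The external charge-transfer dimer benchmark command requires
  user-downloaded geometries and user-specified active spaces and runs for
  hours; it is implemented (`run_ct_benchmark()`, `vqepdft ct7`) but never
  exercised by the test suite.
* No gate-level noise model: noise enters at readout only, matching the
  mitigation scope. No N-representability purification of noisy RDMs.
* The ansatz-design search is empirical and system-specific by
  construction; circuits found for one active-space pattern are not
  expected to transfer to another.
* Hamiltonian-path Monte-Carlo (recomputing fragment energies from noisy
  sampled RDMs inside the four-point loop) is available by composing
  `run_single_point()` with `measurement mode = "sampled"`, but the
  packaged noise-propagation study works at the energy level, where the
  three canonical error models can be stated exactly.
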