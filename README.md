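# vqepdft

A quantum–classical hybrid electronic-structure toolkit in R, for the kind of
strongly correlated, compact active spaces that arise in biological
electron transfer (e.g. the three frontier π orbitals of a tryptophan indole
ring alternating between neutral and cationic states).

The division of labour is the one used by hybrid quantum/pair-density
functional schemes:

* a **simulated quantum circuit** solves the CASCI active-space Hamiltonian
  variationally (VQE) — the circuit only has to represent *static*
  correlation inside a small (N_e, N_o) window;
* the frozen-parameter circuit is **measured** — exactly, or by simulated
  shot sampling of qubit-wise-commuting Pauli groups with a readout-error
  channel and confusion-matrix mitigation — yielding the one- and
  two-particle reduced density matrices γ and Γ, the sole interface between
  the quantum and classical halves;
* the **total energy is assembled classically** from the RDMs with a
  translated-PBE on-top pair-density functional,

  E = T + V_ne + V_nn + V_ee(ρ) + E_ot(ρ, Π),

  where the on-top pair density Π(r) (from Γ) replaces the spin polarization
  as the descriptor of electron pairing, recovering *dynamic* correlation at
  DFT cost;
* a **Marcus layer** turns four-point energy tables into reorganization
  energies λ and driving forces ΔG° (ΔG° = |E^i_i − E^f_f|,
  λ = |E^i_f − E^i_i| + |E^f_i − E^f_f|), Boys-localized direct couplings
  H_DA = [T_DA − (e_D + e_A)S_DA/2]/(1 − S_DA²), and nonadiabatic rates
  k_ET = (2π/ħ)⟨|H_DA|²⟩(4πλk_BT)^(−1/2) exp(−(ΔG°+λ)²/4λk_BT),
  with ensemble averaging and a Monte-Carlo study of how correlated
  single-point errors cancel in the energy differences.

Everything below the functional — Gaussian integrals (McMurchie–Davidson,
compiled), RHF/ROHF, CASCI, parity fermion-to-qubit mapping with two-qubit
symmetry tapering, the statevector engine, UCCSD/ROUCCSD, Becke grids and
the PBE kernel — is implemented in the package. A design workflow
(`synthesize_hea()`) builds shallow particle-conserving hardware-efficient
circuits from {X, RY, CNOT, CRY} by symmetry-guided beam search; the two
reference circuits it produced on the packaged allyl π fixtures (depth 4
with 2 parameters for the closed-shell (4e,3o) pattern, depth 6 with 5
parameters for the open-shell (3e,3o) pattern) ship as circuit JSON.

## Worked example

A single-point hybrid calculation on H₂ (0.74 Å, minimal basis, full (2e,2o)
active space):

```r
library(vqepdft)
writeLines(c("2", "hydrogen molecule", "H 0 0 0", "H 0 0 0.74"), "h2.xyz")
cfg <- load_run_config(list(
  geometry = "h2.xyz", basis = "sto-3g",
  active_space = list(n_electrons = 2, n_orbitals = 2),
  ansatz = "uccsd", grid_level = 5, seed = 1))
res <- run_single_point(cfg)
res$energy
#> <energy_breakdown> (Hartree)
#>   T + Vne :    -2.4869049725
#>   Vnn     :     0.7151043391
#>   Vee     :     1.3489667219
#>   E_ot    :    -0.7337943245
#>   total   :    -1.1566282360
```

The mean field converges to −1.11675931 Ha and the circuit solver reaches
the exact CASCI ground state, −1.13728383 Ha (UCCSD is exact for two
electrons). The functional total −1.15662824 Ha agrees with an independent
pair-density-functional implementation to ~3·10⁻⁷ Ha; the E_ot term is what
adds dynamic correlation on top of the CASCI-level reference.

The Marcus layer, with ensemble-averaged parameters λ = 0.4356 eV,
ΔG° = 0.0724 eV and ⟨|H_DA|²⟩ = 1.1431·10⁻⁴ eV² at 300 K:

```r
marcus_rate(lambda = 0.4356, dG = 0.0724, mean_sq_coupling = 1.1431e-4)
#> [1] 9.427e+09     # s^-1
```

a transfer on the 100 ps scale, as measured for adjacent tryptophan
residues in a cryptochrome photoreceptor.

The packaged closed-shell reference circuit:

```r
reference_hea("chea")
#> <pdft_circuit> 4 qubits, 5 gates, 2 parameters, depth 4
```

## Command line

```
vqepdft energy     --config run.yaml --out outdir
vqepdft marcus     --table fourpoint.txt [--couplings c.csv] [--out dir]
vqepdft design-hea --problem problem.h5 --depth 4 --params 2
vqepdft fixtures   --kind allyl_radical --out problem.h5
vqepdft ct7        --config systems.yaml       # external benchmark inputs
```

(`exec/vqepdft` is installed with the package; equivalently call
`vqepdft_main(c("marcus", "--table", "fourpoint.txt"))` from R.)

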