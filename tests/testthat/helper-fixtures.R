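# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

h2_geometry <- function(d = 0.74)
  geometry(c("H", "H"), matrix(c(0, 0, 0, 0, 0, d), ncol = 3, byrow = TRUE))

h2_problem <- function() cached("h2_problem", {
  extract_active_space(run_mean_field(h2_geometry(), "sto-3g"),
                       active_space_spec(2, 2))
})

allyl_anion_problem <- function() cached("allyl_anion", {
  generate_fixtures("allyl_anion")
})

allyl_radical_problem <- function() cached("allyl_radical", {
  generate_fixtures("allyl_radical")
})

anion_hamiltonian <- function() cached("anion_H", {
  p <- allyl_anion_problem()
  taper(parity_map(p), symmetry_sector(p$spec))
})

radical_hamiltonian <- function() cached("radical_H", {
  p <- allyl_radical_problem()
  taper(parity_map(p), symmetry_sector(p$spec))
})

radical_plan <- function() cached("radical_plan", {
  measurement_plan(allyl_radical_problem())
})

radical_vqe <- function() cached("radical_vqe", {
  p <- allyl_radical_problem()
  circ <- build_rouccsd(p)
  res <- vqe_minimize(radical_hamiltonian(), circ, seed = 7)
  list(circ = circ, res = res, psi = apply_circuit(circ, res$theta))
})

# exact ground state of a problem prepared directly on the tapered register
exact_tapered_state <- function(problem) {
  ex <- casci_solve(problem, 1)
  n <- 2L * problem$spec$n_orbitals - 2L
  psi <- complex(2^n)
  tap <- vapply(ex$dets, vqepdft:::det_to_tapered, integer(1),
                n_orb = problem$spec$n_orbitals)
  psi[tap + 1] <- ex$vectors[, 1]
  list(psi = psi, energy = ex$energies[1], vec = ex$vectors[, 1],
       dets = ex$dets)
}
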