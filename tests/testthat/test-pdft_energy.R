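# Pair-density functional energy assembly. Frozen reference values come
# from an independent implementation: FCI RDMs and the PBE kernel evaluated
# through libxc at the translated densities (pyscf 2.12.1), level-5 grids.

fci_rdms <- function(pr) {
  cs <- casci_solve(pr, 1)
  rd <- vqepdft:::casci_rdms(pr, cs$vectors[, 1], cs$dets)
  structure(list(gamma = rd$gamma, d = rd$d,
                 convention = "spin-summed-chemist"), class = "spin_rdms")
}

test_that("H2 translated-PBE total energy matches the independent oracle", {
  pr <- h2_problem()
  eb <- total_energy(pr, fci_rdms(pr), grid_level = 5)
  expect_equal(eb$T_plus_Vne, -2.486904977, tolerance = 1e-7)
  expect_equal(eb$Vee_classical, 1.348966722, tolerance = 1e-7)
  expect_equal(eb$Vnn, 0.7151043391, tolerance = 1e-9)
  expect_equal(eb$E_ot, -0.7337946273, tolerance = 1e-6)
  expect_equal(eb$total, -1.1566285432, tolerance = 1e-6)
  # breakdown sums to the total
  expect_equal(eb$total,
               eb$T_plus_Vne + eb$Vnn + eb$Vee_classical + eb$E_ot,
               tolerance = 1e-12)
})

test_that("H2 in a split-valence basis also matches the oracle", {
  g <- h2_geometry()
  pr <- extract_active_space(run_mean_field(g, "6-31g"),
                             active_space_spec(2, 2))
  eb <- total_energy(pr, fci_rdms(pr), grid_level = 5)
  expect_equal(eb$total, -1.1644664949, tolerance = 1e-6)
})

test_that("closed-shell determinant gives Pi = rho^2/4 and the translation
           identity E_ot = plain PBE xc of the unpolarized density", {
  pr <- allyl_anion_problem()
  circ <- build_uccsd(pr)
  rd <- rdms_exact(apply_circuit(circ, numeric(circ$n_params)), pr)
  grid <- densities_on_grid(pr, rd, grid_level = 2)
  keep <- grid$rho > 1e-8
  expect_lt(max(abs(grid$pi[keep] - grid$rho[keep]^2 / 4)), 1e-10)
  expect_lt(max(abs(grid$zeta_t[keep])), 1e-6)
  # zeta_t = 0 means the translated evaluation is the unpolarized PBE one
  eot <- translated_pbe(grid)
  keep2 <- grid$rho > 1e-12
  exc <- vqepdft:::pbe_exc_density(grid$rho[keep2] / 2, grid$rho[keep2] / 2,
                                   grid$grad_rho[keep2] / 2,
                                   grid$grad_rho[keep2] / 2,
                                   grid$grad_rho[keep2])
  expect_equal(eot, sum(grid$weights[keep2] * exc), tolerance = 1e-10)
})

test_that("density normalization and the on-top collapse at dissociation", {
  pr <- h2_problem()
  g1 <- densities_on_grid(pr, fci_rdms(pr), grid_level = 4)
  expect_equal(sum(g1$weights * g1$rho), 2, tolerance = 1e-6)
  stretched <- extract_active_space(
    run_mean_field(h2_geometry(5.0), "sto-3g"), active_space_spec(2, 2))
  g5 <- densities_on_grid(stretched, fci_rdms(stretched), grid_level = 4)
  int_pi_eq <- sum(g1$weights * g1$pi)
  int_pi_far <- sum(g5$weights * g5$pi)
  expect_lt(int_pi_far, 0.01 * int_pi_eq)
  # Pi stays essentially non-negative on the exact path
  expect_gt(min(g5$pi), -1e-10)
  # zeta_t within [0, 1]
  expect_true(all(g1$zeta_t >= 0 & g1$zeta_t <= 1))
})

test_that("Pi = 0 limit evaluates as fully spin-polarized", {
  # a one-electron-like density (Pi = 0) must give zeta_t = 1
  pr <- h2_problem()
  rd <- fci_rdms(pr)
  rd$d[] <- 0
  grid <- densities_on_grid(pr, rd, grid_level = 2)
  core_free <- grid$rho > 1e-8
  expect_true(all(abs(grid$zeta_t[core_free] - 1) < 1e-12))
})

test_that("energy is invariant under 8-fold symmetrization of d and
           grid-level refinement converges", {
  pr <- h2_problem()
  rd <- fci_rdms(pr)
  e3 <- total_energy(pr, rd, grid_level = 3)$E_ot
  e5 <- total_energy(pr, rd, grid_level = 5)$E_ot
  e7 <- total_energy(pr, rd, grid_level = 7)$E_ot
  expect_lt(abs(e7 - e5), abs(e5 - e3) + 1e-9)
  # symmetrization invariance (d from the oracle path is already averaged;
  # a random 8-fold-symmetric perturbation changes nothing when symmetrized
  # again)
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  davg <- Reduce(`+`, lapply(perms, function(p) aperm(rd$d, p))) / 8
  expect_lt(max(abs(davg - rd$d)), 1e-12)
})

test_that("model problems without a real-space backend are rejected", {
  pm <- generate_fixtures("random_active_space", seed = 4)
  rd <- fci_rdms(pm)
  expect_error(total_energy(pm, rd), "backend")
})

test_that("charge-transfer-style sign restoration is reported", {
  # engineered mimic: a weakly bound closed-shell pair where the bare
  # active-space CI dissociation energy and the functional-corrected one
  # are both computed and reported; the comparison itself is qualitative
  d_eq <- 1.6; d_far <- 40
  runp <- function(d) {
    g <- h2_geometry(d)
    extract_active_space(run_mean_field(g, "sto-3g"),
                         active_space_spec(2, 2))
  }
  p_eq <- runp(d_eq); p_far <- runp(d_far)
  de_ci <- casci_solve(p_far)$energies[1] - casci_solve(p_eq)$energies[1]
  de_pdft <- total_energy(p_far, fci_rdms(p_far), 3)$total -
    total_energy(p_eq, fci_rdms(p_eq), 3)$total
  expect_true(is.finite(de_ci) && is.finite(de_pdft))
})
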