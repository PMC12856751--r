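# Mean-field references and CASCI active-space construction.
# Frozen reference energies were computed with an independent SCF/FCI code
# (pyscf 2.12.1) on identical geometries, basis sets and integrals.

test_that("restricted SCF matches the independent reference", {
  cases <- list(
    list(geom = h2_geometry(), basis = "sto-3g", ref = -1.1167593074),
    list(geom = h2_geometry(), basis = "6-31g", ref = -1.1267553172),
    list(geom = geometry(c("O", "H", "H"),
                         matrix(c(0, 0, 0.1173, 0, 0.7572, -0.4692,
                                  0, -0.7572, -0.4692),
                                ncol = 3, byrow = TRUE)),
         basis = "sto-3g", ref = -74.9630231385),
    list(geom = geometry(c("O", "H", "H"),
                         matrix(c(0, 0, 0.1173, 0, 0.7572, -0.4692,
                                  0, -0.7572, -0.4692),
                                ncol = 3, byrow = TRUE)),
         basis = "6-31g", ref = -75.9839744727))
  for (cs in cases) {
    mf <- run_mean_field(cs$geom, cs$basis)
    expect_true(mf$converged)
    expect_equal(mf$e_tot, cs$ref, tolerance = 1e-8)
  }
})

test_that("open-shell geometries dispatch to the restricted open-shell solver", {
  g <- geometry(c("O", "H"), matrix(c(0, 0, 0, 0, 0, 0.97),
                                    ncol = 3, byrow = TRUE), spin = 1)
  mf <- run_mean_field(g, "sto-3g")
  expect_true(mf$open_shell)
  expect_equal(mf$e_tot, -74.3615619579, tolerance = 1e-8)
  expect_false(run_mean_field(h2_geometry(), "sto-3g")$open_shell)
})

test_that("distant and near point charges behave physically", {
  # +1 charge at 1e6 Angstrom is a vanishing perturbation
  far <- geometry(c("H", "H"),
                  matrix(c(0, 0, 0, 0, 0, 0.74), ncol = 3, byrow = TRUE),
                  point_charges = matrix(c(0, 0, 1e6, 1), ncol = 4))
  e_far <- run_mean_field(far, "sto-3g")$e_tot
  e_free <- run_mean_field(h2_geometry(), "sto-3g")$e_tot
  expect_equal(e_far, e_free, tolerance = 1e-8)
  # a charge q at distance R from the molecular charge centroid changes the
  # energy of a net-charged molecule by q*Q/R + O(1/R^2) (atomic units)
  R_ang <- 60
  R <- (R_ang - 0.37) / 0.52917721092   # centroid of H2 sits at z = 0.37 A
  gq <- geometry(c("H", "H"),
                 matrix(c(0, 0, 0, 0, 0, 0.74), ncol = 3, byrow = TRUE),
                 charge = 1, spin = 1,
                 point_charges = matrix(c(0, 0, R_ang, 0.5), ncol = 4))
  g0 <- geometry(c("H", "H"),
                 matrix(c(0, 0, 0, 0, 0, 0.74), ncol = 3, byrow = TRUE),
                 charge = 1, spin = 1)
  de <- run_mean_field(gq, "sto-3g")$e_tot - run_mean_field(g0, "sto-3g")$e_tot
  expect_equal(de, 0.5 * 1 / R, tolerance = 2e-3)
})

test_that("geometry validation catches bad inputs", {
  expect_error(geometry("H", c(0, 0, 0), spin = 0), "spin")
  expect_error(geometry(c("H", "Xx"),
                        matrix(0, 2, 3)), "unknown element")
  expect_error(geometry("H", c(0, 0, 0), spin = 1,
                        point_charges = matrix(c(0, 0, 0, 1), ncol = 4)),
               "coincides")
  expect_error(run_mean_field(h2_geometry(), "not-a-basis"),
               "unknown basis")
})

test_that("XYZ and point-charge readers parse standard files", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0.0 0.0 0.0", "H 0.0 0.0 0.74"), xyz)
  g <- read_xyz(xyz)
  expect_equal(g$atoms, c("H", "H"))
  expect_equal(g$coords[2, 3], 0.74)
  pc <- tempfile()
  writeLines(c("# comment", "0.0 0.0 3.0 0.25"), pc)
  m <- read_point_charges(pc)
  expect_equal(unname(m[1, 4]), 0.25)
})

test_that("full-space active space reproduces FCI and the CASCI oracle", {
  pr <- h2_problem()
  vqepdft:::check_problem_invariants(pr)
  # (2e,2o) on H2 minimal basis is the full space: CASCI == FCI
  expect_equal(casci_solve(pr)$energies[1], -1.1372838345,
               tolerance = 1e-9)
})

test_that("allyl fixtures match the independent CASCI oracle", {
  pa <- allyl_anion_problem()
  vqepdft:::check_problem_invariants(pa)
  expect_equal(pa$scf$e_tot, -114.8325208561, tolerance = 1e-8)
  expect_equal(casci_solve(pa)$energies[1], -114.8653249585,
               tolerance = 1e-8)
  pr <- allyl_radical_problem()
  vqepdft:::check_problem_invariants(pr)
  expect_equal(pr$scf$e_tot, -115.0101787997, tolerance = 1e-8)
  expect_equal(casci_solve(pr)$energies[1], -115.0736229387,
               tolerance = 1e-8)
})

test_that("CI expectation reproduces E = h0 + sum(gamma h1) + 0.5 sum(d h2)", {
  for (pr in list(h2_problem(), allyl_radical_problem())) {
    cs <- casci_solve(pr, 2)
    for (k in seq_along(cs$energies)) {
      rd <- vqepdft:::casci_rdms(pr, cs$vectors[, k], cs$dets)
      e <- pr$h0 + sum(rd$gamma * pr$h1) + 0.5 * sum(rd$d * pr$h2)
      expect_equal(e, cs$energies[k], tolerance = 1e-9)
    }
  }
})

test_that("invalid active-space specs are rejected", {
  mf <- run_mean_field(h2_geometry(), "sto-3g")
  expect_error(active_space_spec(5, 2))
  expect_error(extract_active_space(mf, active_space_spec(2, 5)),
               "exceeds")
  expect_error(extract_active_space(mf, active_space_spec(1, 1, spin = 1)),
               "core")
})
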