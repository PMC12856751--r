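# Configuration, fixtures, serialization, and end-to-end workflows.

test_that("fixture generation is deterministic under a fixed seed", {
  a <- generate_fixtures("random_active_space", seed = 7)
  b <- generate_fixtures("random_active_space", seed = 7)
  expect_identical(a$h1, b$h1)
  expect_identical(a$h2, b$h2)
  c2 <- generate_fixtures("random_active_space", seed = 8)
  expect_false(identical(a$h1, c2$h1))
  vqepdft:::check_problem_invariants(a)
  open_p <- generate_fixtures("random_active_space", seed = 7,
                              pattern = "open")
  expect_identical(open_p$spec$n_alpha, 2L)
  expect_identical(open_p$spec$n_beta, 1L)
  expect_error(generate_fixtures("nonsense"), "unknown fixture")
})

test_that("four-point table fixture inverts to its stated parameters", {
  tab <- generate_fixtures("four_point_table", seed = 11)
  fp <- four_point(four_point_from_fragments(tab))
  expect_equal(fp$lambda, attr(tab, "lambda"), tolerance = 1e-10)
  expect_equal(fp$dG, attr(tab, "dG"), tolerance = 1e-10)
})

test_that("problem and RDM HDF5 round trips preserve the data", {
  pr <- allyl_radical_problem()
  tmp <- tempfile(fileext = ".h5")
  problem_to_hdf5(pr, tmp)
  p2 <- problem_from_hdf5(tmp)
  expect_equal(p2$h0, pr$h0, tolerance = 1e-12)
  expect_equal(p2$h1, pr$h1, tolerance = 1e-12)
  expect_equal(p2$h2, pr$h2, tolerance = 1e-12)
  expect_identical(p2$spec$n_alpha, pr$spec$n_alpha)
  ex <- exact_tapered_state(pr)
  rd <- rdms_exact(ex$psi, pr, plan = radical_plan())
  tmp2 <- tempfile(fileext = ".h5")
  rdms_to_hdf5(rd, tmp2)
  r2 <- rdms_from_hdf5(tmp2)
  expect_equal(r2$gamma, rd$gamma, tolerance = 1e-12)
  expect_equal(r2$d, rd$d, tolerance = 1e-12)
})

test_that("single-point pipeline reproduces the frozen functional oracle", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "h2", "H 0 0 0", "H 0 0 0.74"), xyz)
  cfg <- load_run_config(list(
    geometry = xyz, basis = "sto-3g",
    active_space = list(n_electrons = 2, n_orbitals = 2),
    ansatz = "uccsd", grid_level = 5, seed = 1,
    output_dir = tempfile("run")))
  res <- run_single_point(cfg)
  expect_equal(res$energy$total, -1.1566285432, tolerance = 1e-6)
  expect_equal(res$casci_energy, -1.1372838345, tolerance = 1e-7)
  # artifacts and resolved config are persisted
  expect_true(file.exists(file.path(cfg$output_dir, "report.json")))
  expect_true(file.exists(file.path(cfg$output_dir, "circuit.json")))
  expect_true(file.exists(file.path(cfg$output_dir,
                                    "resolved_config.yaml")))
  rep <- jsonlite::fromJSON(file.path(cfg$output_dir, "report.json"))
  expect_equal(rep$energy$total, res$energy$total, tolerance = 1e-12)
})

test_that("exact-path pipeline is deterministic bit-for-bit", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "h2", "H 0 0 0", "H 0 0 0.74"), xyz)
  cfg <- list(geometry = xyz, basis = "sto-3g",
              active_space = list(n_electrons = 2, n_orbitals = 2),
              ansatz = "uccsd", grid_level = 2, seed = 3)
  r1 <- run_single_point(load_run_config(cfg))
  r2 <- run_single_point(load_run_config(cfg))
  expect_identical(r1$energy$total, r2$energy$total)
  expect_identical(r1$vqe$theta, r2$vqe$theta)
})

test_that("sampled-path total stays within a few combined standard errors", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "h2", "H 0 0 0", "H 0 0 0.74"), xyz)
  base <- list(geometry = xyz, basis = "sto-3g",
               active_space = list(n_electrons = 2, n_orbitals = 2),
               ansatz = "uccsd", grid_level = 3, seed = 5)
  exact <- run_single_point(load_run_config(base))
  samp_cfg <- utils::modifyList(base, list(
    measurement = list(mode = "sampled", shots = 2048)))
  samp <- run_single_point(load_run_config(samp_cfg))
  # functional total from 2048-shot RDMs: loose statistical envelope
  expect_lt(abs(samp$energy$total - exact$energy$total), 0.05)
  expect_gt(max(samp$rdms$gamma_se), 0)
})

test_that("open-shell pipeline with the reference OHEA hits the band", {
  pr <- allyl_radical_problem()
  H <- radical_hamiltonian()
  best <- Inf
  for (s in c(7, 77)) {
    r <- vqe_minimize(H, reference_hea("ohea"), seed = s, n_restarts = 3,
                      restart_spread = 2.5)
    best <- min(best, r$energy)
  }
  expect_lt(best - casci_solve(pr)$energies[1], 4e-3)
})

test_that("four-point ensemble workflow averages and reports", {
  t1 <- generate_fixtures("four_point_table", seed = 1)
  t2 <- generate_fixtures("four_point_table", seed = 2)
  t1$conformation <- 1; t2$conformation <- 2
  out <- tempfile("marcus")
  res <- run_four_point_ensemble(rbind(t1, t2),
                                 couplings = c(5e-3, 7e-3),
                                 output_dir = out)
  expect_equal(res$ensemble$lambda,
               mean(c(attr(t1, "lambda"), attr(t2, "lambda"))),
               tolerance = 1e-10)
  expect_equal(res$ensemble$H_DA_sq, mean(c(5e-3, 7e-3)^2))
  expect_true(file.exists(file.path(out, "marcus_ensemble.csv")))
  expect_true(file.exists(file.path(out, "marcus_report.json")))
  expect_identical(nrow(res$per_conformation), 2L)
})

test_that("four-point text tables parse and feed the CLI layer", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("# point fragment energy",
               "a donor -362.92966", "a acceptor -363.17866",
               "b donor -363.20554", "b acceptor -362.91475",
               "c donor -363.19954", "c acceptor -362.91126",
               "d donor -362.92451", "d acceptor -363.18130"), tf)
  tab <- read_four_point_table(tf)
  expect_identical(nrow(tab), 8L)
  fp <- four_point(four_point_from_fragments(tab))
  expect_lt(abs(fp$dG - 0.06764) / 0.06764, 0.003)
  out <- capture.output(vqepdft_main(c("marcus", "--table", tf)))
  expect_true(any(grepl("lambda", out)))
})
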