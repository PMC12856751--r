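# RDM extraction: exact path, sampled path with readout noise/mitigation.

test_that("measurement plan enumerates the declared element counts", {
  plan <- radical_plan()
  n_so <- 6
  expect_identical(plan$n_elements_1, as.integer(n_so^2 / 2))   # 18
  expect_identical(plan$n_elements_2, as.integer(n_so^4 / 4))   # 324
  expect_lte(length(plan$groups), length(plan$words))
  # every non-identity word appears in exactly one group
  expect_setequal(unlist(lapply(plan$groups, `[[`, "words")), plan$words)
  expect_error(measurement_plan(allyl_radical_problem(),
                                shots_per_group = 0), "positive")
})

test_that("exact RDMs match the CI-expansion brute-force oracle", {
  pr <- allyl_radical_problem()
  ex <- exact_tapered_state(pr)
  rd <- rdms_exact(ex$psi, pr, plan = radical_plan())
  oracle <- vqepdft:::casci_rdms(pr, ex$vec, ex$dets)
  expect_lt(max(abs(rd$gamma - oracle$gamma)), 1e-10)
  expect_lt(max(abs(rd$d - oracle$d)), 1e-10)
  # trace identities: Tr(gamma) = N, partial trace = (N-1) gamma
  expect_equal(sum(diag(rd$gamma)), 3, tolerance = 1e-8)
  pt <- apply(rd$d, c(1, 2), function(x) NA)
  for (p in 1:3) for (q in 1:3)
    pt[p, q] <- sum(vapply(1:3, function(r) rd$d[p, q, r, r], numeric(1)))
  expect_lt(max(abs(pt - 2 * rd$gamma)), 1e-8)
  ev <- eigen(rd$gamma, symmetric = TRUE)$values
  expect_true(all(ev > -1e-10 & ev < 2 + 1e-10))
  # energy contraction reproduces <H>
  expect_equal(vqepdft:::rdm_energy(pr, rd), ex$energy, tolerance = 1e-9)
})

test_that("the HF determinant gives integer occupations", {
  pr <- allyl_anion_problem()
  circ <- build_uccsd(pr)
  psi <- apply_circuit(circ, numeric(circ$n_params))
  rd <- rdms_exact(psi, pr)
  expect_equal(diag(rd$gamma), c(2, 2, 0), tolerance = 1e-10)
  expect_lt(max(abs(rd$gamma - diag(diag(rd$gamma)))), 1e-10)
})

test_that("sector leakage is detected", {
  pr <- allyl_radical_problem()
  psi <- complex(16)
  psi[1] <- 1  # |0000> is outside the (2,1) sector
  expect_error(rdms_exact(psi, pr), "leak")
})

test_that("infinite-shot sampling equals the exact path", {
  rv <- radical_vqe()
  plan <- radical_plan()
  pr <- allyl_radical_problem()
  rd_ex <- rdms_exact(rv$psi, pr, plan = plan)
  rd_inf <- rdms_sampled(rv$circ, rv$res$theta, plan, infinite_shots = TRUE)
  expect_lt(max(abs(rd_inf$gamma - rd_ex$gamma)), 1e-12)
  expect_lt(max(abs(rd_inf$d - rd_ex$d)), 1e-12)
})

test_that("sampled-RDM errors shrink as shots^(-1/2)", {
  rv <- radical_vqe()
  pr <- allyl_radical_problem()
  rd_ex <- rdms_exact(rv$psi, pr, plan = radical_plan())
  shots <- c(512, 2048, 8192)
  n_seeds <- 20
  mean_err <- vapply(shots, function(s) {
    plan <- measurement_plan(pr, shots_per_group = s)
    errs <- vapply(seq_len(n_seeds), function(k) {
      rd <- rdms_sampled(rv$circ, rv$res$theta, plan, seed = 1000 + k)
      sqrt(mean((rd$gamma - rd_ex$gamma)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  slope <- coef(lm(log(mean_err) ~ log(shots)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  # trace identities hold within 3 standard errors on the sampled path
  plan <- radical_plan()
  rd <- rdms_sampled(rv$circ, rv$res$theta, plan, seed = 9)
  tr_se <- sqrt(sum(diag(rd$gamma_se)^2))
  expect_lt(abs(sum(diag(rd$gamma)) - 3), 3 * tr_se + 1e-6)
})

test_that("mitigation identities hold", {
  ident <- calibration_model(3, f0 = 1, f1 = 1)
  p <- c(0.5, 0.2, 0.1, 0.05, 0.05, 0.04, 0.03, 0.03)
  expect_equal(mitigate(p, ident), p, tolerance = 1e-12)
  # a known flip channel applied to exact probabilities is undone exactly
  ch <- calibration_model(3, f0 = 0.97, f1 = 0.93)
  expect_equal(mitigate(as.numeric(ch$matrix %*% p), ch), p,
               tolerance = 1e-10)
  expect_error(mitigate(p[1:4], ch), "dimension")
})

test_that("readout channel built from the device fidelities is recovered by
           mitigation with the generating model", {
  rv <- radical_vqe()
  plan <- radical_plan()
  pr <- allyl_radical_problem()
  ch <- generate_fixtures("readout_noise")   # F0 = 98.35%, F1 = 95.88%
  rd_ex <- rdms_exact(rv$psi, pr, plan = plan)
  # infinite-shot: noise + own-model mitigation is an exact inverse
  rd_m <- rdms_sampled(rv$circ, rv$res$theta, plan, noise = ch,
                       calibration = ch, infinite_shots = TRUE)
  expect_lt(max(abs(rd_m$gamma - rd_ex$gamma)), 1e-10)
  # finite shots: mitigated energy is within a few standard errors while
  # the unmitigated energy carries a visible bias
  rd_raw <- rdms_sampled(rv$circ, rv$res$theta, plan, noise = ch,
                         seed = 4, infinite_shots = TRUE)
  expect_gt(max(abs(rd_raw$gamma - rd_ex$gamma)), 0.01)
})

test_that("mitigation beats raw readout in most seeded trials", {
  # Monte-Carlo in the actual measurement context: the frozen-parameter
  # circuit state, a random readout channel around the device fidelities,
  # and a diagonal (Z-basis) measurement word whose expectation carries the
  # dominant occupation signal.
  set.seed(31)
  n <- 4
  ch <- calibration_model(n, f0 = runif(n, 0.95, 0.99),
                          f1 = runif(n, 0.92, 0.97))
  psi <- radical_vqe()$psi
  p_true <- Mod(psi)^2
  z <- vqepdft:::word_eigenvalues("ZZZZ", n)
  truth <- sum(p_true * z)
  shots <- 2048
  wins <- vapply(1:200, function(k) {
    set.seed(5000 + k)
    noisy <- as.numeric(ch$matrix %*% p_true)
    cnt <- rmultinom(1, shots, noisy)[, 1] / shots
    e_raw <- sum(cnt * z)
    e_fix <- sum(mitigate(cnt, ch) * z)
    abs(e_fix - truth) <= abs(e_raw - truth)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("a finite-shot calibration estimate still mitigates well", {
  ch <- generate_fixtures("readout_noise")
  est <- simulate_calibration(ch, calibration_shots = 8192, seed = 12)
  expect_equal(est$kind, "correlated")
  expect_lt(max(abs(est$matrix - ch$matrix)), 0.02)
})
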