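# Parity mapping, symmetry tapering, Pauli algebra and measurement grouping.

test_that("parity-mapped number operator has the Fock-space spectrum", {
  fop <- fermion_op(list(
    list(coeff = 1, modes = c(1, 1), dagger = c(TRUE, FALSE)),
    list(coeff = 1, modes = c(2, 2), dagger = c(TRUE, FALSE))), 2)
  op <- parity_map(fop)
  ev <- sort(Re(eigen(vqepdft:::pauli_matrix(op))$values))
  expect_equal(ev, c(0, 1, 1, 2), tolerance = 1e-12)
})

test_that("identity fermionic operator maps to the identity word", {
  fop <- fermion_op(list(list(coeff = 2.5, modes = integer(0),
                              dagger = logical(0))), 4)
  op <- parity_map(fop)
  expect_equal(op$words, "IIII")
  expect_equal(op$coeffs, 2.5 + 0i)
})

test_that("three-orbital problems map to 6 qubits, 4 after tapering", {
  H <- parity_map(allyl_radical_problem())
  expect_identical(H$n_qubits, 6L)
  Ht <- taper(H, symmetry_sector(allyl_radical_problem()$spec))
  expect_identical(Ht$n_qubits, 4L)
})

test_that("mapped Hamiltonian spectrum equals the Fock-space spectrum", {
  pr <- h2_problem()
  Hq <- parity_map(pr)
  evq <- sort(Re(eigen(vqepdft:::pauli_matrix(Hq), symmetric = TRUE)$values))
  Hf <- as.matrix(vqepdft:::hamiltonian_fock(pr))
  evf <- sort(eigen(Hf, symmetric = TRUE)$values) + pr$h0
  expect_equal(evq, evf, tolerance = 1e-10)
})

test_that("tapering preserves the sector spectrum (dense-diagonalization check)", {
  for (pr in list(h2_problem(), allyl_radical_problem(),
                  allyl_anion_problem())) {
    spec <- pr$spec
    sector <- symmetry_sector(spec)
    Ht <- taper(parity_map(pr), sector)
    expect_identical(Ht$n_qubits, 2L * spec$n_orbitals - 2L)
    # restrict the tapered operator to the sector-allowed subspace and
    # compare with the Fock-space sector spectrum
    Hm <- Re(vqepdft:::pauli_matrix(Ht))
    allowed <- sector_states(spec) + 1
    evt <- sort(eigen(Hm[allowed, allowed], symmetric = TRUE)$values)
    idx <- vqepdft:::sector_fock_indices(spec$n_orbitals, spec$n_alpha,
                                         spec$n_beta)
    Hf <- as.matrix(vqepdft:::hamiltonian_fock(pr))[idx, idx]
    evf <- sort(eigen(Hf, symmetric = TRUE)$values) + pr$h0
    expect_equal(evt, evf, tolerance = 1e-9)
  }
})

test_that("tapering the identity and rejecting non-commuting operators", {
  sector <- symmetry_sector(n_alpha = 2, n_beta = 1, n_orbitals = 3)
  id6 <- vqepdft:::pauli_identity(6, 3.5)
  idt <- taper(id6, sector)
  expect_identical(idt$n_qubits, 4L)
  expect_equal(idt$words, "IIII")
  bad <- pauli_op("IIXIII", 1, 6)
  expect_error(taper(bad, sector), "does not commute")
})

test_that("mapping preserves the operator algebra (commutators)", {
  set.seed(11)
  n <- 4
  rand_fop <- function() {
    terms <- lapply(1:3, function(k) {
      m <- sample(n, 2)
      list(coeff = rnorm(1), modes = m, dagger = c(TRUE, FALSE))
    })
    fermion_op(terms, n)
  }
  for (rep in 1:5) {
    A <- rand_fop(); B <- rand_fop()
    MA <- vqepdft:::pauli_matrix(parity_map(A))
    MB <- vqepdft:::pauli_matrix(parity_map(B))
    # commutator computed on the mapped side
    comm_mapped <- MA %*% MB - MB %*% MA
    # commutator computed on the fermionic side via Jordan-Wigner matrices,
    # then conjugated into the parity basis by the basis permutation
    ad <- lapply(1:n, vqepdft:::creation_op, n = n)
    fmat <- function(fop) {
      M <- matrix(0, 2^n, 2^n)
      for (t in fop$terms) {
        term <- diag(2^n)
        for (k in seq_along(t$modes)) {
          op1 <- as.matrix(ad[[t$modes[k]]])
          term <- term %*% (if (t$dagger[k]) op1 else t(op1))
        }
        M <- M + t$coeff * term
      }
      M
    }
    P <- matrix(0, 2^n, 2^n)
    for (s in 0:(2^n - 1))
      P[vqepdft:::occ_to_parity(s, n) + 1, s + 1] <- 1
    commf <- fmat(A) %*% fmat(B) - fmat(B) %*% fmat(A)
    expect_lt(max(Mod(comm_mapped - P %*% commf %*% t(P))), 1e-10)
  }
})

test_that("qubit-wise grouping merges compatible words and covers all terms", {
  g <- group_qubitwise(c("ZZII", "IIZZ"))
  expect_length(g, 1)
  expect_equal(g[[1]]$basis, "ZZZZ")
  g2 <- group_qubitwise(c("XI", "ZI"))
  expect_length(g2, 2)
  set.seed(5)
  words <- unique(replicate(50, paste(sample(c("I", "X", "Y", "Z"), 4,
                                             replace = TRUE),
                                      collapse = "")))
  groups <- group_qubitwise(words)
  expect_lte(length(groups), length(words))
  expect_setequal(unlist(lapply(groups, `[[`, "words")), words)
  for (gr in groups)
    for (w in gr$words)
      expect_true(vqepdft:::qubitwise_compatible(gr$basis, w))
})

test_that("grouped measurement reproduces direct expectations exactly", {
  # infinite-shot path through the measurement machinery vs direct
  # statevector expectation, on random states and random words
  set.seed(17)
  n <- 4
  words <- unique(replicate(20, paste(sample(c("I", "X", "Y", "Z"), n,
                                             replace = TRUE),
                                      collapse = "")))
  words <- setdiff(words, strrep("I", n))
  groups <- group_qubitwise(words)
  for (rep in 1:3) {
    amp <- rnorm(2^n) + 1i * rnorm(2^n)
    psi <- amp / sqrt(sum(Mod(amp)^2))
    for (gr in groups) {
      phi <- vqepdft:::rotate_to_basis(psi, gr$basis, n)
      p <- Mod(phi)^2
      for (w in gr$words) {
        z <- vqepdft:::word_eigenvalues(w, n)
        direct <- expectation(pauli_op(w, 1, n), psi)
        expect_equal(sum(p * z), direct, tolerance = 1e-12)
      }
    }
  }
})

test_that("Pauli text serialization round-trips", {
  op <- pauli_op(c("ZZII", "XYZI", "IIII"), c(0.5, -0.25 + 0.1i, 1.5), 4)
  lines_txt <- pauli_to_text(op)
  op2 <- pauli_from_text(lines_txt)
  expect_equal(op2$words, op$words)
  expect_equal(op2$coeffs, op$coeffs, tolerance = 1e-12)
  gj <- groups_to_json(group_qubitwise(c("ZZII", "IIZZ", "XIII")))
  g2 <- groups_from_json(gj)
  expect_length(g2, 2)
})
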