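# Second quantization in the occupation-number (Fock) basis. Spin-orbital
# ordering is fixed package-wide: alpha block (modes 1..M) then beta block
# (modes M+1..2M), with mode k stored in bit k-1 of the basis-state integer.
# This block ordering is what makes the two parity-symmetry qubits land at
# the end of each spin block after the parity transformation.

popcount_bits <- function(x, bits) {
  out <- integer(length(x))
  for (b in bits) out <- out + bitwAnd(bitwShiftR(x, b), 1L)
  out
}

# sparse Jordan-Wigner creation operator for mode k (1-based) on n modes
creation_op <- function(k, n) {
  dim <- 2^n
  s <- 0:(dim - 1)
  absent <- bitwAnd(bitwShiftR(s, k - 1L), 1L) == 0L
  src <- s[absent]
  dst <- src + 2^(k - 1)
  sign <- (-1)^popcount_bits(src, seq_len(k - 1) - 1L)
  Matrix::sparseMatrix(i = dst + 1, j = src + 1, x = sign, dims = c(dim, dim))
}

# spin-summed excitation operators E_pq = sum_sigma a^dag_{p sigma} a_{q sigma}
excitation_ops <- function(n_orb) {
  n <- 2L * n_orb
  adag <- lapply(seq_len(n), creation_op, n = n)
  a <- lapply(adag, Matrix::t)
  E <- vector("list", n_orb * n_orb)
  for (p in seq_len(n_orb)) for (q in seq_len(n_orb)) {
    E[[(p - 1) * n_orb + q]] <- adag[[p]] %*% a[[q]] +
      adag[[n_orb + p]] %*% a[[n_orb + q]]
  }
  E
}

# full second-quantized Hamiltonian (without h0) in the Fock space
hamiltonian_fock <- function(problem) {
  no <- problem$spec$n_orbitals
  E <- excitation_ops(no)
  dim <- 2^(2 * no)
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(dim, dim))
  Eij <- function(p, q) E[[(p - 1) * no + q]]
  for (p in seq_len(no)) for (q in seq_len(no))
    if (abs(problem$h1[p, q]) > 1e-14) H <- H + problem$h1[p, q] * Eij(p, q)
  for (u in seq_len(no)) for (v in seq_len(no))
    for (x in seq_len(no)) for (y in seq_len(no)) {
      g <- problem$h2[u, v, x, y]
      if (abs(g) < 1e-14) next
      term <- Eij(u, v) %*% Eij(x, y)
      if (v == x) term <- term - Eij(u, y)
      H <- H + 0.5 * g * term
    }
  H
}

# indices (1-based) of Fock states in the (n_alpha, n_beta) sector
sector_fock_indices <- function(n_orb, n_alpha, n_beta) {
  s <- 0:(2^(2 * n_orb) - 1)
  pa <- popcount_bits(s, 0:(n_orb - 1))
  pb <- popcount_bits(s, n_orb:(2 * n_orb - 1))
  which(pa == n_alpha & pb == n_beta)
}

#' Dense CASCI diagonalization of an active-space problem
#'
#' Assembles the second-quantized Hamiltonian in the occupation-number basis
#' and diagonalizes it in the requested (N_alpha, N_beta) sector. This is the
#' classical reference solver against which the variational circuit solver is
#' compared; it is practical for the compact active spaces this package
#' targets (up to ~6 orbitals).
#'
#' @param problem a `pdft_problem`.
#' @param n_roots number of lowest eigenstates to return.
#' @return list with `energies` (Hartree, including `h0`), `vectors`
#'   (columns; determinant basis), and `dets` (occupation bitmasks of the
#'   sector basis, bit k-1 = spin orbital k).
#' @export
casci_solve <- function(problem, n_roots = 1) {
  spec <- problem$spec
  H <- hamiltonian_fock(problem)
  idx <- sector_fock_indices(spec$n_orbitals, spec$n_alpha, spec$n_beta)
  Hs <- as.matrix(H[idx, idx, drop = FALSE])
  e <- eigen(0.5 * (Hs + t(Hs)), symmetric = TRUE)
  ord <- order(e$values)
  k <- seq_len(min(n_roots, length(idx)))
  list(energies = e$values[ord][k] + problem$h0,
       vectors = e$vectors[, ord[k], drop = FALSE],
       dets = idx - 1L)
}

# ground-state energy shortcut
casci_energy <- function(problem) casci_solve(problem, 1)$energies[1]

# 1- and 2-RDM of a CI vector by explicit operator application in the Fock
# space (brute-force reference path; conventions match rdms_exact()).
casci_rdms <- function(problem, ci_vector, dets) {
  no <- problem$spec$n_orbitals
  dim <- 2^(2 * no)
  psi <- numeric(dim)
  psi[dets + 1] <- ci_vector
  E <- excitation_ops(no)
  Eij <- function(p, q) E[[(p - 1) * no + q]]
  gamma <- matrix(0, no, no)
  d2 <- array(0, c(no, no, no, no))
  Epsi <- vector("list", no * no)
  for (p in seq_len(no)) for (q in seq_len(no))
    Epsi[[(p - 1) * no + q]] <- as.numeric(Eij(p, q) %*% psi)
  for (p in seq_len(no)) for (q in seq_len(no))
    gamma[p, q] <- sum(psi * Epsi[[(p - 1) * no + q]])
  for (u in seq_len(no)) for (v in seq_len(no))
    for (x in seq_len(no)) for (y in seq_len(no)) {
      val <- sum(psi * as.numeric(Eij(u, v) %*% Epsi[[(x - 1) * no + y]]))
      if (v == x) val <- val - gamma[u, y]
      d2[u, v, x, y] <- val
    }
  # same 8-fold averaging convention as the measurement path: only the
  # symmetric part of d is observable through h2 or the on-top density
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  d2 <- Reduce(`+`, lapply(perms, function(p) aperm(d2, p))) / 8
  list(gamma = gamma, d = d2)
}
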