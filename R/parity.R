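# Parity fermion-to-qubit mapping and two-qubit symmetry tapering.
#
# Spin-orbital ordering is the package-wide block order: alpha modes 1..M
# then beta modes M+1..2M. Qubit j stores the cumulative occupation parity
# of modes 1..j, so qubit M carries the total alpha parity and qubit 2M the
# total electron parity. In a fixed (N_alpha, N_beta) sector those two
# qubits are frozen and can be removed (the tapering step).

#' Fermionic operator as a sum of ladder-operator products
#'
#' @param terms list; each element is `list(coeff, modes, dagger)` where
#'   `modes` are 1-based spin-orbital indices and `dagger` a logical vector
#'   (`TRUE` for creation), applied left to right as written.
#' @param n_modes number of spin orbitals.
#' @return object of class `fermion_op`.
#' @export
fermion_op <- function(terms, n_modes) {
  structure(list(terms = terms, n_modes = as.integer(n_modes)),
            class = "fermion_op")
}

# parity-encoded ladder operator as a 2-term Pauli operator.
# a^dag_j = 1/2 (prod_{k>j} X_k)(X_j Z_{j-1} -+ i Y_j); annihilation flips
# the sign of the iY term.
parity_ladder <- function(j, n, dagger) {
  base <- rep("I", n)
  if (j < n) base[(j + 1):n] <- "X"
  w1 <- base; w1[j] <- "X"
  if (j > 1) w1[j - 1] <- "Z"
  w2 <- base; w2[j] <- "Y"
  sgn <- if (dagger) -1i else 1i
  pauli_op(c(paste(w1, collapse = ""), paste(w2, collapse = "")),
           c(0.5 + 0i, 0.5 * sgn), n)
}

#' Map a fermionic operator or active-space problem to Pauli form
#'
#' Uses the parity transformation with cumulative-occupation encoding over
#' the alpha-then-beta block ordering. For an active-space problem the full
#' second-quantized Hamiltonian (including the constant `h0`) is mapped onto
#' `2 * n_orbitals` qubits.
#'
#' @param x a [fermion_op()] or `pdft_problem`.
#' @return [pauli_op()] on `n_modes` qubits.
#' @export
parity_map <- function(x) {
  if (inherits(x, "pdft_problem")) return(parity_map_problem(x))
  stopifnot(inherits(x, "fermion_op"))
  n <- x$n_modes
  out <- pauli_op(character(0), complex(0), n)
  for (t in x$terms) {
    stopifnot(length(t$modes) == length(t$dagger),
              all(t$modes >= 1), all(t$modes <= n))
    acc <- pauli_identity(n, t$coeff)
    for (k in seq_along(t$modes))
      acc <- pauli_mult(acc, parity_ladder(t$modes[k], n, t$dagger[k]))
    out <- out + acc
  }
  out
}

# spin-orbital index helpers for block ordering
so_index <- function(p, sigma, n_orb) if (sigma == 1) p else n_orb + p

hamiltonian_fermion_terms <- function(problem) {
  no <- problem$spec$n_orbitals
  terms <- list()
  add <- function(coeff, modes, dagger)
    terms[[length(terms) + 1]] <<- list(coeff = coeff, modes = modes,
                                        dagger = dagger)
  for (p in 1:no) for (q in 1:no) {
    if (abs(problem$h1[p, q]) < 1e-14) next
    for (s in 1:2)
      add(problem$h1[p, q], c(so_index(p, s, no), so_index(q, s, no)),
          c(TRUE, FALSE))
  }
  for (u in 1:no) for (v in 1:no) for (x in 1:no) for (y in 1:no) {
    g <- problem$h2[u, v, x, y]
    if (abs(g) < 1e-14) next
    for (s in 1:2) for (t in 1:2)
      add(0.5 * g,
          c(so_index(u, s, no), so_index(x, t, no),
            so_index(y, t, no), so_index(v, s, no)),
          c(TRUE, TRUE, FALSE, FALSE))
  }
  fermion_op(terms, 2L * no)
}

parity_map_problem <- function(problem) {
  op <- parity_map(hamiltonian_fermion_terms(problem))
  op + pauli_identity(op$n_qubits, problem$h0)
}

#' Symmetry sector of the parity-mapped register
#'
#' Records the particle numbers and the resulting +-1 eigenvalues of the two
#' parity qubits (total alpha parity at qubit M, total parity at qubit 2M)
#' that are frozen and removed by [taper()].
#'
#' @param spec an [active_space_spec()] (or n_alpha/n_beta given directly).
#' @param n_alpha,n_beta,n_orbitals used when `spec` is missing.
#' @return object of class `symmetry_sector`.
#' @export
symmetry_sector <- function(spec = NULL, n_alpha = NULL, n_beta = NULL,
                            n_orbitals = NULL) {
  if (!is.null(spec)) {
    n_alpha <- spec$n_alpha; n_beta <- spec$n_beta
    n_orbitals <- spec$n_orbitals
  }
  structure(list(
    n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
    n_orbitals = as.integer(n_orbitals),
    tapered_positions = c(n_orbitals, 2L * n_orbitals),
    tapered_values = c((-1)^n_alpha, (-1)^(n_alpha + n_beta))),
    class = "symmetry_sector")
}

#' Remove the two symmetry-frozen parity qubits
#'
#' Every term of a particle-number-conserving operator acts as `I` or `Z` on
#' the two parity qubits; `Z` is replaced by its sector eigenvalue and the
#' qubits are deleted, shrinking the register from `2M` to `2M - 2`.
#'
#' @param op [pauli_op()] on the full parity register.
#' @param sector a [symmetry_sector()].
#' @return [pauli_op()] on `op$n_qubits - 2` qubits.
#' @export
taper <- function(op, sector) {
  pos <- sector$tapered_positions
  vals <- sector$tapered_values
  stopifnot(op$n_qubits == 2 * sector$n_orbitals)
  words <- coeffs <- NULL
  new_words <- character(length(op$words))
  new_coeffs <- op$coeffs
  for (i in seq_along(op$words)) {
    letters_w <- strsplit(op$words[i], "")[[1]]
    for (k in 1:2) {
      l <- letters_w[pos[k]]
      if (l == "X" || l == "Y")
        stop("taper: term '", op$words[i],
             "' does not commute with the parity symmetries")
      if (l == "Z") new_coeffs[i] <- new_coeffs[i] * vals[k]
    }
    new_words[i] <- paste(letters_w[-pos], collapse = "")
  }
  pauli_op(new_words, new_coeffs, op$n_qubits - 2L)
}

# occupation bitmask (bit k-1 = mode k) -> parity bitmask on 2M qubits
occ_to_parity <- function(det, n_modes) {
  acc <- 0L
  out <- 0L
  for (k in seq_len(n_modes)) {
    acc <- bitwXor(acc, bitwAnd(bitwShiftR(det, k - 1L), 1L))
    out <- bitwOr(out, bitwShiftL(acc, k - 1L))
  }
  out
}

# parity bitmask -> tapered-register bitmask (drop qubits M and 2M)
parity_to_tapered <- function(pbits, n_orb) {
  keep <- setdiff(seq_len(2 * n_orb), c(n_orb, 2 * n_orb))
  out <- 0L
  for (i in seq_along(keep))
    out <- bitwOr(out, bitwShiftL(bitwAnd(bitwShiftR(pbits, keep[i] - 1L), 1L),
                                  i - 1L))
  out
}

# determinant (occupation bitmask over 2M modes) -> tapered basis index
det_to_tapered <- function(det, n_orb) {
  parity_to_tapered(occ_to_parity(det, 2L * n_orb), n_orb)
}
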