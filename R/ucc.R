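# Unitary coupled-cluster singles-and-doubles ansatzes on the tapered parity
# register. The closed-shell builder (UCCSD) and the restricted open-shell
# builder (ROUCCSD) share one engine: spin-conserving single and double
# excitations out of the Hartree-Fock determinant, each excitation
# exponentiated term by term (single first-order Trotter step, deterministic
# operator ordering; the variational principle absorbs Trotter bias).

hf_determinant <- function(spec) {
  no <- spec$n_orbitals
  det <- 0L
  if (spec$n_alpha > 0)
    for (k in seq_len(spec$n_alpha)) det <- bitwOr(det, bitwShiftL(1L, k - 1L))
  if (spec$n_beta > 0)
    for (k in seq_len(spec$n_beta))
      det <- bitwOr(det, bitwShiftL(1L, no + k - 1L))
  det
}

# spin-conserving excitation list (singles + doubles) for an occupation
ucc_excitations <- function(spec) {
  no <- spec$n_orbitals
  occ_a <- seq_len(spec$n_alpha)
  occ_b <- if (spec$n_beta > 0) no + seq_len(spec$n_beta) else integer(0)
  vir_a <- setdiff(seq_len(no), occ_a)
  vir_b <- setdiff(no + seq_len(no), occ_b)
  occ <- c(occ_a, occ_b)
  vir <- c(vir_a, vir_b)
  spin_of <- function(m) ifelse(m <= no, 1L, 2L)
  ex <- list()
  for (i in occ) for (a in vir)
    if (spin_of(i) == spin_of(a))
      ex[[length(ex) + 1]] <- list(type = "single", from = i, to = a)
  no2 <- length(occ)
  for (ii in seq_along(occ)) for (jj in seq_along(occ)) {
    if (jj <= ii) next
    i <- occ[ii]; j <- occ[jj]
    for (aa in seq_along(vir)) for (bb in seq_along(vir)) {
      if (bb <= aa) next
      a <- vir[aa]; b <- vir[bb]
      if (identical(sort(c(spin_of(i), spin_of(j))),
                    sort(c(spin_of(a), spin_of(b))))) {
        # assign targets spin-consistently
        if (spin_of(i) == spin_of(j)) {
          ex[[length(ex) + 1]] <- list(type = "double", from = c(i, j),
                                       to = c(a, b))
        } else {
          ta <- if (spin_of(a) == spin_of(i)) c(a, b) else c(b, a)
          ex[[length(ex) + 1]] <- list(type = "double", from = c(i, j),
                                       to = ta)
        }
      }
    }
  }
  ex
}

excitation_generator <- function(exc, n_modes) {
  if (exc$type == "single") {
    fermion_op(list(
      list(coeff = 1, modes = c(exc$to, exc$from), dagger = c(TRUE, FALSE)),
      list(coeff = -1, modes = c(exc$from, exc$to), dagger = c(TRUE, FALSE))),
      n_modes)
  } else {
    fermion_op(list(
      list(coeff = 1,
           modes = c(exc$to[1], exc$to[2], exc$from[2], exc$from[1]),
           dagger = c(TRUE, TRUE, FALSE, FALSE)),
      list(coeff = -1,
           modes = c(exc$from[1], exc$from[2], exc$to[2], exc$to[1]),
           dagger = c(TRUE, TRUE, FALSE, FALSE))),
      n_modes)
  }
}

build_ucc <- function(problem, tapered = TRUE) {
  spec <- problem$spec
  no <- spec$n_orbitals
  sector <- symmetry_sector(spec)
  det <- hf_determinant(spec)
  ex <- ucc_excitations(spec)
  n_q <- if (tapered) 2L * no - 2L else 2L * no
  init <- if (tapered) det_to_tapered(det, no) else occ_to_parity(det, 2L * no)
  gates <- list()
  pidx <- 0L
  for (e in ex) {
    gen <- parity_map(excitation_generator(e, 2L * no))
    if (tapered) gen <- taper(gen, sector)
    if (length(gen$words) == 0) next   # excitation annihilated by symmetry
    if (max(abs(Re(gen$coeffs))) > 1e-12)
      stop("excitation generator is not anti-Hermitian after mapping")
    pidx <- pidx + 1L
    for (k in seq_along(gen$words)) {
      w <- Im(gen$coeffs[k])
      gates[[length(gates) + 1]] <-
        list(name = "PAULI_EXP", word = gen$words[k],
             param_index = pidx, mult = -2 * w)
    }
  }
  circuit(n_q, gates, initial_state = init,
          meta = list(ansatz = if (spec$n_alpha == spec$n_beta) "uccsd"
                      else "rouccsd",
                      n_excitations = pidx, tapered = tapered))
}

#' Build a UCCSD circuit for a closed-shell active space
#'
#' @param problem a `pdft_problem` with a closed-shell spec
#'   (`n_alpha == n_beta`).
#' @param tapered build on the symmetry-tapered register (default) or on the
#'   full parity register.
#' @return [circuit()] whose initial state is the Hartree-Fock determinant.
#' @export
build_uccsd <- function(problem, tapered = TRUE) {
  if (problem$spec$n_alpha != problem$spec$n_beta)
    stop("UCCSD requires a closed-shell active space; use build_rouccsd()")
  build_ucc(problem, tapered)
}

#' Build a restricted open-shell UCCSD (ROUCCSD) circuit
#'
#' Accepts any `n_alpha >= n_beta` occupation; single occupations and the
#' corresponding spin-conserving excitations are treated explicitly.
#'
#' @inheritParams build_uccsd
#' @return [circuit()].
#' @export
build_rouccsd <- function(problem, tapered = TRUE) {
  build_ucc(problem, tapered)
}
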