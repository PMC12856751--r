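# Active-space Hamiltonians: (N_e, N_o) windows of canonical orbitals around
# the Fermi level, with core contributions folded into an effective
# one-electron operator and a constant h0.

#' Specify an active space
#'
#' @param n_electrons total active electrons N_e.
#' @param n_orbitals active spatial orbitals N_o.
#' @param n_alpha,n_beta spin occupations; default from `spin`
#'   (`n_alpha - n_beta = spin`).
#' @param spin N_alpha - N_beta (used when `n_alpha` is missing).
#' @return object of class `pdft_active_spec`.
#' @export
active_space_spec <- function(n_electrons, n_orbitals, n_alpha = NULL,
                              n_beta = NULL, spin = 0L) {
  if (is.null(n_alpha)) {
    n_alpha <- (n_electrons + spin) / 2
    n_beta <- (n_electrons - spin) / 2
  }
  if (n_alpha != round(n_alpha) || n_beta != round(n_beta))
    stop("active space: electron count and spin are inconsistent")
  n_alpha <- as.integer(n_alpha); n_beta <- as.integer(n_beta)
  stopifnot(n_electrons > 0, n_electrons <= 2 * n_orbitals,
            n_alpha + n_beta == n_electrons, n_alpha >= n_beta, n_beta >= 0,
            n_alpha <= n_orbitals)
  structure(list(n_electrons = as.integer(n_electrons),
                 n_orbitals = as.integer(n_orbitals),
                 n_alpha = n_alpha, n_beta = n_beta),
            class = "pdft_active_spec")
}

#' @export
print.pdft_active_spec <- function(x, ...) {
  cat(sprintf("<active space> (%de, %do), %d alpha / %d beta\n",
              x$n_electrons, x$n_orbitals, x$n_alpha, x$n_beta))
  invisible(x)
}

# contract tensor mode `mode` of 4-index array with coefficient matrix C
mode_mult4 <- function(A, C, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(1:4, mode))
  A <- aperm(A, perm)
  m <- matrix(A, d[mode], prod(d[-mode]))
  out <- t(C) %*% m
  d[mode] <- ncol(C)
  A <- array(out, d[perm])
  aperm(A, order(perm))
}

#' Carve a CASCI active-space Hamiltonian out of a mean-field solution
#'
#' The active orbitals are the contiguous canonical-orbital window bracketing
#' the Fermi level implied by the (N_e, N_o) pattern: all lower orbitals form
#' a doubly occupied core whose mean field (plus nuclear and point-charge
#' terms) is absorbed into the scalar `h0`.
#'
#' @param mf converged [run_mean_field()] result.
#' @param spec an [active_space_spec()].
#' @return object of class `pdft_problem` with `h0` (Hartree), `h1`
#'   (N_o x N_o, Hartree), `h2` (chemist-notation `(pq|rs)` array), active
#'   `mo_coeff` (AO x N_o), `core_density` (AO basis), the spec, and a
#'   backend reference for real-space quantities.
#' @export
extract_active_space <- function(mf, spec) {
  stopifnot(inherits(mf, "pdft_scf"), inherits(spec, "pdft_active_spec"))
  if (!mf$converged) stop("mean field not converged")
  n <- mf$ints$nbf
  nelec <- mf$geom$n_electrons
  ncore <- (nelec - spec$n_electrons) / 2
  if (ncore != round(ncore) || ncore < 0)
    stop("active space: (", nelec, " electrons, ", spec$n_electrons,
         " active) leaves a non-closed-shell core")
  ncore <- as.integer(ncore)
  if (ncore + spec$n_orbitals > n)
    stop("active space exceeds orbital space (", n, " orbitals)")
  if (spec$n_alpha - spec$n_beta != mf$n_alpha - mf$n_beta)
    stop("active-space spin does not match the mean-field spin")
  C <- mf$mo_coeff
  C_core <- C[, seq_len(ncore), drop = FALSE]
  C_act <- C[, ncore + seq_len(spec$n_orbitals), drop = FALSE]
  Dcore <- if (ncore > 0) 2 * C_core %*% t(C_core) else matrix(0, n, n)
  jk <- coulomb_exchange(mf$ints$eri, Dcore)
  veff <- jk$J - 0.5 * jk$K
  h1 <- t(C_act) %*% (mf$ints$hcore + veff) %*% C_act
  h1 <- 0.5 * (h1 + t(h1))
  h0 <- mf$ints$enuc + sum(Dcore * (mf$ints$hcore + 0.5 * veff))
  h2 <- mf$ints$eri
  for (k in 1:4) h2 <- mode_mult4(h2, C_act, k)
  structure(list(h0 = unname(h0), h1 = h1, h2 = h2, mo_coeff = C_act,
                 core_density = Dcore, basis = mf$basis, spec = spec,
                 n_core = ncore, scf = mf),
            class = "pdft_problem")
}

#' Construct an active-space problem from raw integral tables
#'
#' Used by the synthetic fixture generators (model pi-electron Hamiltonians,
#' random symmetry-respecting integrals). No real-space backend is attached,
#' so such problems support everything except grid-based functional
#' evaluation.
#'
#' @param h0 scalar core energy (Hartree).
#' @param h1 symmetric one-electron integral matrix.
#' @param h2 two-electron integral array, chemist notation `(pq|rs)`.
#' @param spec an [active_space_spec()].
#' @param basis label recorded for provenance.
#' @return `pdft_problem`.
#' @export
problem_from_integrals <- function(h0, h1, h2, spec, basis = "model") {
  stopifnot(inherits(spec, "pdft_active_spec"))
  no <- spec$n_orbitals
  h1 <- matrix(h1, no, no)
  stopifnot(max(abs(h1 - t(h1))) < 1e-10, all(dim(h2) == no))
  structure(list(h0 = h0, h1 = h1, h2 = h2, mo_coeff = NULL,
                 core_density = NULL, basis = basis, spec = spec,
                 n_core = 0L, scf = NULL),
            class = "pdft_problem")
}

#' @export
print.pdft_problem <- function(x, ...) {
  cat(sprintf("<pdft_problem> (%de, %do) active space, basis %s, h0 = %.8f\n",
              x$spec$n_electrons, x$spec$n_orbitals, x$basis, x$h0))
  invisible(x)
}

# assert hermiticity / 8-fold ERI symmetry; called by constructors and tests
check_problem_invariants <- function(problem, tol = 1e-8) {
  h1 <- problem$h1; h2 <- problem$h2
  stopifnot(max(abs(h1 - t(h1))) < tol)
  perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  for (p in perms) stopifnot(max(abs(h2 - aperm(h2, p))) < tol)
  invisible(TRUE)
}
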