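# Mean-field references: restricted (RHF) and restricted open-shell (ROHF)
# Hartree-Fock with DIIS acceleration. These supply the canonical orbitals
# from which active-space Hamiltonians are carved.

coulomb_exchange <- function(eri, D) {
  n <- dim(eri)[1]
  G <- matrix(eri, n * n, n * n)
  J <- matrix(G %*% as.vector(D), n, n)
  # K_{mu nu} = sum_{ls} (ml|sn) D_{ls}: permute to (m,n,l,s) order
  Kmat <- matrix(aperm(eri, c(1, 4, 2, 3)), n * n, n * n)
  K <- matrix(Kmat %*% as.vector(t(D)), n, n)
  list(J = J, K = K)
}

diis_update <- function(hist, F, err, max_vec = 8) {
  hist$F <- c(hist$F, list(F)); hist$e <- c(hist$e, list(err))
  if (length(hist$F) > max_vec) {
    hist$F <- hist$F[-1]; hist$e <- hist$e[-1]
  }
  m <- length(hist$F)
  if (m < 2) return(list(hist = hist, F = F))
  B <- matrix(0, m + 1, m + 1)
  for (i in 1:m) for (j in 1:m)
    B[i, j] <- sum(hist$e[[i]] * hist$e[[j]])
  B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  co <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) return(list(hist = hist, F = F))
  Fd <- Reduce(`+`, Map(`*`, hist$F, co))
  list(hist = hist, F = Fd)
}

#' Run a mean-field (Hartree-Fock) reference calculation
#'
#' Dispatches to a closed-shell restricted solver for `spin == 0` and to a
#' restricted open-shell (Roothaan effective Fock) solver otherwise. When
#' the geometry carries background point charges, their potential is part of
#' the one-electron Hamiltonian and all classical Coulomb terms
#' (nuclear-nuclear, nuclear-charge, charge-charge) are included in the
#' reported total energy.
#'
#' @param geom a [geometry()].
#' @param basis basis-set name, e.g. `"sto-3g"` or `"6-31g"`.
#' @param max_iter,conv_tol SCF iteration budget and energy/DIIS-error
#'   convergence threshold (Hartree).
#' @return object of class `pdft_scf` with orbital coefficients `mo_coeff`,
#'   orbital energies `mo_energy`, occupations, total energy `e_tot`
#'   (Hartree), Fock/overlap matrices and the integral set.
#' @export
run_mean_field <- function(geom, basis, max_iter = 120, conv_tol = 1e-10) {
  ints <- compute_integrals(geom, basis)
  n <- ints$nbf
  nelec <- geom$n_electrons
  na <- (nelec + geom$spin) / 2
  nb <- (nelec - geom$spin) / 2
  if (na != round(na) || nb < 0)
    stop("invalid electron count/spin: nelec=", nelec, " spin=", geom$spin)
  na <- as.integer(na); nb <- as.integer(nb)
  S <- ints$S
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8)
    warning("near-linear dependence in basis (min S eigenvalue ",
            format(min(es$values)), ")")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  hcore <- ints$hcore

  # eigen() sorts decreasing; ascending-orbital-energy order is wanted
  eig_asc <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    idx <- order(e$values)
    list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
  }

  # core-Hamiltonian initial guess
  C <- X %*% eig_asc(t(X) %*% hcore %*% X)$vectors
  open_shell <- geom$spin != 0
  e_old <- 0; converged <- FALSE; hist <- list(F = list(), e = list())
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Ca <- C[, seq_len(na), drop = FALSE]
    Cb <- C[, seq_len(nb), drop = FALSE]
    Da <- Ca %*% t(Ca)
    Db <- if (nb > 0) Cb %*% t(Cb) else matrix(0, n, n)
    jka <- coulomb_exchange(ints$eri, Da + Db)
    Ka <- coulomb_exchange(ints$eri, Da)$K
    Kb <- if (nb > 0) coulomb_exchange(ints$eri, Db)$K else matrix(0, n, n)
    Fa <- hcore + jka$J - Ka
    Fb <- hcore + jka$J - Kb
    e_elec <- 0.5 * sum(Da * (hcore + Fa)) + 0.5 * sum(Db * (hcore + Fb))
    e_tot <- e_elec + ints$enuc
    trace <- c(trace, e_tot)

    if (!open_shell) {
      Feff <- Fa
    } else {
      # Roothaan single-matrix effective Fock for ROHF
      fc <- 0.5 * (Fa + Fb)
      pc <- Db %*% S                    # closed (doubly occupied) projector
      po <- (Da - Db) %*% S             # open-shell projector
      pv <- diag(n) - Da %*% S          # virtual projector
      Feff <- 0.5 * (t(pc) %*% fc %*% pc + t(po) %*% fc %*% po +
                     t(pv) %*% fc %*% pv)
      Feff <- Feff + t(po) %*% Fb %*% pc + t(po) %*% Fa %*% pv +
              t(pv) %*% fc %*% pc
      Feff <- Feff + t(Feff)
    }
    err <- Feff %*% (Da + Db) %*% S - S %*% (Da + Db) %*% Feff
    dd <- diis_update(hist, Feff, err)
    hist <- dd$hist
    Fuse <- dd$F
    eo <- eig_asc(t(X) %*% Fuse %*% X)
    C <- X %*% eo$vectors
    mo_energy <- eo$values
    if (abs(e_tot - e_old) < conv_tol && max(abs(err)) < 1e-6) {
      converged <- TRUE
      break
    }
    e_old <- e_tot
  }
  if (!converged)
    stop(sprintf(
      "SCF failed to converge in %d iterations (last dE=%.3e, |err|=%.3e)",
      max_iter, e_tot - e_old, max(abs(err))))
  occ <- rep(0, n); occ[seq_len(nb)] <- 2
  if (na > nb) occ[seq(nb + 1, na)] <- 1
  structure(list(mo_coeff = C, mo_energy = mo_energy, occ = occ,
                 n_alpha = na, n_beta = nb, e_tot = e_tot,
                 converged = converged, n_iter = it, trace = trace,
                 geom = geom, basis = basis, ints = ints,
                 open_shell = open_shell),
            class = "pdft_scf")
}

#' @export
print.pdft_scf <- function(x, ...) {
  cat(sprintf("<pdft_scf> %s  E = %.10f Ha  (%s, %d iterations)\n",
              if (x$open_shell) "ROHF" else "RHF", x$e_tot,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
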