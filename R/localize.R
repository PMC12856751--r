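# Boys localization of occupied orbital windows and the direct-coupling
# extraction of the donor-acceptor electronic coupling from a dimer
# mean-field calculation.

# Boys localization by 2x2 Jacobi sweeps maximizing sum_i |<i|r|i>|^2
boys_localize <- function(C, dip, max_sweeps = 100, tol = 1e-10) {
  n <- ncol(C)
  if (n < 2) return(C)
  r_mats <- lapply(dip, function(Dk) t(C) %*% Dk %*% C)
  U <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    change <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- 0; b <- 0
      for (k in 1:3) {
        rij <- r_mats[[k]][i, j]
        dd <- r_mats[[k]][i, i] - r_mats[[k]][j, j]
        a <- a + rij^2 - 0.25 * dd^2
        b <- b + rij * dd
      }
      if (sqrt(a^2 + b^2) < 1e-14) next
      alpha <- 0.25 * atan2(b, -a)
      # candidate rotation; keep it only if the objective improves
      cs <- cos(alpha); sn <- sin(alpha)
      obj <- function(rm) sum(vapply(rm, function(m)
        sum(diag(m)^2), numeric(1)))
      rot_pair <- function(rm) lapply(rm, function(m) {
        mi <- m[, i] * cs + m[, j] * sn
        mj <- -m[, i] * sn + m[, j] * cs
        m[, i] <- mi; m[, j] <- mj
        ri <- m[i, ] * cs + m[j, ] * sn
        rj <- -m[i, ] * sn + m[j, ] * cs
        m[i, ] <- ri; m[j, ] <- rj
        m
      })
      new_r <- rot_pair(r_mats)
      gain <- obj(new_r) - obj(r_mats)
      if (gain > 0) {
        r_mats <- new_r
        ui <- U[, i] * cs + U[, j] * sn
        uj <- -U[, i] * sn + U[, j] * cs
        U[, i] <- ui; U[, j] <- uj
        change <- change + gain
      }
    }
    if (change < tol) break
  }
  C %*% U
}

#' Donor/acceptor coupling inputs from a dimer calculation
#'
#' Runs a closed-shell mean field on the dimer, Boys-localizes the
#' `n_window` highest occupied canonical orbitals onto sites, assigns the
#' donor and acceptor orbitals by Mulliken population on the two fragment
#' atom sets, and returns the localized-basis Fock and overlap elements
#' feeding [direct_coupling()].
#'
#' @param geom dimer [geometry()].
#' @param basis basis-set name.
#' @param frag1,frag2 disjoint atom index sets defining the fragments.
#' @param n_window how many top occupied orbitals to localize (default 2).
#' @param population_min minimum fragment Mulliken population for an
#'   unambiguous assignment (default 0.6).
#' @return list with `T_DA`, `S_DA`, `e_D`, `e_A` (eV), `H_DA` (eV from
#'   [direct_coupling()]), populations and the localized coefficients.
#' @export
coupling_from_dimer <- function(geom, basis, frag1, frag2, n_window = 2,
                                population_min = 0.6) {
  stopifnot(length(intersect(frag1, frag2)) == 0)
  mf <- run_mean_field(geom, basis)
  if (mf$open_shell) stop("coupling_from_dimer expects a closed-shell dimer")
  nocc <- mf$n_beta
  win <- seq(nocc - n_window + 1, nocc)
  C <- mf$mo_coeff[, win, drop = FALSE]
  L <- boys_localize(C, mf$ints$dip)
  S <- mf$ints$S
  # Fock matrix of the converged mean field
  D <- 2 * mf$mo_coeff[, seq_len(nocc), drop = FALSE] %*%
    t(mf$mo_coeff[, seq_len(nocc), drop = FALSE])
  jk <- coulomb_exchange(mf$ints$eri, D)
  Fao <- mf$ints$hcore + jk$J - 0.5 * jk$K
  ao_at <- mf$ints$basis$ao_atom
  mulliken_frag <- function(l, frag) {
    contrib <- l * (S %*% l)
    sum(contrib[ao_at %in% frag])
  }
  pop1 <- apply(L, 2, mulliken_frag, frag = frag1)
  pop2 <- apply(L, 2, mulliken_frag, frag = frag2)
  i_d <- which.max(pop1)
  i_a <- which.max(pop2)
  if (i_d == i_a || pop1[i_d] < population_min || pop2[i_a] < population_min)
    stop(sprintf(paste0("ambiguous localization: fragment populations ",
                        "%.3f / %.3f (need >= %.2f on distinct orbitals)"),
                 max(pop1), max(pop2), population_min))
  ha2ev <- pdft_constants$hartree2ev
  ld <- L[, i_d]; la <- L[, i_a]
  T_DA <- as.numeric(t(ld) %*% Fao %*% la) * ha2ev
  e_D <- as.numeric(t(ld) %*% Fao %*% ld) * ha2ev
  e_A <- as.numeric(t(la) %*% Fao %*% la) * ha2ev
  S_DA <- as.numeric(t(ld) %*% S %*% la)
  list(T_DA = T_DA, S_DA = S_DA, e_D = e_D, e_A = e_A,
       H_DA = direct_coupling(T_DA, S_DA, e_D, e_A),
       populations = cbind(frag1 = pop1, frag2 = pop2),
       localized = L, window = win, scf = mf)
}
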