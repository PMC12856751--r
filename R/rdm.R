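# Reduced-density-matrix extraction from the frozen-parameter circuit:
# exactly from the statevector, or via simulated shot measurement of
# qubit-wise-commuting groups with an optional readout-error channel and
# confusion-matrix mitigation (the six-step measurement protocol, emulated
# in software).
#
# Conventions (fixed package-wide): gamma and d are spin-summed over spatial
# active orbitals; d[p,q,r,s] = sum_{sigma tau} <a+_{p sigma} a+_{r tau}
# a_{s tau} a_{q sigma}> i.e. chemist pairing (pq|rs), so that
# E = h0 + sum(gamma * h1) + 0.5 * sum(d * h2).

rdm_element_list <- function(n_orb) {
  els <- list()
  for (s in 1:2) for (p in seq_len(n_orb)) for (q in seq_len(n_orb))
    els[[length(els) + 1]] <- list(kind = "gamma", idx = c(p, q),
                                   spins = s)
  for (s in 1:2) for (t in 1:2)
    for (u in seq_len(n_orb)) for (v in seq_len(n_orb))
      for (x in seq_len(n_orb)) for (y in seq_len(n_orb))
        els[[length(els) + 1]] <- list(kind = "d", idx = c(u, v, x, y),
                                       spins = c(s, t))
  els
}

rdm_element_fermion <- function(el, n_orb) {
  if (el$kind == "gamma") {
    s <- el$spins
    fermion_op(list(list(coeff = 1,
                         modes = c(so_index(el$idx[1], s, n_orb),
                                   so_index(el$idx[2], s, n_orb)),
                         dagger = c(TRUE, FALSE))), 2L * n_orb)
  } else {
    s <- el$spins[1]; t <- el$spins[2]
    u <- el$idx[1]; v <- el$idx[2]; x <- el$idx[3]; y <- el$idx[4]
    fermion_op(list(list(coeff = 1,
                         modes = c(so_index(u, s, n_orb),
                                   so_index(x, t, n_orb),
                                   so_index(y, t, n_orb),
                                   so_index(v, s, n_orb)),
                         dagger = c(TRUE, TRUE, FALSE, FALSE))), 2L * n_orb)
  }
}

#' Build a measurement plan for the 1- and 2-RDM of an active space
#'
#' Enumerates every spin-conserving spin-orbital RDM element (N_so^2/2
#' one-body and N_so^4/4 two-body operators for N_so spin orbitals), maps
#' each through the parity transformation, tapers it into the symmetry
#' sector, and groups all distinct Pauli words qubit-wise into simultaneous
#' measurement settings.
#'
#' @param problem a `pdft_problem`.
#' @param sector a [symmetry_sector()]; defaults to the problem's spec.
#' @param shots_per_group measurement shots per group (default 2048).
#' @return object of class `measurement_plan`: `elements` (with mapped
#'   operators), `groups`, `words` (distinct non-identity words),
#'   `n_elements_1`, `n_elements_2`, `shots_per_group`.
#' @export
measurement_plan <- function(problem, sector = NULL, shots_per_group = 2048) {
  if (shots_per_group <= 0) stop("shots_per_group must be positive")
  no <- problem$spec$n_orbitals
  if (is.null(sector)) sector <- symmetry_sector(problem$spec)
  els <- rdm_element_list(no)
  ops <- vector("list", length(els))
  for (i in seq_along(els)) {
    op <- parity_map(rdm_element_fermion(els[[i]], no))
    ops[[i]] <- taper(op, sector)
  }
  idw <- strrep("I", 2L * no - 2L)
  words <- unique(unlist(lapply(ops, `[[`, "words")))
  words <- setdiff(words, idw)
  groups <- group_qubitwise(words)
  structure(list(elements = els, ops = ops, words = sort(words),
                 groups = groups,
                 n_elements_1 = sum(vapply(els, function(e)
                   e$kind == "gamma", TRUE)),
                 n_elements_2 = sum(vapply(els, function(e)
                   e$kind == "d", TRUE)),
                 shots_per_group = as.integer(shots_per_group),
                 n_qubits = 2L * no - 2L, n_orb = no, sector = sector),
            class = "measurement_plan")
}

#' @export
print.measurement_plan <- function(x, ...) {
  cat(sprintf(paste0("<measurement_plan> %d + %d RDM elements, %d distinct",
                     " Pauli words in %d groups, %d shots/group\n"),
              x$n_elements_1, x$n_elements_2, length(x$words),
              length(x$groups), x$shots_per_group))
  invisible(x)
}

# assemble spatial spin-summed RDMs from per-element values
assemble_rdms <- function(plan, values, ses = NULL, nelec = NULL) {
  no <- plan$n_orb
  gamma <- matrix(0, no, no)
  d <- array(0, c(no, no, no, no))
  g_se <- matrix(0, no, no); d_se <- array(0, c(no, no, no, no))
  for (i in seq_along(plan$elements)) {
    el <- plan$elements[[i]]
    if (el$kind == "gamma") {
      gamma[el$idx[1], el$idx[2]] <- gamma[el$idx[1], el$idx[2]] + values[i]
      if (!is.null(ses)) g_se[el$idx[1], el$idx[2]] <-
          sqrt(g_se[el$idx[1], el$idx[2]]^2 + ses[i]^2)
    } else {
      k <- el$idx
      d[k[1], k[2], k[3], k[4]] <- d[k[1], k[2], k[3], k[4]] + values[i]
      if (!is.null(ses)) d_se[k[1], k[2], k[3], k[4]] <-
          sqrt(d_se[k[1], k[2], k[3], k[4]]^2 + ses[i]^2)
    }
  }
  # hermiticity restoration: gamma symmetrized, d averaged over its 8-fold
  # permutational symmetry so noisy RDMs stay valid functional inputs
  gamma <- 0.5 * (gamma + t(gamma))
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  d <- Reduce(`+`, lapply(perms, function(p) aperm(d, p))) / 8
  structure(list(gamma = gamma, d = d,
                 gamma_se = if (is.null(ses)) NULL else g_se,
                 d_se = if (is.null(ses)) NULL else d_se,
                 convention = "spin-summed-chemist"),
            class = "spin_rdms")
}

#' @export
print.spin_rdms <- function(x, ...) {
  cat(sprintf("<spin_rdms> %d orbitals, Tr(gamma) = %.8f (%s)\n",
              nrow(x$gamma), sum(diag(x$gamma)), x$convention))
  invisible(x)
}

# fraction of |psi|^2 outside the (n_alpha, n_beta) sector
sector_leakage <- function(psi, sector) {
  allowed <- sector_tapered_states(sector)
  1 - sum(Mod(psi[allowed + 1])^2)
}

# tapered-register basis states compatible with the sector
sector_tapered_states <- function(sector) {
  no <- sector$n_orbitals
  dets <- sector_fock_indices(no, sector$n_alpha, sector$n_beta) - 1L
  sort(vapply(dets, det_to_tapered, integer(1), n_orb = no))
}

#' Exact RDMs from a statevector
#'
#' Evaluates every element operator of the measurement plan as an exact
#' expectation value on the tapered-register state.
#'
#' @param psi statevector on the tapered register (from a sector-preserving
#'   circuit; leakage beyond `1e-8` errors).
#' @param problem a `pdft_problem`.
#' @param sector optional [symmetry_sector()].
#' @param plan optional precomputed [measurement_plan()] (reuse saves time).
#' @return `spin_rdms` (spatial, spin-summed, chemist convention).
#' @export
rdms_exact <- function(psi, problem, sector = NULL, plan = NULL) {
  if (is.null(sector)) sector <- symmetry_sector(problem$spec)
  leak <- sector_leakage(psi, sector)
  if (leak > 1e-8)
    stop(sprintf("state leaks out of the (%d,%d) sector by %.2e",
                 sector$n_alpha, sector$n_beta, leak))
  if (is.null(plan)) plan <- measurement_plan(problem, sector)
  vals <- vapply(plan$ops, function(op) {
    v <- sum(Conj(psi) * pauli_apply(op, psi))
    Re(v)
  }, numeric(1))
  assemble_rdms(plan, vals)
}

#' Readout-error channel from per-qubit assignment fidelities
#'
#' Confusion matrix columns are true states, rows measured states. With
#' per-qubit fidelities `f0` (P(read 0 | prepared 0)) and `f1`, the full
#' matrix is the tensor product over qubits; an arbitrary correlated matrix
#' may be supplied instead.
#'
#' @param n_qubits register size.
#' @param f0,f1 per-qubit readout fidelities (defaults: the device values
#'   98.35% and 95.88% used for the packaged noise studies).
#' @param matrix optional full `2^n x 2^n` correlated confusion matrix.
#' @param calibration_shots bookkeeping field (default 8192).
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(n_qubits, f0 = 0.9835, f1 = 0.9588,
                              matrix = NULL, calibration_shots = 8192) {
  if (is.null(matrix)) {
    m1 <- lapply(rep_len(list(NULL), n_qubits), function(...) NULL)
    f0 <- rep_len(f0, n_qubits); f1 <- rep_len(f1, n_qubits)
    M <- 1
    for (q in seq_len(n_qubits)) {
      Mq <- rbind(c(f0[q], 1 - f1[q]), c(1 - f0[q], f1[q]))
      M <- Mq %x% M   # qubit 1 = least significant bit
    }
    matrix <- M
    kind <- "tensor"
  } else {
    kind <- "correlated"
    stopifnot(nrow(matrix) == 2^n_qubits, ncol(matrix) == 2^n_qubits)
  }
  csum <- colSums(matrix)
  if (max(abs(csum - 1)) > 1e-8)
    stop("calibration columns must be probability distributions")
  structure(list(matrix = matrix, n_qubits = as.integer(n_qubits),
                 kind = kind, calibration_shots = calibration_shots,
                 condition = kappa(matrix, exact = TRUE)),
            class = "calibration_model")
}

#' Estimate a correlated confusion matrix from calibration circuits
#'
#' Simulates the standard calibration run: every computational basis state
#' is prepared, pushed through `channel`, and measured with
#' `calibration_shots` shots; the empirical outcome frequencies form the
#' estimated confusion matrix (columns renormalized).
#'
#' @param channel the true `calibration_model` to emulate.
#' @param calibration_shots shots per basis state (default 8192).
#' @param seed RNG seed.
#' @return `calibration_model` of kind `"correlated"`.
#' @export
simulate_calibration <- function(channel, calibration_shots = 8192,
                                 seed = 1) {
  n <- channel$n_qubits
  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  M <- matrix(0, 2^n, 2^n)
  for (s in seq_len(2^n)) {
    cnt <- stats::rmultinom(1, calibration_shots, channel$matrix[, s])
    M[, s] <- cnt / calibration_shots
  }
  calibration_model(n, matrix = M, calibration_shots = calibration_shots)
}

#' Correct a measured distribution with a calibration model
#'
#' Applies the (pseudo)inverse of the confusion matrix, clips negative
#' entries to zero and renormalizes onto the probability simplex.
#'
#' @param probs raw outcome probabilities (length `2^n`).
#' @param calibration a [calibration_model()].
#' @return corrected probability vector.
#' @export
mitigate <- function(probs, calibration) {
  if (length(probs) != nrow(calibration$matrix))
    stop("outcome space does not match the calibration dimension")
  p <- tryCatch(solve(calibration$matrix, probs),
                error = function(e)
                  stop("singular calibration matrix: ", conditionMessage(e)))
  p[p < 0] <- 0
  s <- sum(p)
  if (s <= 0) stop("mitigation produced an empty distribution")
  p / s
}

# rotate psi into the measurement basis of a group (X -> H, Y -> special U)
rotate_to_basis <- function(psi, basis_word, n_qubits) {
  letters_w <- strsplit(basis_word, "")[[1]]
  s <- 0:(2^n_qubits - 1)
  for (q in seq_len(n_qubits)) {
    l <- letters_w[q]
    if (l == "I" || l == "Z") next
    U <- if (l == "X") matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)
         else matrix(c(1, 1, -1i, 1i), 2, 2) / sqrt(2)  # rows <+i|, <-i|
    bit <- bitwAnd(bitwShiftR(s, q - 1L), 1L)
    partner <- bitwXor(s, bitwShiftL(1L, q - 1L))
    out <- psi
    i0 <- which(bit == 0L); i1 <- which(bit == 1L)
    out[i0] <- U[1, 1] * psi[i0] + U[1, 2] * psi[partner[i0] + 1]
    out[i1] <- U[2, 1] * psi[partner[i1] + 1] + U[2, 2] * psi[i1]
    psi <- out
  }
  psi
}

# +-1 eigenvalue of word for each outcome bitstring
word_eigenvalues <- function(word, n_qubits) {
  sup <- which(strsplit(word, "")[[1]] != "I")
  s <- 0:(2^n_qubits - 1)
  z <- rep(1, length(s))
  for (q in sup) z <- z * (1 - 2 * bitwAnd(bitwShiftR(s, q - 1L), 1L))
  z
}

#' Sampled RDMs with optional readout noise and mitigation
#'
#' Executes the frozen-parameter circuit, measures every qubit-wise group of
#' the plan with multinomial shot sampling, optionally distorts outcome
#' distributions with a readout channel and corrects them with a calibration
#' model, and assembles symmetrized spin-summed RDMs with per-element
#' standard errors.
#'
#' @param circ frozen [circuit()].
#' @param theta frozen parameters.
#' @param plan a [measurement_plan()].
#' @param noise optional true readout channel (`calibration_model`).
#' @param calibration optional calibration used for mitigation (often the
#'   same model, or a finite-shot estimate of it).
#' @param seed RNG seed for shot sampling.
#' @param infinite_shots when `TRUE`, uses exact probabilities (no sampling);
#'   with no noise this reproduces [rdms_exact()] to numerical precision.
#' @return `spin_rdms` with `gamma_se` / `d_se` standard errors.
#' @export
rdms_sampled <- function(circ, theta, plan, noise = NULL, calibration = NULL,
                         seed = 1, infinite_shots = FALSE) {
  shots <- plan$shots_per_group
  psi <- apply_circuit(circ, theta)
  n <- plan$n_qubits
  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  word_exp <- c(); word_se <- c()
  for (g in plan$groups) {
    phi <- rotate_to_basis(psi, g$basis, n)
    p <- Mod(phi)^2
    p <- p / sum(p)
    if (!is.null(noise)) p <- as.numeric(noise$matrix %*% p)
    phat <- if (infinite_shots) p
            else as.numeric(stats::rmultinom(1, shots, p)) / shots
    if (!is.null(calibration)) phat <- mitigate(phat, calibration)
    for (w in g$words) {
      z <- word_eigenvalues(w, n)
      ev <- sum(phat * z)
      word_exp[w] <- ev
      word_se[w] <- if (infinite_shots) 0
                    else sqrt(max(1 - ev^2, 0) / shots)
    }
  }
  idw <- strrep("I", n)
  vals <- ses <- numeric(length(plan$ops))
  for (i in seq_along(plan$ops)) {
    op <- plan$ops[[i]]
    v <- 0; s2 <- 0
    for (k in seq_along(op$words)) {
      w <- op$words[k]; cf <- op$coeffs[k]
      if (w == idw) { v <- v + Re(cf); next }
      v <- v + Re(cf * word_exp[[w]])
      s2 <- s2 + Mod(cf)^2 * word_se[[w]]^2
    }
    vals[i] <- v; ses[i] <- sqrt(s2)
  }
  assemble_rdms(plan, vals, ses)
}

# energy from RDMs (Hartree): h0 + sum(gamma h1) + 1/2 sum(d h2)
rdm_energy <- function(problem, rdms) {
  problem$h0 + sum(rdms$gamma * problem$h1) + 0.5 * sum(rdms$d * problem$h2)
}
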