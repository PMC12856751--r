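# Variational minimization of a Pauli-form Hamiltonian over a circuit
# ansatz. Optimization always runs on the exact statevector expectation;
# shot noise enters only at the later measurement stage, mirroring the
# freeze-then-measure protocol.

#' Expectation value of a Pauli operator in a state
#'
#' @param op a [pauli_op()] (Hermitian for a physical observable).
#' @param psi complex statevector.
#' @return real expectation; an imaginary component above `1e-10` (relative)
#'   signals a non-Hermitian operator and errors.
#' @export
expectation <- function(op, psi) {
  if (2^op$n_qubits != length(psi))
    stop("register size mismatch: operator on ", op$n_qubits,
         " qubits, state of length ", length(psi))
  val <- sum(Conj(psi) * pauli_apply(op, psi))
  if (abs(Im(val)) > 1e-8 * max(1, abs(Re(val))))
    stop("expectation has a non-negligible imaginary part: ", Im(val))
  Re(val)
}

#' Minimize the energy of an ansatz over its parameters
#'
#' Quasi-Newton (BFGS) local minimization with multi-start: `n_restarts`
#' seeded starting points derived from `seed`, best result kept. The
#' reported iteration trace is the running best energy (monotone).
#'
#' @param hamiltonian [pauli_op()] on the ansatz register.
#' @param ansatz a [circuit()].
#' @param theta0 initial parameters (defaults to zeros).
#' @param max_iter BFGS iteration budget per start (0 returns the
#'   initial-point energy unoptimized).
#' @param tol convergence tolerance on the energy (Hartree).
#' @param n_restarts number of starts (first start is `theta0` itself).
#' @param seed master seed for the restart perturbations.
#' @param restart_spread standard deviation of the restart perturbations.
#' @return list (`vqe_result`): `theta`, `energy`, `trace`, `converged`,
#'   `n_eval`, `seed`.
#' @export
vqe_minimize <- function(hamiltonian, ansatz, theta0 = NULL, max_iter = 500,
                         tol = 1e-8, n_restarts = 3, seed = 1,
                         restart_spread = 0.1) {
  stopifnot(hamiltonian$n_qubits == ansatz$n_qubits)
  if (is.null(theta0)) theta0 <- numeric(ansatz$n_params)
  if (length(theta0) != ansatz$n_params)
    stop("theta0 has length ", length(theta0), ", ansatz needs ",
         ansatz$n_params)
  env <- new.env()
  env$trace <- numeric(0)
  env$best <- Inf
  efun <- function(theta) {
    e <- expectation(hamiltonian, apply_circuit(ansatz, theta))
    if (!is.finite(e)) return(1e6)
    env$best <- min(env$best, e)
    env$trace <- c(env$trace, env$best)
    e
  }
  if (ansatz$n_params == 0 || max_iter == 0) {
    e0 <- efun(theta0)
    return(structure(list(theta = theta0, energy = e0, trace = env$trace,
                          converged = ansatz$n_params == 0, n_eval = 1,
                          seed = seed),
                     class = "vqe_result"))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    th0 <- if (r == 1) theta0 else theta0 + rnorm(length(theta0), 0,
                                                  restart_spread)
    res <- tryCatch(
      stats::optim(th0, efun, method = "BFGS",
                   control = list(maxit = max_iter, reltol = tol / 10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("VQE optimization failed on every restart (NaN energies?)")
  structure(list(theta = best$par, energy = best$value, trace = env$trace,
                 converged = best$convergence == 0,
                 n_eval = length(env$trace), seed = seed),
            class = "vqe_result")
}

#' @export
print.vqe_result <- function(x, ...) {
  cat(sprintf("<vqe_result> E = %.10f Ha after %d evaluations (%s)\n",
              x$energy, x$n_eval,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
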