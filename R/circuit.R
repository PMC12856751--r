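# Deterministic statevector circuit engine. Qubit 1 is the least-significant
# bit of the basis-state index (little-endian); this convention is shared
# with the Pauli layer and asserted in the test suite.

#' Construct a parameterized circuit
#'
#' Gates are applied in list order to the initial computational basis state.
#' Supported gates: `X` (qubits = target), `RY` (target; angle), `CNOT`
#' (control, target), `CRY` (control, target; angle), `PAULI_EXP`
#' (`word`; applies `exp(-i angle/2 * P)`). A gate angle is either fixed
#' (`angle`) or bound to parameter `param_index` as
#' `angle = mult * theta[param_index]`.
#'
#' @param n_qubits register size.
#' @param gates list of gate specifications.
#' @param initial_state integer basis-state index (0-based) the circuit
#'   starts from.
#' @param meta optional free-form metadata list.
#' @return object of class `pdft_circuit`.
#' @export
circuit <- function(n_qubits, gates = list(), initial_state = 0L,
                    meta = list()) {
  pidx <- vapply(gates, function(g)
    if (is.null(g$param_index)) NA_integer_ else as.integer(g$param_index),
    integer(1))
  n_params <- if (all(is.na(pidx))) 0L else max(pidx, na.rm = TRUE)
  for (g in gates) {
    stopifnot(g$name %in% c("X", "RY", "CNOT", "CRY", "PAULI_EXP"))
    if (g$name != "PAULI_EXP") {
      stopifnot(all(g$qubits >= 1), all(g$qubits <= n_qubits),
                !anyDuplicated(g$qubits))
    }
  }
  structure(list(n_qubits = as.integer(n_qubits), gates = gates,
                 n_params = n_params, initial_state = as.integer(initial_state),
                 meta = meta),
            class = "pdft_circuit")
}

#' @export
print.pdft_circuit <- function(x, ...) {
  cat(sprintf("<pdft_circuit> %d qubits, %d gates, %d parameters, depth %d\n",
              x$n_qubits, length(x$gates), x$n_params, circuit_depth(x)))
  invisible(x)
}

gate_qubits <- function(g, n_qubits) {
  if (g$name == "PAULI_EXP") {
    which(strsplit(g$word, "")[[1]] != "I")
  } else g$qubits
}

#' Apply a circuit to obtain the statevector
#'
#' @param circ a [circuit()].
#' @param theta numeric parameter vector of length `circ$n_params`.
#' @return complex amplitude vector of length `2^n_qubits`.
#' @export
apply_circuit <- function(circ, theta = numeric(0)) {
  if (length(theta) != circ$n_params)
    stop("parameter count mismatch: circuit has ", circ$n_params,
         ", got ", length(theta))
  n <- circ$n_qubits
  psi <- complex(2^n)
  psi[circ$initial_state + 1] <- 1
  s <- 0:(2^n - 1)
  for (g in circ$gates) {
    ang <- if (!is.null(g$param_index) && !is.na(g$param_index)) {
      m <- if (is.null(g$mult)) 1 else g$mult
      m * theta[g$param_index]
    } else if (!is.null(g$angle)) g$angle else 0
    psi <- switch(g$name,
      X = {
        q <- g$qubits[1]
        psi[bitwXor(s, bitwShiftL(1L, q - 1L)) + 1]
      },
      RY = {
        q <- g$qubits[1]
        bit <- bitwAnd(bitwShiftR(s, q - 1L), 1L)
        partner <- bitwXor(s, bitwShiftL(1L, q - 1L))
        c0 <- cos(ang / 2); s0 <- sin(ang / 2)
        out <- psi
        i0 <- which(bit == 0L); i1 <- which(bit == 1L)
        out[i0] <- c0 * psi[i0] - s0 * psi[partner[i0] + 1]
        out[i1] <- s0 * psi[partner[i1] + 1] + c0 * psi[i1]
        out
      },
      CNOT = {
        ctrl <- g$qubits[1]; tgt <- g$qubits[2]
        on <- bitwAnd(bitwShiftR(s, ctrl - 1L), 1L) == 1L
        out <- psi
        src <- bitwXor(s[on], bitwShiftL(1L, tgt - 1L))
        out[s[on] + 1] <- psi[src + 1]
        out
      },
      CRY = {
        ctrl <- g$qubits[1]; tgt <- g$qubits[2]
        c0 <- cos(ang / 2); s0 <- sin(ang / 2)
        on <- bitwAnd(bitwShiftR(s, ctrl - 1L), 1L) == 1L
        bit <- bitwAnd(bitwShiftR(s, tgt - 1L), 1L)
        partner <- bitwXor(s, bitwShiftL(1L, tgt - 1L))
        out <- psi
        i0 <- which(on & bit == 0L); i1 <- which(on & bit == 1L)
        out[i0] <- c0 * psi[i0] - s0 * psi[partner[i0] + 1]
        out[i1] <- s0 * psi[partner[i1] + 1] + c0 * psi[i1]
        out
      },
      PAULI_EXP = {
        act <- pauli_word_action(g$word, n)
        ppsi <- complex(length(psi))
        ppsi[act$target + 1] <- act$phase * psi
        cos(ang / 2) * psi - 1i * sin(ang / 2) * ppsi
      },
      stop("unknown gate ", g$name))
  }
  psi
}

#' Logical circuit depth (parallel moments)
#'
#' Gates are packed greedily to the left; gates sharing any qubit occupy
#' distinct moments.
#'
#' @param circ a [circuit()].
#' @return integer moment count.
#' @export
circuit_depth <- function(circ) {
  avail <- integer(circ$n_qubits)
  d <- 0L
  for (g in circ$gates) {
    qs <- gate_qubits(g, circ$n_qubits)
    m <- if (length(qs)) max(avail[qs]) + 1L else 1L
    avail[qs] <- m
    d <- max(d, m)
  }
  d
}

#' Serialize a circuit to JSON (and back)
#'
#' @param circ a [circuit()].
#' @param path optional file path.
#' @return JSON string, invisibly when written to `path`.
#' @export
circuit_to_json <- function(circ, path = NULL) {
  gl <- lapply(circ$gates, function(g) {
    out <- list(name = g$name)
    if (!is.null(g$qubits)) out$qubits <- as.integer(g$qubits)
    if (!is.null(g$word)) out$word <- g$word
    if (!is.null(g$angle)) out$angle <- g$angle
    if (!is.null(g$param_index) && !is.na(g$param_index)) {
      out$param_index <- as.integer(g$param_index)
      out$mult <- if (is.null(g$mult)) 1 else g$mult
    }
    out
  })
  js <- jsonlite::toJSON(
    list(n_qubits = circ$n_qubits, initial_state = circ$initial_state,
         gates = gl, meta = circ$meta),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname circuit_to_json
#' @param json JSON string or file path.
#' @export
circuit_from_json <- function(json) {
  src <- if (length(json) == 1 && file.exists(json)) json else json
  p <- jsonlite::fromJSON(src, simplifyVector = FALSE)
  gates <- lapply(p$gates, function(g) {
    g$qubits <- if (!is.null(g$qubits)) unlist(g$qubits)
    g
  })
  circuit(p$n_qubits, gates, initial_state = p$initial_state,
          meta = if (is.null(p$meta)) list() else p$meta)
}
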