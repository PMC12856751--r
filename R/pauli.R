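# Pauli-string algebra. A PauliOperator is a weighted sum of Pauli words;
# word position i (1-based) is the letter on qubit i, and qubit 1 is the
# least-significant bit of the statevector index (little-endian).

#' Construct a Pauli operator
#'
#' @param words character vector of Pauli words over `{I,X,Y,Z}`; position i
#'   is qubit i.
#' @param coeffs complex (or numeric) coefficients, recycled if scalar.
#' @param n_qubits register size; defaults to the word length.
#' @return object of class `pauli_op`; duplicate words are combined and
#'   negligible terms dropped.
#' @export
pauli_op <- function(words, coeffs, n_qubits = NULL) {
  if (length(words) == 0) {
    stopifnot(!is.null(n_qubits))
    return(structure(list(words = character(0), coeffs = complex(0),
                          n_qubits = as.integer(n_qubits)),
                     class = "pauli_op"))
  }
  if (is.null(n_qubits)) n_qubits <- nchar(words[1])
  stopifnot(all(nchar(words) == n_qubits),
            !grepl("[^IXYZ]", paste(words, collapse = "")))
  coeffs <- rep_len(as.complex(coeffs), length(words))
  agg <- tapply(coeffs, words, sum)
  keep <- Mod(agg) > 1e-14
  w <- names(agg)[keep]
  ord <- order(w)
  structure(list(words = w[ord], coeffs = as.complex(agg[keep][ord]),
                 n_qubits = as.integer(n_qubits)),
            class = "pauli_op")
}

#' @export
print.pauli_op <- function(x, ...) {
  cat(sprintf("<pauli_op> %d terms on %d qubits\n",
              length(x$words), x$n_qubits))
  n <- min(length(x$words), 8)
  for (i in seq_len(n))
    cat(sprintf("  %s  %s\n", format(x$coeffs[i], digits = 6), x$words[i]))
  if (length(x$words) > n) cat("  ...\n")
  invisible(x)
}

pauli_identity <- function(n_qubits, coeff = 1) {
  pauli_op(strrep("I", n_qubits), coeff, n_qubits)
}

#' @export
`+.pauli_op` <- function(e1, e2) {
  stopifnot(e1$n_qubits == e2$n_qubits)
  pauli_op(c(e1$words, e2$words), c(e1$coeffs, e2$coeffs), e1$n_qubits)
}

pauli_scale <- function(op, s) {
  pauli_op(op$words, op$coeffs * s, op$n_qubits)
}

# single-letter product table: result letter and phase
.pauli_prod_letter <- local({
  L <- c("I", "X", "Y", "Z")
  res <- matrix("", 4, 4, dimnames = list(L, L))
  ph <- matrix(complex(real = 1), 4, 4, dimnames = list(L, L))
  res["I", ] <- L; res[, "I"] <- L
  for (l in L) res[l, l] <- "I"
  res["X", "Y"] <- "Z"; ph["X", "Y"] <- 1i
  res["Y", "X"] <- "Z"; ph["Y", "X"] <- -1i
  res["Y", "Z"] <- "X"; ph["Y", "Z"] <- 1i
  res["Z", "Y"] <- "X"; ph["Z", "Y"] <- -1i
  res["Z", "X"] <- "Y"; ph["Z", "X"] <- 1i
  res["X", "Z"] <- "Y"; ph["X", "Z"] <- -1i
  list(res = res, ph = ph)
})

pauli_word_mult <- function(w1, w2) {
  a <- strsplit(w1, "")[[1]]
  b <- strsplit(w2, "")[[1]]
  letters_out <- .pauli_prod_letter$res[cbind(a, b)]
  phase <- prod(.pauli_prod_letter$ph[cbind(a, b)])
  list(word = paste(letters_out, collapse = ""), phase = phase)
}

pauli_mult <- function(A, B) {
  stopifnot(A$n_qubits == B$n_qubits)
  words <- character(0); coeffs <- complex(0)
  for (i in seq_along(A$words)) for (j in seq_along(B$words)) {
    pm <- pauli_word_mult(A$words[i], B$words[j])
    words <- c(words, pm$word)
    coeffs <- c(coeffs, A$coeffs[i] * B$coeffs[j] * pm$phase)
  }
  pauli_op(words, coeffs, A$n_qubits)
}

# action of a single Pauli word on index vector 0..2^n-1:
# returns flipped indices and per-index phases
pauli_word_action <- function(word, n_qubits) {
  letters_w <- strsplit(word, "")[[1]]
  s <- 0:(2^n_qubits - 1)
  mask <- 0L
  phase <- rep(complex(real = 1), length(s))
  for (q in seq_len(n_qubits)) {
    l <- letters_w[q]
    if (l == "X" || l == "Y") mask <- bitwOr(mask, bitwShiftL(1L, q - 1L))
    if (l == "Y" || l == "Z") {
      bit <- bitwAnd(bitwShiftR(s, q - 1L), 1L)
      if (l == "Z") phase <- phase * (1 - 2 * bit)
      else phase <- phase * 1i * (1 - 2 * bit)
    }
  }
  list(target = bitwXor(s, mask), phase = phase)
}

# op |psi>  (psi complex vector of length 2^n)
pauli_apply <- function(op, psi) {
  out <- complex(length(psi))
  for (i in seq_along(op$words)) {
    act <- pauli_word_action(op$words[i], op$n_qubits)
    out[act$target + 1] <- out[act$target + 1] + op$coeffs[i] * act$phase * psi
  }
  out
}

# dense matrix representation (oracle/testing path; n <= ~10)
pauli_matrix <- function(op) {
  n <- op$n_qubits
  dim <- 2^n
  M <- matrix(complex(real = 0), dim, dim)
  for (i in seq_along(op$words)) {
    act <- pauli_word_action(op$words[i], n)
    M[cbind(act$target + 1, 1:dim)] <-
      M[cbind(act$target + 1, 1:dim)] + op$coeffs[i] * act$phase
  }
  M
}

is_hermitian_pauli <- function(op, tol = 1e-10) {
  all(abs(Im(op$coeffs)) < tol)
}

#' Serialize / parse a Pauli operator as plain text
#'
#' One `coefficient word` per line, e.g. `0.5 ZZII`. Complex coefficients are
#' written as `re+imi`.
#'
#' @param op a [pauli_op()].
#' @param path optional file; when `NULL` the lines are returned.
#' @return character lines (invisibly when written to file).
#' @export
pauli_to_text <- function(op, path = NULL) {
  fmt <- function(z) {
    if (abs(Im(z)) < 1e-14) sprintf("%.16g", Re(z))
    else sprintf("%.16g%+.16gi", Re(z), Im(z))
  }
  lines_out <- vapply(seq_along(op$words),
                      function(i) paste(fmt(op$coeffs[i]), op$words[i]),
                      "")
  if (!is.null(path)) {
    writeLines(lines_out, path)
    return(invisible(lines_out))
  }
  lines_out
}

#' @rdname pauli_to_text
#' @param lines character lines or a file path (when `length(lines) == 1`
#'   and the file exists).
#' @export
pauli_from_text <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  coeffs <- vapply(parts, function(p) {
    z <- p[1]
    if (grepl("i$", z)) as.complex(z) else complex(real = as.numeric(z))
  }, complex(1))
  words <- vapply(parts, `[[`, "", 2)
  pauli_op(words, coeffs)
}
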