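# Qubit-wise commuting measurement grouping: two Pauli words can share one
# measurement setting when, qubit by qubit, their letters agree or one is I.
# E.g. ZZII and IIZZ are both readable from a single ZZZZ measurement.

qubitwise_compatible <- function(w1, w2) {
  a <- strsplit(w1, "")[[1]]
  b <- strsplit(w2, "")[[1]]
  all(a == b | a == "I" | b == "I")
}

merge_basis <- function(basis, word) {
  a <- strsplit(basis, "")[[1]]
  b <- strsplit(word, "")[[1]]
  a[a == "I"] <- b[a == "I"]
  paste(a, collapse = "")
}

#' Group Pauli words into simultaneous measurement settings
#'
#' Greedy first-fit over the words in deterministic lexicographic order:
#' each word joins the first existing group whose letters are compatible
#' (equal or identity) on every qubit, otherwise starts a new group. The
#' identity word, if present, joins the first group (it is measurable in any
#' basis).
#'
#' @param words character vector of Pauli words (one register size).
#' @return list of groups, each `list(basis, words)` where `basis` is the
#'   combined measurement word.
#' @export
group_qubitwise <- function(words) {
  stopifnot(length(unique(nchar(words))) <= 1)
  words <- sort(unique(words))
  groups <- list()
  for (w in words) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (qubitwise_compatible(groups[[gi]]$basis, w)) {
        groups[[gi]]$words <- c(groups[[gi]]$words, w)
        groups[[gi]]$basis <- merge_basis(groups[[gi]]$basis, w)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      groups[[length(groups) + 1]] <- list(basis = w, words = w)
  }
  groups
}

#' Serialize a measurement plan to JSON
#'
#' @param groups output of [group_qubitwise()].
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
groups_to_json <- function(groups, path = NULL) {
  js <- jsonlite::toJSON(groups, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname groups_to_json
#' @param json JSON string or path.
#' @export
groups_from_json <- function(json) {
  parsed <- if (length(json) == 1 && file.exists(json))
    jsonlite::fromJSON(json, simplifyVector = FALSE)
  else jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(parsed, function(g)
    list(basis = g$basis, words = unlist(g$words)))
}
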