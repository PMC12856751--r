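# Persistence: active-space problems and RDMs to HDF5 (via rhdf5 when
# available), counts/calibration tables and run reports as JSON.

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 serialization requires the 'rhdf5' package")
}

#' Write / read an active-space problem to HDF5
#'
#' Datasets: `h0`, `h1`, `h2`, `mo_coeff`, `core_density`; attributes carry
#' the basis name and the (N_e, N_o, N_alpha, N_beta) pattern. The
#' real-space backend (geometry and integral tables) is not persisted:
#' problems restored from file support everything except grid-based
#' functional evaluation.
#'
#' @param problem a `pdft_problem`.
#' @param path output file.
#' @export
problem_to_hdf5 <- function(problem, path) {
  require_rhdf5()
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(problem$h0, path, "h0")
  rhdf5::h5write(problem$h1, path, "h1")
  rhdf5::h5write(problem$h2, path, "h2")
  if (!is.null(problem$mo_coeff))
    rhdf5::h5write(problem$mo_coeff, path, "mo_coeff")
  if (!is.null(problem$core_density))
    rhdf5::h5write(problem$core_density, path, "core_density")
  spec <- problem$spec
  rhdf5::h5write(c(spec$n_electrons, spec$n_orbitals, spec$n_alpha,
                   spec$n_beta), path, "spec")
  rhdf5::h5write(problem$basis, path, "basis")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname problem_to_hdf5
#' @export
problem_from_hdf5 <- function(path) {
  require_rhdf5()
  s <- as.integer(rhdf5::h5read(path, "spec"))
  spec <- active_space_spec(s[1], s[2], s[3], s[4])
  ls <- rhdf5::h5ls(path)$name
  pr <- problem_from_integrals(
    as.numeric(rhdf5::h5read(path, "h0")),
    rhdf5::h5read(path, "h1"),
    rhdf5::h5read(path, "h2"), spec,
    basis = as.character(rhdf5::h5read(path, "basis")))
  if ("mo_coeff" %in% ls) pr$mo_coeff <- rhdf5::h5read(path, "mo_coeff")
  if ("core_density" %in% ls)
    pr$core_density <- rhdf5::h5read(path, "core_density")
  rhdf5::h5closeAll()
  pr
}

#' Write / read spin-summed RDMs to HDF5
#'
#' @param rdms a `spin_rdms`.
#' @param path file path.
#' @export
rdms_to_hdf5 <- function(rdms, path) {
  require_rhdf5()
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rdms$gamma, path, "gamma")
  rhdf5::h5write(rdms$d, path, "d")
  rhdf5::h5write(rdms$convention, path, "convention")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname rdms_to_hdf5
#' @export
rdms_from_hdf5 <- function(path) {
  require_rhdf5()
  out <- structure(list(gamma = rhdf5::h5read(path, "gamma"),
                        d = rhdf5::h5read(path, "d"),
                        convention = as.character(
                          rhdf5::h5read(path, "convention"))),
                   class = "spin_rdms")
  rhdf5::h5closeAll()
  out
}

#' Counts / calibration tables as JSON (bitstring -> count)
#'
#' @param counts named integer vector, names are bitstrings (qubit 1 first).
#' @param path optional file.
#' @export
counts_to_json <- function(counts, path = NULL) {
  js <- jsonlite::toJSON(as.list(counts), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname counts_to_json
#' @param json JSON string or file path.
#' @export
counts_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  unlist(x)
}
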