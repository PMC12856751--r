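#' Molecular geometry with optional embedding point charges
#'
#' Constructs a validated molecular geometry. Coordinates are given in
#' Angstrom and converted to Bohr internally by the integral layer. Optional
#' background point charges provide a minimal electrostatic-embedding
#' surrogate for a surrounding classical environment: their potential enters
#' the one-electron Hamiltonian, and nuclear-charge plus charge-charge
#' Coulomb terms are added to the constant energy.
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix (n_atoms x 3) of Cartesian positions, Angstrom.
#' @param charge integer net charge.
#' @param spin integer N_alpha - N_beta.
#' @param point_charges optional numeric matrix with columns x, y, z, q
#'   (Angstrom, elementary charge).
#' @return object of class `pdft_geometry`.
#' @export
geometry <- function(atoms, coords, charge = 0L, spin = 0L,
                     point_charges = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(atoms) == nrow(coords))
  if (!all(is.finite(coords))) stop("geometry: non-finite coordinates")
  if (!all(atoms %in% names(ELEMENT_Z)))
    stop("geometry: unknown element(s): ",
         paste(setdiff(atoms, names(ELEMENT_Z)), collapse = ", "))
  nelec <- sum(ELEMENT_Z[atoms]) - charge
  if ((nelec - spin) %% 2 != 0)
    stop("geometry: spin ", spin, " inconsistent with ", nelec, " electrons")
  if (!is.null(point_charges)) {
    point_charges <- matrix(as.numeric(point_charges), ncol = 4)
    for (i in seq_len(nrow(point_charges))) {
      d <- sqrt(rowSums((coords - matrix(point_charges[i, 1:3],
                                         nrow(coords), 3, byrow = TRUE))^2))
      if (any(d < 1e-6))
        stop("geometry: point charge ", i, " coincides with a nucleus")
    }
  }
  structure(list(atoms = atoms, coords = coords, charge = as.integer(charge),
                 spin = as.integer(spin), point_charges = point_charges,
                 n_electrons = as.integer(nelec)),
            class = "pdft_geometry")
}

#' @export
print.pdft_geometry <- function(x, ...) {
  cat(sprintf("<pdft_geometry> %d atoms, charge %d, spin %d, %d electrons\n",
              length(x$atoms), x$charge, x$spin, x$n_electrons))
  if (!is.null(x$point_charges))
    cat(sprintf("  + %d background point charges\n", nrow(x$point_charges)))
  invisible(x)
}

#' Read a standard XYZ file
#'
#' First line: atom count; second line: comment (ignored); then one
#' `element x y z` line per atom, coordinates in Angstrom.
#'
#' @param path file path.
#' @inheritParams geometry
#' @return `pdft_geometry`.
#' @export
read_xyz <- function(path, charge = 0L, spin = 0L, point_charges = NULL) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- ln[seq(3, 2 + n)]
  tok <- strsplit(trimws(rows), "\\s+")
  atoms <- vapply(tok, `[[`, "", 1)
  coords <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  geometry(atoms, coords, charge, spin, point_charges)
}

#' Read a point-charge file
#'
#' Whitespace-separated `x y z q` lines (Angstrom, elementary charge);
#' blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return numeric matrix with columns x, y, z, q.
#' @export
read_point_charges <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  m <- t(vapply(strsplit(ln, "\\s+"),
                function(t) as.numeric(t[1:4]), numeric(4)))
  colnames(m) <- c("x", "y", "z", "q")
  m
}

# nuclear repulsion + nuclear-charge + charge-charge energies (Hartree)
nuclear_energy <- function(geom) {
  xyz <- geom$coords * pdft_constants$ang2bohr
  Z <- ELEMENT_Z[geom$atoms]
  e <- 0
  n <- nrow(xyz)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      e <- e + Z[i] * Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  if (!is.null(geom$point_charges)) {
    q <- geom$point_charges[, 4]
    cxyz <- geom$point_charges[, 1:3, drop = FALSE] * pdft_constants$ang2bohr
    for (i in seq_len(n)) for (k in seq_along(q)) {
      e <- e + Z[i] * q[k] / sqrt(sum((xyz[i, ] - cxyz[k, ])^2))
    }
    if (length(q) > 1) {
      for (k in seq_len(length(q) - 1)) for (l in seq(k + 1, length(q))) {
        e <- e + q[k] * q[l] / sqrt(sum((cxyz[k, ] - cxyz[l, ])^2))
      }
    }
  }
  unname(e)
}
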