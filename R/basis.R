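# Built-in Gaussian basis sets (exponents / contraction coefficients from the
# Basis Set Exchange, Pople forms). Sufficient for the packaged fixtures:
# H2 scans, allyl pi systems, small closed-shell dimers.

BASIS_LIBRARY <- list(
  "sto-3g" = list(
    H = list(list(l = 0, e = c(3.42525091, 0.62391373, 0.16885540),
                  c = c(0.15432897, 0.53532814, 0.44463454))),
    C = list(list(l = 0, e = c(71.6168370, 13.0450960, 3.5305122),
                  c = c(0.15432897, 0.53532814, 0.44463454)),
             list(l = 0, e = c(2.9412494, 0.6834831, 0.2222899),
                  c = c(-0.09996723, 0.39951283, 0.70011547)),
             list(l = 1, e = c(2.9412494, 0.6834831, 0.2222899),
                  c = c(0.15591627, 0.60768372, 0.39195739))),
    N = list(list(l = 0, e = c(99.1061690, 18.0523120, 4.8856602),
                  c = c(0.15432897, 0.53532814, 0.44463454)),
             list(l = 0, e = c(3.7804559, 0.8784966, 0.2857144),
                  c = c(-0.09996723, 0.39951283, 0.70011547)),
             list(l = 1, e = c(3.7804559, 0.8784966, 0.2857144),
                  c = c(0.15591627, 0.60768372, 0.39195739))),
    O = list(list(l = 0, e = c(130.7093200, 23.8088610, 6.4436083),
                  c = c(0.15432897, 0.53532814, 0.44463454)),
             list(l = 0, e = c(5.0331513, 1.1695961, 0.3803890),
                  c = c(-0.09996723, 0.39951283, 0.70011547)),
             list(l = 1, e = c(5.0331513, 1.1695961, 0.3803890),
                  c = c(0.15591627, 0.60768372, 0.39195739)))
  ),
  "6-31g" = list(
    H = list(list(l = 0, e = c(18.7311370, 2.8253937, 0.6401217),
                  c = c(0.03349460, 0.23472695, 0.81375733)),
             list(l = 0, e = 0.1612778, c = 1.0)),
    C = list(list(l = 0,
                  e = c(3047.5249, 457.36951, 103.94869, 29.210155,
                        9.2866630, 3.1639270),
                  c = c(0.0018347, 0.0140373, 0.0688426, 0.2321844,
                        0.4679413, 0.3623120)),
             list(l = 0, e = c(7.8682724, 1.8812885, 0.5442493),
                  c = c(-0.1193324, -0.1608542, 1.1434564)),
             list(l = 1, e = c(7.8682724, 1.8812885, 0.5442493),
                  c = c(0.0689991, 0.3164240, 0.7443083)),
             list(l = 0, e = 0.1687144, c = 1.0),
             list(l = 1, e = 0.1687144, c = 1.0)),
    N = list(list(l = 0,
                  e = c(4173.5110, 627.45790, 142.90210, 40.234330,
                        12.820210, 4.3904370),
                  c = c(0.0018348, 0.0139950, 0.0685870, 0.2322410,
                        0.4690700, 0.3604550)),
             list(l = 0, e = c(11.6263580, 2.7162800, 0.7722180),
                  c = c(-0.1149610, -0.1691180, 1.1458520)),
             list(l = 1, e = c(11.6263580, 2.7162800, 0.7722180),
                  c = c(0.0675800, 0.3239070, 0.7408950)),
             list(l = 0, e = 0.2120313, c = 1.0),
             list(l = 1, e = 0.2120313, c = 1.0)),
    O = list(list(l = 0,
                  e = c(5484.6717, 825.23495, 188.04696, 52.964500,
                        16.897570, 5.7996353),
                  c = c(0.0018311, 0.0139501, 0.0684451, 0.2327143,
                        0.4701930, 0.3585209)),
             list(l = 0, e = c(15.5396160, 3.5999336, 1.0137618),
                  c = c(-0.1107775, -0.1480263, 1.1307670)),
             list(l = 1, e = c(15.5396160, 3.5999336, 1.0137618),
                  c = c(0.0708743, 0.3397528, 0.7271586)),
             list(l = 0, e = 0.2700058, c = 1.0),
             list(l = 1, e = 0.2700058, c = 1.0))
  )
)

#' List or construct a basis set for a geometry
#'
#' @param geom a [geometry()].
#' @param basis basis-set name (case-insensitive); one of
#'   `r paste(names(BASIS_LIBRARY), collapse = ", ")`.
#' @return list of shells (`center` in Bohr, `l`, `exponents`,
#'   `coefficients`) plus per-shell atom indices, as used by the integral
#'   engine.
#' @keywords internal
build_basis <- function(geom, basis) {
  bname <- tolower(basis)
  if (!bname %in% names(BASIS_LIBRARY))
    stop("unknown basis '", basis, "'; available: ",
         paste(names(BASIS_LIBRARY), collapse = ", "))
  lib <- BASIS_LIBRARY[[bname]]
  missing <- setdiff(unique(geom$atoms), names(lib))
  if (length(missing))
    stop("basis '", basis, "' not tabulated for: ",
         paste(missing, collapse = ", "))
  shells <- list()
  shell_atom <- integer(0)
  ao_atom <- integer(0)
  for (ia in seq_along(geom$atoms)) {
    ctr <- geom$coords[ia, ] * pdft_constants$ang2bohr
    for (sh in lib[[geom$atoms[ia]]]) {
      shells[[length(shells) + 1L]] <-
        list(center = ctr, l = sh$l, exponents = sh$e, coefficients = sh$c)
      shell_atom <- c(shell_atom, ia)
      ncomp <- (sh$l + 1L) * (sh$l + 2L) / 2L
      ao_atom <- c(ao_atom, rep(ia, ncomp))
    }
  }
  list(shells = shells, shell_atom = shell_atom, ao_atom = ao_atom,
       name = bname)
}

# one-electron integrals (+ dipole) and ERI array for a geometry/basis
compute_integrals <- function(geom, basis, two_electron = TRUE) {
  b <- build_basis(geom, basis)
  xyz <- geom$coords * pdft_constants$ang2bohr
  Z <- as.numeric(ELEMENT_Z[geom$atoms])
  if (is.null(geom$point_charges)) {
    cxyz <- matrix(0, 0, 3); cq <- numeric(0)
  } else {
    cxyz <- geom$point_charges[, 1:3, drop = FALSE] * pdft_constants$ang2bohr
    cq <- geom$point_charges[, 4]
  }
  one <- .int1e_cpp(b$shells, xyz, Z, cxyz, cq)
  eri <- if (two_electron) .int2e_cpp(b$shells) else NULL
  list(S = one$S, T = one$T, V = one$V, hcore = one$T + one$V,
       dip = one$dip, eri = eri, nbf = one$nbf, basis = b,
       enuc = nuclear_energy(geom))
}
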