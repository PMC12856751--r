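#' Physical constants and unit conversions
#'
#' Internal unit system is Hartree/Bohr; user-facing geometry input is in
#' Angstrom and electron-transfer quantities in eV.
#'
#' @format Named list with elements `ang2bohr`, `hartree2ev`, `hartree2kcal`,
#'   `hbar_eVs` (reduced Planck constant, eV s), `kB_eVK` (Boltzmann constant,
#'   eV/K).
#' @export
pdft_constants <- list(
  ang2bohr     = 1 / 0.52917721092,
  hartree2ev   = 27.211386,
  hartree2kcal = 627.5094740631,
  hbar_eVs     = 6.582119569e-16,
  kB_eVK       = 8.617333262e-5
)

ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
               S = 16, Cl = 17, Ar = 18)

# Bragg-Slater radii (Angstrom) used by the Becke grid partitioning
BRAGG_RADII <- c(H = 0.35, He = 0.35, Li = 1.45, Be = 1.05, B = 0.85,
                 C = 0.70, N = 0.65, O = 0.60, F = 0.50, Ne = 0.45,
                 Na = 1.80, Mg = 1.50, Al = 1.25, Si = 1.10, P = 1.00,
                 S = 1.00, Cl = 1.00, Ar = 1.00)
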