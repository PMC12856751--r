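# Marcus electron-transfer layer: four-point reorganization energy and
# driving force, nonadiabatic rate, direct-coupling electronic coupling,
# ensemble statistics, and the noise-propagation (error-cancellation) study.

#' Four-point reorganization energy and driving force
#'
#' Takes the four state/geometry single-point energies (Hartree) and applies
#'   dG0    = |E^i_i - E^f_f|
#'   lambda = |E^i_f - E^i_i| + |E^f_i - E^f_f|
#' where superscripts label the geometry and subscripts the electronic
#' state ("i" initial, "f" final). Results are converted to eV.
#'
#' @param e 2x2 numeric matrix: rows = geometry (initial, final), columns =
#'   state (initial, final); i.e. `e["initial","final"]` is E^i_f.
#' @return list with `lambda` and `dG` in eV (both non-negative).
#' @export
four_point <- function(e) {
  e <- as.matrix(e)
  stopifnot(all(dim(e) == c(2, 2)), all(is.finite(e)))
  if (!is.null(rownames(e))) e <- e[c("initial", "final"), ]
  if (!is.null(colnames(e))) e <- e[, c("initial", "final")]
  ha2ev <- pdft_constants$hartree2ev
  dG <- abs(e[1, 1] - e[2, 2]) * ha2ev
  lambda <- (abs(e[1, 2] - e[1, 1]) + abs(e[2, 1] - e[2, 2])) * ha2ev
  list(lambda = lambda, dG = dG)
}

#' Four-point energies from a fragment table
#'
#' The four points a-d each consist of a donor-fragment and an
#' acceptor-fragment single-point energy whose sum is the point's total:
#' a = initial state at initial geometry, b = final state at initial
#' geometry, c = final state at final geometry, d = initial state at final
#' geometry.
#'
#' @param tab data frame with columns `point` (one of "a","b","c","d") and
#'   `energy` (Hartree); several rows per point are summed.
#' @return 2x2 energy matrix suitable for [four_point()], with fragment sums
#'   as attribute `point_totals`.
#' @export
four_point_from_fragments <- function(tab) {
  stopifnot(all(c("point", "energy") %in% names(tab)))
  tot <- tapply(tab$energy, tab$point, sum)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tot)))
  e <- matrix(c(tot["a"], tot["d"], tot["b"], tot["c"]), 2, 2,
              dimnames = list(c("initial", "final"),
                              c("initial", "final")))
  attr(e, "point_totals") <- tot
  e
}

#' Nonadiabatic Marcus electron-transfer rate
#'
#' k = (2 pi / hbar) <|H_DA|^2> (4 pi lambda k_B T)^(-1/2)
#'     exp(-(dG0 + lambda)^2 / (4 lambda k_B T))
#' with the driving force entering as its positive magnitude.
#'
#' @param lambda reorganization energy (eV, > 0).
#' @param dG driving force magnitude (eV, >= 0).
#' @param mean_sq_coupling ensemble mean of `|H_DA|^2` (eV^2).
#' @param temperature Kelvin (default 300).
#' @return rate in s^-1.
#' @export
marcus_rate <- function(lambda, dG, mean_sq_coupling, temperature = 300) {
  stopifnot(mean_sq_coupling >= 0, temperature > 0, dG >= 0)
  if (lambda <= 0) stop("marcus_rate: lambda must be positive (singular)")
  kT <- pdft_constants$kB_eVK * temperature
  pref <- (2 * pi / pdft_constants$hbar_eVs) * mean_sq_coupling /
    sqrt(4 * pi * lambda * kT)
  pref * exp(-(dG + lambda)^2 / (4 * lambda * kT))
}

#' Direct-coupling electronic coupling from localized-orbital elements
#'
#' H_DA = (T_DA - (e_D + e_A) S_DA / 2) / (1 - S_DA^2).
#'
#' @param T_DA Hamiltonian coupling element (eV).
#' @param S_DA donor-acceptor overlap (|S_DA| < 1).
#' @param e_D,e_A localized donor/acceptor orbital energies (eV).
#' @return H_DA in eV.
#' @export
direct_coupling <- function(T_DA, S_DA, e_D, e_A) {
  if (abs(S_DA) >= 1) stop("direct_coupling: |S_DA| >= 1 is singular")
  (T_DA - (e_D + e_A) * S_DA / 2) / (1 - S_DA^2)
}

#' Ensemble averages of Marcus parameters and the resulting rate
#'
#' Arithmetic means of lambda, dG0, |H_DA| and |H_DA|^2 over conformations;
#' the rate uses the mean-square coupling (not the squared mean).
#'
#' @param params list of per-conformation lists with elements `lambda`,
#'   `dG` and (optionally) `H_DA` (all eV).
#' @param temperature Kelvin.
#' @return list with the means, dispersions (sd), and `k_ET` when couplings
#'   are present.
#' @export
ensemble_average <- function(params, temperature = 300) {
  if (length(params) == 0) stop("ensemble_average: empty parameter list")
  lam <- vapply(params, `[[`, numeric(1), "lambda")
  dg <- vapply(params, `[[`, numeric(1), "dG")
  hda <- vapply(params, function(p)
    if (is.null(p$H_DA)) NA_real_ else abs(p$H_DA), numeric(1))
  out <- list(lambda = mean(lam), dG = mean(dg),
              lambda_sd = stats::sd(lam), dG_sd = stats::sd(dg),
              n = length(params), temperature = temperature)
  if (!anyNA(hda)) {
    out$H_DA <- mean(hda)
    out$H_DA_sq <- mean(hda^2)
    out$k_ET <- marcus_rate(out$lambda, out$dG, out$H_DA_sq, temperature)
  }
  out
}

#' Noise propagation through the four-point energy differences
#'
#' Monte-Carlo study of how single-point energy errors propagate into the
#' Marcus parameters. For each seed the eight fragment energies receive an
#' error drawn from the chosen model, the four-point scheme is re-applied,
#' and the parameter errors are compared against the mean single-point
#' error; systematic (shared) components cancel in the differences.
#'
#' @param fragment_tab baseline fragment table (see
#'   [four_point_from_fragments()]), 8 rows.
#' @param model `"systematic"` (one shared offset per seed), `"iid"`
#'   (independent zero-mean errors), or `"correlated"` (shared offset plus
#'   small independent jitter).
#' @param offset_sigma sd of the shared offset (Hartree).
#' @param jitter_sigma sd of the per-fragment jitter (Hartree).
#' @param n_seeds Monte-Carlo replicates.
#' @param seed master seed.
#' @return list with per-seed errors and summary statistics (eV), including
#'   `cancellation_fraction`: share of seeds where both parameter errors are
#'   below the mean single-point error.
#' @export
noise_propagation_study <- function(fragment_tab, model = "correlated",
                                    offset_sigma = 0.065,
                                    jitter_sigma = 0.005,
                                    n_seeds = 100, seed = 1) {
  model <- match.arg(model, c("systematic", "iid", "correlated"))
  base <- four_point(four_point_from_fragments(fragment_tab))
  ha2ev <- pdft_constants$hartree2ev
  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  sp_err <- lam_err <- dg_err <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    delta <- switch(model,
      systematic = rep(stats::rnorm(1, 0, offset_sigma), nrow(fragment_tab)),
      iid = stats::rnorm(nrow(fragment_tab), 0, jitter_sigma),
      correlated = stats::rnorm(1, 0, offset_sigma) +
        stats::rnorm(nrow(fragment_tab), 0, jitter_sigma))
    noisy <- fragment_tab
    noisy$energy <- noisy$energy + delta
    fp <- four_point(four_point_from_fragments(noisy))
    sp_err[k] <- mean(abs(delta)) * ha2ev
    lam_err[k] <- abs(fp$lambda - base$lambda)
    dg_err[k] <- abs(fp$dG - base$dG)
  }
  cancel <- mean(lam_err < sp_err & dg_err < sp_err)
  list(model = model, n_seeds = n_seeds,
       mean_single_point_error = mean(sp_err),
       mean_lambda_error = mean(lam_err),
       mean_dG_error = mean(dg_err),
       cancellation_fraction = cancel,
       single_point_errors = sp_err, lambda_errors = lam_err,
       dG_errors = dg_err, baseline = base)
}
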