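# Packaged synthetic fixtures. The allyl anion / allyl radical pi systems
# stand in for the neutral / cationic three-frontier-orbital indole active
# spaces: closed-shell (4e,3o) and open-shell (3e,3o) patterns on three
# 2p_z-dominated frontier orbitals. All fixtures are generated
# deterministically in code (seeded where random).

#' Planar allyl geometry (C3H5)
#'
#' Symmetric C2v geometry with delocalized C-C bonds (1.388 A, CCC 124.3
#' degrees, C-H 1.09 A), in the xy-plane so the pi system points along z.
#'
#' @param charge net charge (-1 anion, 0 radical).
#' @param spin N_alpha - N_beta (0 for the anion, 1 for the radical).
#' @return [geometry()].
#' @export
allyl_geometry <- function(charge = -1, spin = 0) {
  r_cc <- 1.388; r_ch <- 1.09
  half <- (124.3 / 2) * pi / 180
  C1 <- c(0, 0, 0)
  C2 <- c(r_cc * sin(half), r_cc * cos(half), 0)
  C3 <- c(-C2[1], C2[2], 0)
  rot <- function(u, phi)
    c(u[1] * cos(phi) - u[2] * sin(phi),
      u[1] * sin(phi) + u[2] * cos(phi), 0)
  u2 <- (C1 - C2) / sqrt(sum((C1 - C2)^2))
  u3 <- (C1 - C3) / sqrt(sum((C1 - C3)^2))
  coords <- rbind(C1, C2, C3,
                  C1 + c(0, -r_ch, 0),
                  C2 + r_ch * rot(u2, 2 * pi / 3),
                  C2 + r_ch * rot(u2, -2 * pi / 3),
                  C3 + r_ch * rot(u3, -2 * pi / 3),
                  C3 + r_ch * rot(u3, 2 * pi / 3))
  geometry(c("C", "C", "C", "H", "H", "H", "H", "H"), coords,
           charge = charge, spin = spin)
}

#' Generate packaged fixtures
#'
#' * `allyl_anion`: closed-shell (4e,3o) active-space problem (STO-3G).
#' * `allyl_radical`: open-shell (3e,3o) problem, 2 alpha / 1 beta.
#' * `h2_scan`: list of H2 (2e,2o) problems over a bond-length grid.
#' * `random_active_space`: seeded random symmetry-respecting (h0,h1,h2)
#'   with the requested occupation pattern.
#' * `four_point_table`: synthetic fragment-energy table with known
#'   (lambda, dG) that [four_point()] recovers exactly.
#' * `readout_noise`: readout channel from per-qubit fidelities
#'   F0 = 98.35%, F1 = 95.88%.
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed for the random fixtures.
#' @param ... kind-specific options (`pattern` = "closed"/"open" for
#'   `random_active_space`; `distances` for `h2_scan`; `n_qubits` for
#'   `readout_noise`; `lambda`, `dG` for `four_point_table`).
#' @return fixture object (problem, list, table, or calibration model).
#' @export
generate_fixtures <- function(kind, seed = 1, ...) {
  opts <- list(...)
  switch(kind,
    allyl_anion = {
      mf <- run_mean_field(allyl_geometry(-1, 0), "sto-3g")
      extract_active_space(mf, active_space_spec(4, 3))
    },
    allyl_radical = {
      mf <- run_mean_field(allyl_geometry(0, 1), "sto-3g")
      extract_active_space(mf, active_space_spec(3, 3, spin = 1))
    },
    h2_scan = {
      dists <- if (is.null(opts$distances)) c(0.5, 0.74, 1.0, 1.5, 2.5)
               else opts$distances
      lapply(dists, function(d) {
        g <- geometry(c("H", "H"),
                      matrix(c(0, 0, 0, 0, 0, d), ncol = 3, byrow = TRUE))
        extract_active_space(run_mean_field(g, "sto-3g"),
                             active_space_spec(2, 2))
      })
    },
    random_active_space = {
      pattern <- if (is.null(opts$pattern)) "closed" else opts$pattern
      spec <- if (pattern == "closed") active_space_spec(4, 3)
              else active_space_spec(3, 3, spin = 1)
      old <- .Random.seed_get()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed %% .Machine$integer.max)
      no <- spec$n_orbitals
      h1 <- matrix(stats::rnorm(no * no, 0, 0.5), no, no)
      h1 <- 0.5 * (h1 + t(h1)) - diag(no)
      h2 <- array(stats::rnorm(no^4, 0, 0.1), rep(no, 4))
      perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3),
                    c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 1, 2),
                    c(3, 4, 2, 1), c(4, 3, 2, 1))
      h2 <- Reduce(`+`, lapply(perms, function(p) aperm(h2, p))) / 8
      # make the two-electron part repulsive-dominated and bounded
      for (p in 1:no) for (q in 1:no)
        h2[p, p, q, q] <- h2[p, p, q, q] + 0.5
      problem_from_integrals(stats::rnorm(1), h1, h2, spec,
                             basis = "random-model")
    },
    four_point_table = {
      old <- .Random.seed_get()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed %% .Machine$integer.max)
      ev2ha <- 1 / pdft_constants$hartree2ev
      lambda <- if (is.null(opts$lambda)) stats::runif(1, 0.2, 0.8)
                else opts$lambda
      dG <- if (is.null(opts$dG)) stats::runif(1, 0.01, 0.15) else opts$dG
      e_ii <- -726 + stats::rnorm(1, 0, 0.05)
      e_ff <- e_ii + sample(c(-1, 1), 1) * dG * ev2ha
      s1 <- stats::runif(1, 0.3, 0.7)
      e_if <- e_ii + lambda * s1 * ev2ha
      e_fi <- e_ff + lambda * (1 - s1) * ev2ha
      split2 <- function(tot) {
        a <- tot / 2 + stats::rnorm(1, 0, 0.1)
        c(a, tot - a)
      }
      tab <- data.frame(
        point = rep(c("a", "b", "c", "d"), each = 2),
        fragment = rep(c("donor", "acceptor"), 4),
        energy = c(split2(e_ii), split2(e_if), split2(e_ff), split2(e_fi)))
      attr(tab, "lambda") <- lambda
      attr(tab, "dG") <- dG
      tab
    },
    readout_noise = {
      nq <- if (is.null(opts$n_qubits)) 4L else opts$n_qubits
      f0 <- if (is.null(opts$f0)) 0.9835 else opts$f0
      f1 <- if (is.null(opts$f1)) 0.9588 else opts$f1
      calibration_model(nq, f0 = f0, f1 = f1)
    },
    stop("unknown fixture kind '", kind, "'"))
}
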