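# Spin-polarized PBE exchange-correlation energy density (PW92 local
# correlation + PBE gradient corrections). Vectorized over grid points.
# Inputs are the (possibly translated) spin densities and gradient norms.

pw92_G <- function(rs, A, a1, b1, b2, b3, b4) {
  s <- sqrt(rs)
  den <- 2 * A * (b1 * s + b2 * rs + b3 * rs * s + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log(1 + 1 / den)
}

pw92_eps_c <- function(rs, zeta) {
  ec0 <- pw92_G(rs, 0.031091, 0.21370, 7.5957, 3.5876, 1.6382, 0.49294)
  ec1 <- pw92_G(rs, 0.015545, 0.20548, 14.1189, 6.1977, 3.3662, 0.62517)
  mac <- pw92_G(rs, 0.016887, 0.11125, 10.357, 3.6231, 0.88026, 0.49671)
  fz <- ((1 + zeta)^(4 / 3) + (1 - zeta)^(4 / 3) - 2) / (2^(4 / 3) - 2)
  fpp0 <- 1.709920934161365
  z4 <- zeta^4
  ec0 + (-mac) * fz / fpp0 * (1 - z4) + (ec1 - ec0) * fz * z4
}

# PBE exchange energy for one spin channel via the spin-scaling relation:
# returns the integrand contribution 1/2 * n2 * eps_x(n2) * F(s), n2 = 2 rho_s
pbe_exchange_channel <- function(rho_s, grad_s) {
  kappa <- 0.804
  mu <- 0.2195149727645171
  n2 <- 2 * rho_s
  g2 <- 2 * grad_s
  eps_x <- -(3 / 4) * (3 / pi)^(1 / 3) * n2^(1 / 3)
  kF <- (3 * pi^2 * n2)^(1 / 3)
  s <- g2 / (2 * kF * n2)
  Fx <- 1 + kappa - kappa / (1 + mu * s^2 / kappa)
  0.5 * n2 * eps_x * Fx
}

#' PBE exchange-correlation energy density on a set of points
#'
#' @param rho_a,rho_b spin densities (a.u.).
#' @param grad_a,grad_b norms of the spin-density gradients.
#' @param grad_t norm of the total-density gradient.
#' @return vector of energy densities e_xc (Hartree / Bohr^3); multiply by
#'   quadrature weights and sum for the energy.
#' @export
pbe_exc_density <- function(rho_a, rho_b, grad_a, grad_b, grad_t) {
  floor_d <- 1e-12
  n <- rho_a + rho_b
  ok <- n > floor_d
  out <- numeric(length(n))
  if (!any(ok)) return(out)
  ra <- pmax(rho_a[ok], 0); rb <- pmax(rho_b[ok], 0)
  n <- ra + rb
  ex <- numeric(length(n))
  ia <- ra > floor_d
  ex[ia] <- ex[ia] + pbe_exchange_channel(ra[ia], grad_a[ok][ia])
  ib <- rb > floor_d
  ex[ib] <- ex[ib] + pbe_exchange_channel(rb[ib], grad_b[ok][ib])
  # correlation
  zeta <- pmin(pmax((ra - rb) / n, -1), 1)
  rs <- (3 / (4 * pi * n))^(1 / 3)
  eps_c <- pw92_eps_c(rs, zeta)
  phi <- 0.5 * ((1 + zeta)^(2 / 3) + (1 - zeta)^(2 / 3))
  kF <- (3 * pi^2 * n)^(1 / 3)
  ks <- sqrt(4 * kF / pi)
  t <- grad_t[ok] / (2 * phi * ks * n)
  beta <- 0.06672455060314922
  gam <- (1 - log(2)) / pi^2
  Aa <- beta / gam / (exp(-eps_c / (gam * phi^3)) - 1)
  Aa[!is.finite(Aa)] <- 1e12
  t2 <- t^2
  H <- gam * phi^3 *
    log(1 + beta / gam * t2 * (1 + Aa * t2) / (1 + Aa * t2 + Aa^2 * t2^2))
  out[ok] <- ex + n * (eps_c + H)
  out
}
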