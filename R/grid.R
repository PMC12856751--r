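# Atom-centered quadrature grids (Becke partitioning) and AO evaluation.
# Radial: Gauss-Chebyshev (2nd kind) mapped onto (0, inf) with a Bragg-radius
# scale; angular: Gauss-Legendre x uniform-phi product rule on the sphere.

gauss_legendre <- function(n) {
  # Golub-Welsch on the Jacobi matrix
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

# grid level -> (radial points, angular polar points)
grid_sizes <- function(level) {
  stopifnot(level >= 0, level <= 9)
  n_rad <- c(20, 30, 40, 50, 60, 70, 80, 90, 100, 110)[level + 1]
  n_pol <- c(6, 8, 10, 12, 14, 16, 18, 20, 22, 24)[level + 1]
  list(n_rad = n_rad, n_pol = n_pol)
}

becke_smooth <- function(mu) {
  f <- mu
  for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
  0.5 * (1 - f)
}

#' Build a Becke molecular quadrature grid
#'
#' @param geom a [geometry()].
#' @param level grid level 0..9 (default 3, "medium"); controls radial and
#'   angular point counts per atom.
#' @return list with `points` (n x 3, Bohr) and `weights` (Bohr^3).
#' @export
becke_grid <- function(geom, level = 3) {
  gs <- grid_sizes(level)
  xyz <- geom$coords * pdft_constants$ang2bohr
  n_at <- nrow(xyz)
  gl <- gauss_legendre(gs$n_pol)
  n_phi <- 2 * gs$n_pol
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ang <- do.call(rbind, lapply(seq_along(gl$nodes), function(i) {
    ct <- gl$nodes[i]; st <- sqrt(1 - ct^2)
    cbind(st * cos(phi), st * sin(phi), ct,
          gl$weights[i] * 2 * pi / n_phi)
  }))
  i_r <- seq_len(gs$n_rad)
  th <- i_r * pi / (gs$n_rad + 1)
  t_r <- cos(th)
  pts <- NULL; wts <- NULL; owner <- NULL
  for (a in seq_len(n_at)) {
    rm <- BRAGG_RADII[geom$atoms[a]] * pdft_constants$ang2bohr
    if (geom$atoms[a] != "H") rm <- rm * 0.5
    r <- rm * (1 + t_r) / (1 - t_r)
    w_r <- (pi / (gs$n_rad + 1)) * sin(th) * (2 * rm / (1 - t_r)^2) * r^2
    for (k in seq_along(r)) {
      p <- sweep(ang[, 1:3, drop = FALSE] * r[k], 2, xyz[a, ], `+`)
      pts <- rbind(pts, p)
      wts <- c(wts, ang[, 4] * w_r[k])
      owner <- c(owner, rep(a, nrow(ang)))
    }
  }
  # Becke partition weights
  if (n_at > 1) {
    Rab <- as.matrix(dist(xyz))
    P <- matrix(1, nrow(pts), n_at)
    dist_at <- sapply(seq_len(n_at), function(b)
      sqrt(rowSums((pts - matrix(xyz[b, ], nrow(pts), 3, byrow = TRUE))^2)))
    for (a in seq_len(n_at)) for (b in seq_len(n_at)) {
      if (a == b) next
      mu <- (dist_at[, a] - dist_at[, b]) / Rab[a, b]
      P[, a] <- P[, a] * becke_smooth(mu)
    }
    wts <- wts * P[cbind(seq_len(nrow(pts)), owner)] / rowSums(P)
  }
  list(points = pts, weights = wts)
}

# normalized contracted-AO values and gradients at grid points
ao_values <- function(basis, points) {
  prim_norm_r <- function(a, lx, ly, lz) {
    dfact <- function(n) if (n < 2) 1 else prod(seq(n, 1, by = -2))
    L <- lx + ly + lz
    (2 * a / pi)^0.75 * (4 * a)^(L / 2) /
      sqrt(dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1))
  }
  npt <- nrow(points)
  vals <- list(); grads <- list()
  for (sh in basis$shells) {
    dx <- points[, 1] - sh$center[1]
    dy <- points[, 2] - sh$center[2]
    dz <- points[, 3] - sh$center[3]
    r2 <- dx^2 + dy^2 + dz^2
    comps <- list()
    l <- sh$l
    for (lx in seq(l, 0)) for (ly in seq(l - lx, 0)) {
      lz <- l - lx - ly
      comps[[length(comps) + 1]] <- c(lx, ly, lz)
    }
    for (cmp in comps) {
      lx <- cmp[1]; ly <- cmp[2]; lz <- cmp[3]
      cn <- sh$coefficients * vapply(sh$exponents, prim_norm_r, numeric(1),
                                     lx = lx, ly = ly, lz = lz)
      # contraction renormalization (matches the integral engine)
      ss <- 0
      for (i in seq_along(cn)) for (j in seq_along(cn)) {
        p <- sh$exponents[i] + sh$exponents[j]
        dfact <- function(n) if (n < 2) 1 else prod(seq(n, 1, by = -2))
        s1 <- (pi / p)^1.5 / (2 * p)^(lx + ly + lz) *
          dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1)
        ss <- ss + cn[i] * cn[j] * s1
      }
      cn <- cn / sqrt(ss)
      v <- numeric(npt); gx <- numeric(npt); gy <- numeric(npt)
      gz <- numeric(npt)
      poly <- (if (lx > 0) dx^lx else 1) * (if (ly > 0) dy^ly else 1) *
              (if (lz > 0) dz^lz else 1)
      for (i in seq_along(cn)) {
        e <- exp(-sh$exponents[i] * r2)
        v <- v + cn[i] * poly * e
        ddx <- (if (lx > 0) lx * (if (lx > 1) dx^(lx - 1) else 1) *
                  (if (ly > 0) dy^ly else 1) * (if (lz > 0) dz^lz else 1)
                else 0) - 2 * sh$exponents[i] * dx * poly
        ddy <- (if (ly > 0) ly * (if (lx > 0) dx^lx else 1) *
                  (if (ly > 1) dy^(ly - 1) else 1) *
                  (if (lz > 0) dz^lz else 1)
                else 0) - 2 * sh$exponents[i] * dy * poly
        ddz <- (if (lz > 0) lz * (if (lx > 0) dx^lx else 1) *
                  (if (ly > 0) dy^ly else 1) *
                  (if (lz > 1) dz^(lz - 1) else 1)
                else 0) - 2 * sh$exponents[i] * dz * poly
        gx <- gx + cn[i] * ddx * e
        gy <- gy + cn[i] * ddy * e
        gz <- gz + cn[i] * ddz * e
      }
      vals[[length(vals) + 1]] <- v
      grads[[length(grads) + 1]] <- cbind(gx, gy, gz)
    }
  }
  list(val = do.call(cbind, vals),
       gx = do.call(cbind, lapply(grads, function(g) g[, 1])),
       gy = do.call(cbind, lapply(grads, function(g) g[, 2])),
       gz = do.call(cbind, lapply(grads, function(g) g[, 3])))
}
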