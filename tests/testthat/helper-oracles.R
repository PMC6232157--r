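# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Horn's quaternion method for optimal-superposition RMSD: the largest
# eigenvalue of the 4x4 key matrix built from the correlation matrix gives
# the residual in closed form.
quaternionRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lmax) / nrow(P))
}

# Exhaustive in-plane grid search for the slice pore-radius maximum, on a
# window around `center` perpendicular to `axis` (z by construction in the
# fixtures that use it).
gridSliceMax <- function(atoms, center, halfWidth = 1.6, stepGrid = 0.02) {
  u <- seq(-halfWidth, halfWidth, by = stepGrid)
  g <- as.matrix(expand.grid(x = center[1] + u, y = center[2] + u))
  xyz <- atomCoords(atoms)
  vdw <- vdwRadii(atoms)
  d2 <- outer(g[, 1], xyz[, 1], `-`)^2 + outer(g[, 2], xyz[, 2], `-`)^2
  d2 <- sweep(d2, 2, (center[3] - xyz[, 3])^2, `+`)
  r <- sqrt(d2)
  r <- sweep(r, 2, vdw)
  best <- which.max(apply(r, 1, min))
  list(radius = min(r[best, ]), point = c(g[best, ], center[3]))
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# relative-volume trajectory with additive noise scaled to the excursion
noisyVrelTrajectory <- function(clean, noiseFrac, seed) {
  v <- vRel(clean)
  set.seed(seed)
  obs <- v + rnorm(length(v), 0, noiseFrac * diff(range(v)))
  new("VolumeTrajectory", times = times(clean), vRel = obs,
      cGlyIn = rep(NA_real_, length(v)), inactiveFraction = 0)
}
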