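# Shared fixtures: small grids, smooth random fields compatible with the
# even spectral extension (functions of r^2, decaying before the domain
# boundary), and the finite-difference directional-derivative oracle.

unit_params <- function(...) phys_params(eps = 1, ...)

small_grid <- function(nr = 48, nz = 64, r_max = 24, z_min = -16,
                       z_max = 16) {
  build_grid(nr, nz, r_max, z_min, z_max)
}

# Random smooth field: sum of ring bumps, even in r (smooth across the
# axis) and flat near all boundaries.
smooth_bump <- function(g, n_bumps = 4, amp = 1) {
  R2 <- outer(g$r_centers^2, rep.int(1, g$nz))
  Z <- outer(rep.int(1, g$nr), g$z_centers)
  zc <- (g$z_min + g$z_max) / 2
  zhw <- (g$z_max - g$z_min) / 2
  f <- matrix(0, g$nr, g$nz)
  for (i in seq_len(n_bumps)) {
    r0 <- runif(1, 0.15, 0.45) * g$r_max
    z0 <- zc + runif(1, -0.25, 0.25) * zhw
    w <- runif(1, 0.08, 0.12) * min(g$r_max, zhw) + 1
    f <- f + runif(1, -amp, amp) *
      exp(-((R2 - r0^2) / (2 * w * r0))^2 - (Z - z0)^2 / w^2)
  }
  f
}

# Central finite-difference directional derivative of a scalar functional
fd_directional <- function(Efun, f0, df, h = 1e-5) {
  (Efun(f0 + h * df) - Efun(f0 - h * df)) / (2 * h)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
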