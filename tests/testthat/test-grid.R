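test_that("cell-centered grid geometry matches the reference layout", {
  g <- build_grid(144, 735, 96, -245, 245)
  expect_equal(g$dr, 2 / 3)
  expect_equal(g$dz, 2 / 3)
  expect_equal(g$r_centers[1], 1 / 3)
  expect_true(all(g$r_centers > 0))
  expect_equal(diff(g$r_centers), rep(g$dr, 143))

  g2 <- build_grid(8, 8, 8, 0, 8)
  expect_equal(g2$r_centers, seq(0.5, 7.5))
})

test_that("degenerate grid configurations are rejected", {
  expect_error(build_grid(8, 8, 8, 4, 4), "z_max > z_min")
  expect_error(build_grid(8, 8, -1, 0, 8), "r_max")
  expect_error(build_grid(4, 8, 8, 0, 8), ">= 8")
})

test_that("spectral derivatives are exact on transform eigenfunctions", {
  g <- small_grid(32, 64, 8, -8, 8)
  f <- matrix(5, g$nr, g$nz)
  expect_lt(max(abs(field_gradient(f, g)$dr)), 1e-10)
  expect_lt(max(abs(field_gradient(f, g)$dz)), 1e-10)

  L <- g$z_max - g$z_min
  for (n in c(1, 3, 7)) {
    Z <- outer(rep(1, g$nr), cos(pi * n * (g$z_centers - g$z_min) / L))
    dZ <- outer(rep(1, g$nr),
                -(pi * n / L) * sin(pi * n * (g$z_centers - g$z_min) / L))
    expect_lt(max(abs(field_gradient(Z, g)$dz - dZ)), 1e-10)
  }
})

test_that("spectral gradient agrees with high-order finite differences", {
  # wide smooth bump on a fine grid: the 4th-order FD oracle's own
  # truncation error must sit below the comparison threshold
  g <- build_grid(192, 320, 24, -20, 20)
  R2 <- outer(g$r_centers^2, rep(1, g$nz))
  Z <- outer(rep(1, g$nr), g$z_centers)
  f <- exp(-((R2 - 81) / (2 * 6 * 9))^2 - Z^2 / 20)
  gr <- field_gradient(f, g)
  # 4th-order centered differences at interior points
  ii <- 5:(g$nr - 4); jj <- 5:(g$nz - 4)
  fd_r <- (-f[ii + 2, jj] + 8 * f[ii + 1, jj] -
             8 * f[ii - 1, jj] + f[ii - 2, jj]) / (12 * g$dr)
  fd_z <- (-f[ii, jj + 2] + 8 * f[ii, jj + 1] -
             8 * f[ii, jj - 1] + f[ii, jj - 2]) / (12 * g$dz)
  scale <- max(abs(fd_r))
  expect_lt(max(abs(gr$dr[ii, jj] - fd_r)) / scale, 1e-6)
  expect_lt(max(abs(gr$dz[ii, jj] - fd_z)) / scale, 1e-6)
  expect_error(field_gradient(matrix(0, 3, 3), g), "mismatch")
})

test_that("cylindrical Laplacian reproduces closed forms", {
  g <- small_grid(48, 96, 24, -24, 24)
  expect_lt(max(abs(laplacian_cyl(matrix(2, g$nr, g$nz), g))), 1e-9)

  # windowed z^2: compare to the closed-form second derivative
  Z <- outer(rep(1, g$nr), g$z_centers)
  a <- 10
  v <- exp(-(Z / a)^4)
  vp <- -4 * Z^3 / a^4 * v
  vpp <- (-12 * Z^2 / a^4 + 16 * Z^6 / a^8) * v
  lap <- laplacian_cyl(Z^2 * v, g)
  an2 <- 2 * v + 4 * Z * vp + Z^2 * vpp
  mid <- abs(Z) < 8
  expect_lt(max(abs(lap[mid] - an2[mid])) / max(abs(an2)), 1e-6)

  # tanh profile: second derivative of the 1D equilibrium shape
  p <- unit_params()
  gz <- build_grid(16, 128, 8, -16, 16)  # dz = eps/4
  s <- tanh_slab(0, p, gz)
  c2 <- sqrt(2) * p$eps
  an <- -2 * s * (1 - s^2) / c2^2
  expect_lt(max(abs(laplacian_cyl(s, gz) - an)) / max(abs(an)), 1e-6)
})

test_that("differentiation is linear and self-adjoint under quadrature", {
  set.seed(3)
  g <- small_grid(48, 64, 24, -12, 12)
  f1 <- smooth_bump(g); f2 <- smooth_bump(g)
  lhs <- laplacian_cyl(2.5 * f1 - 1.25 * f2, g)
  rhs <- 2.5 * laplacian_cyl(f1, g) - 1.25 * laplacian_cyl(f2, g)
  expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(rhs)))

  # integration by parts: <f, lap h> = <h, lap f> for interior fields,
  # to quadrature tolerance
  a <- integrate_axisym(f1 * laplacian_cyl(f2, g), g)
  b <- integrate_axisym(f2 * laplacian_cyl(f1, g), g)
  den <- integrate_axisym(abs(f1 * laplacian_cyl(f2, g)), g)
  expect_lt(abs(a - b) / den, 1e-4)
})

test_that("axisymmetric quadrature integrates the domain measure exactly", {
  g <- build_grid(33, 57, 7.3, -2.1, 5.9)
  vol <- pi * 7.3^2 * 8
  expect_lt(abs(integrate_axisym(matrix(1, 33, 57), g) - vol) / vol, 1e-12)
})

test_that("implicit biharmonic solve is exact in transform space", {
  set.seed(5)
  g <- small_grid(32, 48, 16, -12, 12)
  rhs <- matrix(rnorm(32 * 48), 32, 48)
  # near-identity limit
  u0 <- helmholtz_solve(rhs, 1e-14, g)
  expect_lt(max(abs(u0 - rhs)), 1e-6)
  # eigenfunction: cosine mode in z
  L <- g$z_max - g$z_min
  mode <- outer(rep(1, g$nr), cos(pi * 4 * (g$z_centers - g$z_min) / L))
  lam <- (pi * 4 / L)^4
  u <- helmholtz_solve(mode, 0.7, g)
  expect_lt(max(abs(u - mode / (1 + 0.7 * lam))), 1e-10)
  # random rhs residual
  u <- helmholtz_solve(rhs, 0.3, g)
  res <- u + 0.3 * vesiclefusion:::apply_stiff_operator(u, g) - rhs
  expect_lt(sqrt(sum(res^2) / sum(rhs^2)), 1e-10)
  expect_error(helmholtz_solve(rhs, -1, g), "positive")
})
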