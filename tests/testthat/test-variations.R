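# Every functional derivative is checked against central finite-difference
# directional derivatives on random smooth fields: the oracle is the
# discrete energy itself, so any algebra slip in the closed forms is
# detectable.

test_that("elastic functional derivatives pass the directional oracle", {
  set.seed(42)
  p <- unit_params()
  g <- build_grid(72, 96, 24, -16, 16)  # h = eps/3
  phi <- tanh_sphere(0, 10, p, g) + 0.15 * smooth_bump(g)
  R2 <- outer(g$r_centers^2, rep(1, g$nz))
  Z <- outer(rep(1, g$nr), g$z_centers)
  eta <- -1 + 0.6 * exp(-((R2 - 25) / 30)^2 - Z^2 / 9) +
    0.1 * smooth_bump(g)

  for (rep in 1:5) {
    dphi <- smooth_bump(g)
    a <- fd_directional(function(x) energy_bending(x, p, g), phi, dphi)
    b <- integrate_axisym(d_bending_dphi(phi, p, g) * dphi, g)
    expect_rel_equal(a, b, 1e-5)

    a <- fd_directional(function(x) energy_gaussian(x, eta, p, g),
                        phi, dphi)
    b <- integrate_axisym(d_gaussian_dphi(phi, eta, p, g) * dphi, g)
    expect_rel_equal(a, b, 1e-4)
  }

  deta <- smooth_bump(g)
  a <- fd_directional(function(x) energy_gaussian(phi, x, p, g), eta, deta)
  b <- integrate_axisym(d_gaussian_deta(phi, eta, p, g) * deta, g)
  expect_rel_equal(a, b, 1e-6)

  a <- fd_directional(function(x) energy_auxiliary(x, p, g), eta, deta,
                      h = 1e-4)
  b <- integrate_axisym(
    vesiclefusion:::d_auxiliary_deta(eta, p, g) * deta, g)
  expect_rel_equal(a, b, 1e-4)
})

test_that("variable-modulus Gaussian derivative reduces correctly", {
  p <- unit_params()
  g <- small_grid(48, 96, 24, -24, 24)
  # uniform modulus and flat slab: everything vanishes
  slab <- tanh_slab(4, p, g, z1 = -4)
  em1 <- matrix(-1, g$nr, g$nz)
  dG <- d_gaussian_dphi(slab, em1, p, g)
  expect_lt(max(abs(dG)), 1e-6)
  # equilibrium slab: bending derivative vanishes (the superposition
  # profile carries an intrinsic ~1e-5 tail residual, amplified by the
  # 1/eps^2 scale of the derivative)
  expect_lt(max(abs(d_bending_dphi(slab, p, g))), 0.05)
  expect_lt(max(abs(d_bending_dphi(matrix(1, g$nr, g$nz), p, g))), 1e-10)
  # the eta-force through E_G switches off inside the patch
  expect_equal(max(abs(d_gaussian_deta(slab, matrix(1, g$nr, g$nz),
                                       p, g))), 0)
})

test_that("assembled total derivatives pass the oracle and reduce termwise", {
  set.seed(17)
  p <- unit_params()
  g <- build_grid(72, 96, 24, -16, 16)
  phi <- tanh_sphere(0, 10, p, g) + 0.1 * smooth_bump(g)
  R2 <- outer(g$r_centers^2, rep(1, g$nz))
  Z <- outer(rep(1, g$nr), g$z_centers)
  eta <- -1 + 0.5 * exp(-((R2 - 25) / 30)^2 - Z^2 / 9)
  cs <- constraint_set(A0 = 900, V0 = 3500, P0 = 40, gamma = 1.5,
                       delta_p = -0.8, gamma_p = 0.3,
                       M1 = 1e-3, M2 = 1e-4, M3 = 1e-2, M4 = 1e-4)
  Ebar <- function(ph, et) total_modified_energy(ph, et, p, cs, g)$E_bar

  for (rep in 1:3) {
    dphi <- smooth_bump(g); deta <- smooth_bump(g)
    a <- fd_directional(function(x) Ebar(x, eta), phi, dphi)
    b <- integrate_axisym(d_total_dphi(phi, eta, p, cs, g) * dphi, g)
    expect_rel_equal(a, b, 1e-4)
    a <- fd_directional(function(x) Ebar(phi, x), eta, deta, h = 1e-4)
    b <- integrate_axisym(d_total_deta(phi, eta, p, cs, g) * deta, g)
    expect_rel_equal(a, b, 1e-4)
  }

  # with no constraints and uniform eta, the phi-derivative reduces to
  # the elastic part
  cs0 <- constraint_set(A0 = 0, V0 = 0, P0 = NA)
  em1 <- matrix(-1, g$nr, g$nz)
  full <- d_total_dphi(phi, em1, p, cs0, g)
  elastic <- d_bending_dphi(phi, p, g) + d_gaussian_dphi(phi, em1, p, g)
  expect_lt(max(abs(full - elastic)), 1e-8 * max(abs(elastic)))
})

test_that("explicit Euler steps along the negative gradient descend", {
  set.seed(9)
  p <- unit_params()
  g <- small_grid(48, 64, 24, -16, 16)
  phi <- tanh_sphere(0, 9, p, g) + 0.05 * smooth_bump(g)
  eta <- matrix(-1, g$nr, g$nz)
  cs <- constraint_set(A0 = area_functional(phi, p, g),
                       V0 = volume_functional(phi, g), P0 = NA,
                       M1 = 1e-3, M2 = 1e-4)
  E0 <- total_modified_energy(phi, eta, p, cs, g)$E_bar
  gphi <- d_total_dphi(phi, eta, p, cs, g)
  dt <- 1e-4
  repeat {
    E1 <- total_modified_energy(phi - dt * gphi, eta, p, cs, g)$E_bar
    if (E1 < E0) break
    dt <- dt / 2
    expect_gt(dt, 1e-12)
  }
  expect_lt(E1, E0)
})

test_that("force density vanishes at equilibrium and on plateaus", {
  p <- unit_params()
  g <- small_grid(32, 96, 16, -24, 24)
  slab <- tanh_slab(4, p, g, z1 = -4)
  em1 <- matrix(-1, g$nr, g$nz)
  f <- force_density(slab, em1, p, g)
  expect_lt(max(abs(f$force_r)), 0.05)
  expect_lt(max(abs(f$force_z)), 0.05)

  phi <- tanh_sphere(0, 8, p, g)
  f2 <- force_density(phi, em1, p, g)
  plateau <- abs(phi) > 1 - 1e-9
  expect_lt(max(abs(f2$force_z[plateau])),
            1e-6 * max(abs(f2$force_z)))
})
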