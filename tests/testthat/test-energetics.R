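test_that("flat and plateau configurations are bending equilibria", {
  p <- unit_params()
  g <- small_grid(32, 96, 16, -24, 24)
  slab <- tanh_slab(5, p, g, z1 = -5)
  expect_lt(max(abs(psi_bending(slab, p, g))) * p$eps^2, 1e-4)
  expect_lt(energy_bending(slab, p, g), 1e-4)
  expect_lt(max(abs(psi_bending(matrix(1, g$nr, g$nz), p, g))), 1e-10)

  # pointwise arithmetic of the double-well term
  pm <- phys_params(eps = 1, m = 0.3)
  phi0 <- matrix(0, g$nr, g$nz)
  expect_equal(max(abs(psi_bending(phi0, pm, g) - sqrt(2) * pm$m)), 0,
               tolerance = 1e-9)
})

test_that("sphere energies approach the Canham-Helfrich sharp limits", {
  p <- unit_params()
  g <- build_grid(120, 240, 60, -60, 60)  # h = eps/2
  R <- 40
  phi <- tanh_sphere(0, R, p, g)
  em1 <- matrix(-1, g$nr, g$nz)
  expect_rel_equal(energy_bending(phi, p, g), 8 * pi * p$k, 0.03)
  expect_rel_equal(energy_gaussian(phi, em1, p, g), 4 * pi * p$kG0, 0.03)
  expect_rel_equal(area_functional(phi, p, g), 4 * pi * R^2, 0.02)
  expect_rel_equal(volume_functional(phi, g), 4 / 3 * pi * R^3, 0.01)

  # spontaneous curvature matched to the sphere kills the bending term
  pm <- phys_params(eps = 1, m = 1 / R)
  expect_lt(energy_bending(phi, pm, g), 0.03 * 8 * pi * p$k)

  # patch everywhere: modulus vanishes, so does the Gaussian energy
  expect_lt(abs(energy_gaussian(phi, matrix(1, g$nr, g$nz), p, g)),
            0.03 * abs(4 * pi * p$kG0))
})

test_that("sharp-interface errors decay monotonically with radius", {
  p <- unit_params()
  errs <- sapply(c(10, 20, 40, 80), function(R) {
    half <- max(R + 8, 24)
    n <- ceiling(half / 0.5 / 2) * 4
    g <- build_grid(n / 2, n, half, -half, half)
    phi <- tanh_sphere(0, R, p, g)
    c(EB = abs(energy_bending(phi, p, g) / (8 * pi * p$k) - 1),
      A = abs(area_functional(phi, p, g) / (4 * pi * R^2) - 1),
      V = abs(volume_functional(phi, g) / (4 / 3 * pi * R^3) - 1))
  })
  for (row in rownames(errs)) {
    expect_true(all(diff(errs[row, ]) < 0),
                info = paste("monotone decay of", row))
  }
})

test_that("local modulus interpolates between baseline and zero", {
  expect_equal(kg_of_eta(-1, -20), -20)
  expect_equal(kg_of_eta(1, -20), 0)
  expect_equal(kg_of_eta(0, -20), -5)
})

test_that("Gaussian energy difference between topologies is quantized", {
  # Gauss-Bonnet: merging two spheres releases one 4*pi*kG quantum,
  # independently of the radii
  p <- unit_params()
  g <- build_grid(100, 440, 50, -110, 110)  # h = eps/2
  em1 <- matrix(-1, g$nr, g$nz)
  quantum <- 4 * pi * p$kG0
  for (radii in list(c(40, 40), c(30, 40), c(25, 32))) {
    two <- compose_union(list(
      tanh_sphere(-radii[1] - 12, radii[1], p, g),
      tanh_sphere(radii[2] + 12, radii[2], p, g)))
    one <- tanh_sphere(0, radii[1], p, g)
    two_minus_one <- energy_gaussian(two, em1, p, g) -
      energy_gaussian(one, em1, p, g)
    expect_rel_equal(two_minus_one, quantum, 0.03)
  }
})

test_that("unidirectional fields carry no Gaussian curvature", {
  p <- unit_params()
  g <- small_grid(32, 96, 16, -24, 24)
  slab <- tanh_slab(4, p, g, z1 = -4)
  em1 <- matrix(-1, g$nr, g$nz)
  expect_lt(abs(energy_gaussian(slab, em1, p, g)),
            1e-3 * abs(4 * pi * p$kG0))
  expect_lt(abs(energy_gaussian(matrix(0.4, g$nr, g$nz), em1, p, g)),
            1e-10)
})

test_that("auxiliary energy vanishes only on equilibrium profiles", {
  p <- unit_params()
  g <- small_grid(32, 96, 16, -24, 24)
  expect_equal(energy_auxiliary(matrix(1, g$nr, g$nz), p, g), 0)
  expect_equal(energy_auxiliary(matrix(-1, g$nr, g$nz), p, g), 0)
  eta_eq <- tanh_slab(0, p, g)
  expect_lt(energy_auxiliary(eta_eq, p, g), 1e-6)
  # doubled interface width is off-equilibrium
  Z <- outer(rep(1, g$nr), g$z_centers)
  eta_wide <- tanh(-Z / (2 * sqrt(2) * p$eps))
  expect_gt(energy_auxiliary(eta_wide, p, g), 0.01)
})

test_that("orthogonality penalty detects aligned interface gradients", {
  set.seed(21)
  p <- unit_params()
  g <- small_grid(48, 64, 24, -16, 16)
  phi <- smooth_bump(g)
  expect_equal(orthogonality_penalty(phi, matrix(0.2, g$nr, g$nz), g), 0)
  # phi varying in z only, eta in r only: gradients orthogonal
  Z <- outer(rep(1, g$nr), g$z_centers)
  R2 <- outer(g$r_centers^2, rep(1, g$nz))
  pz <- tanh(-Z / sqrt(2))
  er <- exp(-((R2 - 64) / 40)^2)
  expect_lt(orthogonality_penalty(pz, er, g),
            1e-6 * orthogonality_penalty(pz, pz, g))
  # eta = phi reduces to the |grad phi|^4 integral
  gr <- field_gradient(phi, g)
  q2 <- (gr$dr^2 + gr$dz^2)^2
  expect_rel_equal(orthogonality_penalty(phi, phi, g),
                   integrate_axisym(q2, g), 1e-10)
})

test_that("patch area is bounded by total area and exact at the extremes", {
  p <- unit_params()
  g <- small_grid(48, 128, 24, -32, 32)
  phi <- tanh_sphere(0, 14, p, g)
  A <- area_functional(phi, p, g)
  expect_equal(patch_area_functional(phi, matrix(-1, g$nr, g$nz), p, g), 0)
  expect_equal(patch_area_functional(phi, matrix(1, g$nr, g$nz), p, g), A)
})

test_that("modified energy assembles penalties and multipliers exactly", {
  p <- unit_params()
  g <- small_grid(32, 64, 16, -16, 16)
  phi <- tanh_sphere(0, 8, p, g)
  eta <- matrix(-1, g$nr, g$nz)
  A <- area_functional(phi, p, g)
  V <- volume_functional(phi, g)
  P <- patch_area_functional(phi, eta, p, g)

  cs0 <- constraint_set(A0 = A, V0 = V, P0 = P)
  r0 <- total_modified_energy(phi, eta, p, cs0, g)
  expect_equal(r0$E, r0$E_B + r0$E_G)
  expect_equal(r0$E_bar, r0$E + r0$E_A + cs0$M4 * r0$O_pen^2)

  # quadratic penalty: A off-target by delta costs M1 delta^2 / 2
  delta <- 7.5
  cs1 <- constraint_set(A0 = A - delta, V0 = V, P0 = P, M1 = 3)
  r1 <- total_modified_energy(phi, eta, p, cs1, g)
  expect_equal(r1$E_bar - r0$E_bar, 0.5 * 3 * delta^2, tolerance = 1e-8)

  # linear multiplier term
  cs2 <- constraint_set(A0 = A - delta, V0 = V, P0 = P, gamma = 2)
  r2 <- total_modified_energy(phi, eta, p, cs2, g)
  expect_equal(r2$E_bar - r0$E_bar, 2 * delta, tolerance = 1e-8)
})

test_that("energies rescale exactly with the elastic moduli", {
  p1 <- unit_params()
  p2 <- phys_params(eps = 1, k = 50, kG0 = -50)
  g <- small_grid(48, 96, 24, -24, 24)
  phi <- tanh_sphere(0, 12, p1, g)
  eta <- tanh_slab(0, p1, g)
  c <- 50 / 20
  expect_equal(energy_bending(phi, p2, g), c * energy_bending(phi, p1, g),
               tolerance = 1e-12)
  expect_equal(energy_gaussian(phi, eta, p2, g),
               c * energy_gaussian(phi, eta, p1, g), tolerance = 1e-12)
})
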