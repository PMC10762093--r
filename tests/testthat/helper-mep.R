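# Desk-scale fusion pathway runner used by the acceptance tests: two
# vesicles of R = 40 eps in the mirror-symmetric half domain (z >= 0) at
# the production grid spacing h = 2/3 eps.  The string starts from the
# staged guess and is evolved in pure-penalty mode (fixed functional, no
# dual updates), which descends monotonically and is the robust regime
# for short runs.  Reported energies are twice the half-domain values.

run_mini_fusion <- function(patch_fraction, n_images = 10,
                            n_cycles = 60, endpoint_steps = 350) {
  p <- phys_params(eps = 1)
  g <- build_grid(84, 180, 56, 0, 120)
  R <- 40; gap <- 3
  use_patch <- patch_fraction > 0
  phi_a <- tanh_sphere(R + gap / 2, R, p, g, check_fit = FALSE)
  eta_a <- init_patch_field(phi_a, 0, patch_fraction, p, g)
  A0 <- area_functional(phi_a, p, g)
  V0 <- volume_functional(phi_a, g)
  P0 <- patch_area_functional(phi_a, eta_a, p, g)
  pen <- vesiclefusion:::default_penalties(p, A0, V0,
                                           if (use_patch) P0 else NA, g)
  # pure-penalty constraint set (duals frozen at zero, stiff penalties)
  cs <- constraint_set(A0 = A0, V0 = V0,
                       P0 = if (use_patch) P0 else NA,
                       M1 = 30 * pen$M1, M2 = 30 * pen$M2,
                       M3 = if (use_patch) 30 * pen$M3 else 0,
                       M4 = if (use_patch) pen$M4 else 0)
  se <- relax_settings(dt = 2e-3, n_steps = endpoint_steps,
                       multiplier_update_every = 100000L,
                       evolve_eta = use_patch)
  end_a <- relax_image(phi_a, eta_a, p, cs, se, g)
  phi_b <- tanh_fused_dumbbell(R, 0.5 * R, p, g)
  eta_b <- init_patch_field(phi_b, 0, patch_fraction, p, g)
  end_b <- relax_image(phi_b, eta_b, p, cs, se, g)
  str0 <- init_fusion_string(list(phi = end_a$phi, eta = end_a$eta),
                             list(phi = end_b$phi, eta = end_b$eta),
                             n_images, R, gap, patch_fraction, p, g)
  s <- relax_settings(dt = 2e-3, n_steps = 4, tol = 1e-5,
                      multiplier_update_every = 100000L,
                      evolve_eta = use_patch,
                      eta_hold_cycles = if (use_patch) 15L else 0L,
                      surgery_eb = 20000)
  str1 <- evolve_string(str0, p, cs, s, n_cycles, g)
  list(mep = mep_profile(str1, p, cs, g), str = str1,
       cs = cs, g = g, p = p,
       n_surgery = attr(str1, "n_surgery"))
}

# radial position of the first phi < 0 cell on the lowest z-layer: the
# neck radius of a fused configuration (~0 when unfused)
neck_radius <- function(phi, g) {
  i <- which(phi[, 1] < 0)[1]
  if (is.na(i)) g$r_max else g$r_centers[i]
}
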