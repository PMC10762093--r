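# End-to-end orchestration of the two-vesicle fusion experiment:
# endpoint construction, string evolution, profile extraction, artifacts.

# Default penalty constants, scaled so that a 0.1% constraint violation
# costs of order k: M1..M3 ~ 1e3 k / target^2, M4 ~ 1e2 k / O_ref^2.
default_penalties <- function(p, A0, V0, P0, g) {
  O_ref <- A0 / p$eps
  list(M1 = 1e3 * p$k / A0^2,
       M2 = 1e3 * p$k / V0^2,
       M3 = if (is.na(P0) || P0 <= 0) 0 else 1e3 * p$k / P0^2,
       M4 = 1e2 * p$k / O_ref^2)
}

#' Build the two-sphere initial state of a fusion run
#'
#' Two equal tanh spheres of the given diameter, stacked along the axis
#' with a surface-to-surface gap, composed by pointwise union. The
#' auxiliary field places the modified-modulus patch as a cap around the
#' contact point at z = 0 covering `patch_fraction` of the total area.
#'
#' @param diameter vesicle diameter (same unit as eps).
#' @param gap surface-to-surface separation.
#' @param patch_fraction patch area fraction in `[0, 1]`.
#' @param p,g model parameters and grid.
#' @return list with `phi`, `eta` and the targets `A0`, `V0`, `P0`.
#' @export
make_two_sphere_state <- function(diameter, gap, patch_fraction, p, g) {
  Rv <- diameter / 2
  zc <- Rv + gap / 2
  phi <- compose_union(list(tanh_sphere(-zc, Rv, p, g),
                            tanh_sphere(zc, Rv, p, g)))
  eta <- init_patch_field(phi, 0, patch_fraction, p, g)
  A0 <- area_functional(phi, p, g)
  V0 <- volume_functional(phi, g)
  P0 <- patch_area_functional(phi, eta, p, g)
  list(phi = phi, eta = eta, A0 = A0, V0 = V0, P0 = P0)
}

#' Build the fused (prolate) final state of a fusion run
#'
#' Constrained relaxation of a smooth prolate-spheroid tanh guess at the
#' area and volume targets of the two-sphere state; at reduced volume
#' 1/sqrt(2) this settles on the stable prolate branch. The patch field
#' is seeded on the relaxed shape around z = 0 with the same patch area
#' target.
#'
#' @param two_sphere output of [make_two_sphere_state()].
#' @param patch_fraction patch area fraction.
#' @param p,g model parameters and grid.
#' @param s [relax_settings()] for the relaxation.
#' @return list with `phi`, `eta` and the final constraint report.
#' @export
make_prolate_state <- function(two_sphere, patch_fraction, p, g,
                               s = relax_settings(n_steps = 800L)) {
  A0 <- two_sphere$A0; V0 <- two_sphere$V0
  # capsule guess: smooth everywhere, wide neck, exact A/V match
  phi <- tanh_capsule(A0, V0, p, g)
  eta <- matrix(-1, g$nr, g$nz)
  pen <- default_penalties(p, A0, V0, NA_real_, g)
  cs <- constraint_set(A0 = A0, V0 = V0, P0 = NA_real_,
                       M1 = pen$M1, M2 = pen$M2, M3 = 0, M4 = 0)
  s$evolve_eta <- FALSE  # eta is a placeholder until the patch is seeded
  rx <- relax_image(phi, eta, p, cs, s, g)
  eta <- init_patch_field(rx$phi, 0, patch_fraction, p, g)
  list(phi = rx$phi, eta = eta, report = rx$report,
       constraints = rx$constraints)
}

#' Fused dumbbell phase field
#'
#' Smooth union (softly filleted maximum of signed distances) of two
#' just-touching spheres and an axial neck of the given radius: the
#' generic fused configuration of two equal vesicles. Relaxed under the
#' area/volume constraints of the two-sphere state this provides the
#' fused (prolate-branch) endpoint of a fusion pathway. Works in the
#' full domain and, with `z_min = contact_z`, in the mirror-symmetric
#' half domain.
#'
#' @param radius sphere radius.
#' @param neck_radius radius of the connecting neck.
#' @param p,g model parameters and grid.
#' @param contact_z contact plane.
#' @param gap residual sphere separation (default `0.3 eps`).
#' @return `nr x nz` matrix.
#' @export
tanh_fused_dumbbell <- function(radius, neck_radius, p, g,
                                contact_z = 0, gap = 0.3 * p$eps) {
  eps <- p$eps
  half <- abs(g$z_min - contact_z) < 1e-9
  R <- outer(g$r_centers, rep.int(1, g$nz))
  Z <- outer(rep.int(1, g$nr), g$z_centers)
  smax <- function(a, b, s = 4 * eps) (a + b + sqrt((a - b)^2 + s^2)) / 2
  zc <- contact_z + radius + gap / 2
  sd1 <- radius - sqrt(R^2 + (Z - zc)^2)
  sd_pair <- if (half) sd1 else {
    smax(sd1, radius - sqrt(R^2 + (Z - (2 * contact_z - zc))^2))
  }
  L <- 2 * (6 * eps + neck_radius^2 / radius)
  dz <- pmax(abs(Z - contact_z) - L / 2, 0)
  sd_neck <- neck_radius - sqrt(R^2 + dz^2)
  tanh(smax(sd_pair, sd_neck) / (sqrt(2) * eps))
}

#' Staged initial string for a fusion pathway
#'
#' Builds an initial path through physically sensible intermediates
#' instead of interpolating the endpoints directly (which sweeps broad
#' double-membrane configurations through the Gaussian-energy sink):
#' first the two vesicles approach (the neutral stretch of the path),
#' then an axial stalk nucleates at the contact point and widens into
#' the neck, and finally the wide-necked union blends into the fused
#' endpoint. The auxiliary field is re-seeded on every guess image by
#' [init_patch_field()], keeping the patch on the contact region with
#' the right area throughout.
#'
#' Works in the full domain (contact plane at `contact_z`) and in the
#' mirror-symmetric half domain (`z_min = 0`, sphere above, implicit
#' mirror below).
#'
#' @param endpoint_a,endpoint_b `list(phi, eta)` endpoint states, the
#'   two-vesicle and fused states (ideally pre-relaxed).
#' @param n_images number of images.
#' @param radius vesicle radius of the two-sphere state.
#' @param gap initial surface-to-surface separation.
#' @param patch_fraction patch area fraction (for re-seeding eta).
#' @param p,g model parameters and grid.
#' @param contact_z contact plane (default `0`).
#' @return a `string_state`.
#' @export
init_fusion_string <- function(endpoint_a, endpoint_b, n_images,
                               radius, gap, patch_fraction, p, g,
                               contact_z = 0) {
  if (n_images < 5) stop("need at least 5 images")
  half <- abs(g$z_min - contact_z) < 1e-9
  eps <- p$eps
  R <- outer(g$r_centers, rep.int(1, g$nz))
  Z <- outer(rep.int(1, g$nr), g$z_centers)
  # smooth maximum: fillets the junction between signed-distance bodies
  # (a hard max leaves a gradient crease that the Gaussian density
  # amplifies violently)
  smax <- function(a, b, s = 4 * eps) (a + b + sqrt((a - b)^2 + s^2)) / 2
  sd_sphere <- function(zc) radius - sqrt(R^2 + (Z - zc)^2)
  sd_pair <- function(gp) {
    zc <- contact_z + radius + gp / 2
    if (half) sd_sphere(zc) else smax(sd_sphere(zc),
                                      radius - sqrt(R^2 + (Z - (2 * contact_z - zc))^2))
  }
  sd_stub <- function(a, L) {
    dz <- pmax(abs(Z - contact_z) - L / 2, 0)
    a - sqrt(R^2 + dz^2)
  }
  c2 <- sqrt(2) * eps
  sphere_pair <- function(gp) tanh(sd_pair(gp) / c2)
  # capsule parameters of the fused state (for the neck radius scale)
  Afull <- area_functional(endpoint_b$phi, p, g) * (if (half) 2 else 1)
  a_cap <- sqrt(Afull / (4 * pi))  # upper bound; true neck target below
  seed_eta <- function(phi) {
    init_patch_field(phi, contact_z, patch_fraction, p, g)
  }

  # dense candidate path along the three stages; images for the string
  # are then *selected* at (approximately) equal arc length, so the
  # first reparametrization does not have to interpolate across stages
  nd <- max(4L * n_images, 40L)
  n1 <- round(0.25 * nd); n3 <- round(0.20 * nd); n2 <- nd - n1 - n3
  cand <- vector("list", nd + 1L)
  cand[[1L]] <- endpoint_a$phi
  k <- 2L
  for (j in seq_len(n1)) {
    gp <- gap * (1 - j / (n1 + 1)) + 0.3 * eps * (j / (n1 + 1))
    cand[[k]] <- sphere_pair(gp); k <- k + 1L
  }
  sd_base <- sd_pair(0.3 * eps)
  # the neck stops at half the vesicle radius: wider stubs add spurious
  # enclosed volume that the pressure constraint then has to crush out
  r_max_neck <- 0.5 * min(a_cap, radius)
  for (j in seq_len(n2)) {
    rn <- 2 * eps + (r_max_neck - 2 * eps) * j / n2
    cand[[k]] <- tanh(smax(sd_base,
                           sd_stub(rn, 2 * (6 * eps + rn^2 / radius))) /
                        c2)
    k <- k + 1L
  }
  phi_u <- cand[[k - 1L]]
  for (j in seq_len(n3)) {
    w <- j / (n3 + 1)
    cand[[k]] <- .interp_fields(phi_u, endpoint_b$phi, w, p, g)
    k <- k + 1L
  }
  cand[[nd + 1L]] <- endpoint_b$phi

  dists <- vapply(seq_len(nd), function(i) {
    sqrt(integrate_axisym((cand[[i + 1L]] - cand[[i]])^2, g))
  }, numeric(1))
  cum <- c(0, cumsum(dists)) / sum(dists)
  targets <- seq(0, 1, length.out = n_images)
  sel <- vapply(targets, function(a) which.min(abs(cum - a)), integer(1))
  sel[1L] <- 1L; sel[n_images] <- nd + 1L
  for (i in 2:n_images) {          # keep the selection strictly increasing
    if (sel[i] <= sel[i - 1L]) sel[i] <- sel[i - 1L] + 1L
  }
  sel <- pmin(sel, nd + 1L)

  images <- vector("list", n_images)
  images[[1L]] <- endpoint_a
  images[[n_images]] <- endpoint_b
  for (i in 2:(n_images - 1L)) {
    phi <- cand[[sel[i]]]
    images[[i]] <- list(phi = phi, eta = seed_eta(phi))
  }
  structure(
    list(images = images, n_images = as.integer(n_images),
         alpha = seq(0, 1, length.out = n_images)),
    class = "string_state")
}

#' Run the full fusion MEP experiment
#'
#' Orchestrates a fusion computation end to end: grid and parameter
#' setup, two-sphere and prolate endpoint construction, patch placement,
#' initial string, string-method evolution, profile extraction and
#' artifact output (MEP CSV, extrema JSON report, optional snapshots and
#' VTK exports, log with per-cycle convergence metrics).
#'
#' @param cfg configuration list from [read_run_config()] /
#'   [default_run_config()].
#' @param write_artifacts write output files under `cfg$output$dir`.
#' @param verbose print progress.
#' @return (invisibly) list with `mep` ([mep_profile()] result),
#'   `string`, `grid`, `params`, `targets` and `artifact_paths`.
#' @export
run_fusion_experiment <- function(cfg = default_run_config(),
                                  write_artifacts = TRUE,
                                  verbose = FALSE) {
  cfg <- validate_run_config(cfg)
  g <- build_grid(cfg$grid$nr, cfg$grid$nz, cfg$grid$r_max,
                  cfg$grid$z_min, cfg$grid$z_max)
  p <- phys_params(k = cfg$physics$k, kG0 = cfg$physics$kG0,
                   m = cfg$physics$m, eps = cfg$physics$eps,
                   mobility = cfg$physics$mobility)

  ts <- make_two_sphere_state(cfg$geometry$diameter, cfg$geometry$gap,
                              cfg$geometry$patch_fraction, p, g)
  pen <- default_penalties(p, ts$A0, ts$V0, ts$P0, g)
  for (nm in names(pen)) {
    if (!is.na(cfg$constraints[[nm]])) pen[[nm]] <- cfg$constraints[[nm]]
  }
  use_patch <- cfg$geometry$patch_fraction > 0
  cs <- constraint_set(
    A0 = ts$A0, V0 = ts$V0,
    P0 = if (use_patch) ts$P0 else NA_real_,
    M1 = pen$M1, M2 = pen$M2,
    M3 = if (use_patch) pen$M3 else 0,
    M4 = if (use_patch) pen$M4 else 0)

  s_inner <- relax_settings(dt = cfg$string$dt,
                            n_steps = cfg$string$n_inner,
                            tol = cfg$string$tol,
                            evolve_eta = use_patch,
                            eta_hold_cycles = if (use_patch) 50L else 0L,
                            surgery_eb = 500 * p$k)
  s_end <- relax_settings(dt = cfg$string$dt, n_steps = 400L,
                          evolve_eta = use_patch)
  # pre-relax both endpoints into their constrained minima (with the
  # patch constraints active) so the string starts between near-minima
  end_a <- relax_image(ts$phi, ts$eta, p, cs, s_end, g)
  pro <- make_prolate_state(ts, cfg$geometry$patch_fraction, p, g, s_end)
  end_b <- relax_image(pro$phi, pro$eta, p, cs, s_end, g)
  str0 <- init_fusion_string(list(phi = end_a$phi, eta = end_a$eta),
                             list(phi = end_b$phi, eta = end_b$eta),
                             cfg$string$n_images,
                             cfg$geometry$diameter / 2,
                             cfg$geometry$gap,
                             cfg$geometry$patch_fraction, p, g)
  str1 <- evolve_string(str0, p, cs, s_inner, cfg$string$n_outer, g,
                        verbose = verbose)
  mep <- mep_profile(str1, p, cs, g)

  paths <- list()
  if (write_artifacts) {
    dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
    paths$mep_csv <- file.path(cfg$output$dir, "mep_profile.csv")
    write_mep_csv(mep, paths$mep_csv)
    paths$extrema <- file.path(cfg$output$dir, "extrema.json")
    jsonlite::write_json(
      list(minima = mep$minima, saddles = mep$saddles,
           barriers = mep$barriers),
      paths$extrema, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths$log <- file.path(cfg$output$dir, "run.log")
    conv <- attr(str1, "convergence")
    writeLines(c(
      sprintf("vesiclefusion %s  config %s",
              as.character(utils::packageVersion("vesiclefusion")),
              .config_hash(cfg)),
      sprintf("grid %dx%d  images %d  outer cycles %d",
              g$nr, g$nz, cfg$string$n_images, length(conv)),
      sprintf("cycle %d  conv %.6g", seq_along(conv), conv)),
      paths$log)
    if (cfg$output$snapshot_every > 0L) {
      idx <- seq(1L, str1$n_images, by = cfg$output$snapshot_every)
      paths$snapshots <- character(0)
      for (i in idx) {
        sp <- file.path(cfg$output$dir, sprintf("image_%03d.snap", i))
        im <- str1$images[[i]]
        fr <- force_density(im$phi, im$eta, p, g)
        write_snapshot(sp,
                       list(phi = im$phi, eta = im$eta,
                            force_r = fr$force_r, force_z = fr$force_z),
                       meta = list(alpha = str1$alpha[i],
                                   grid = list(nr = g$nr, nz = g$nz,
                                               r_max = g$r_max,
                                               z_min = g$z_min,
                                               z_max = g$z_max),
                                   k = p$k, kG0 = p$kG0, eps = p$eps))
        vp <- file.path(cfg$output$dir, sprintf("image_%03d.vtk", i))
        write_vtk(vp, list(phi = im$phi, eta = im$eta), g)
        paths$snapshots <- c(paths$snapshots, sp, vp)
      }
    }
  }
  invisible(list(mep = mep, string = str1, grid = g, params = p,
                 targets = list(A0 = ts$A0, V0 = ts$V0, P0 = ts$P0),
                 constraints = cs, artifact_paths = paths))
}
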