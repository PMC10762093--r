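#' Equilibrium tanh profile of a spherical vesicle
#'
#' Phase field of a sphere of given radius centered on the symmetry axis:
#' `phi(r, z) = tanh((radius - d) / (sqrt(2) eps))` with `d` the distance
#' to the center `(0, center_z)`. This is the 1D equilibrium interface
#' profile wrapped around the sphere: +1 deep inside, -1 far outside, 0 on
#' the membrane mid-surface.
#'
#' @param center_z axial position of the sphere center.
#' @param radius sphere radius; must exceed ~3 eps and fit in the domain
#'   with a margin of at least 6 eps (one bilayer thickness).
#' @param p [phys_params()].
#' @param g [build_grid()] grid.
#' @param check_fit verify the 6 eps boundary margin. Set `FALSE` for
#'   half-domain (mirror-symmetric) setups where the sphere legitimately
#'   approaches the symmetry plane at `z_min`.
#' @return `nr x nz` matrix.
#' @export
tanh_sphere <- function(center_z, radius, p, g, check_fit = TRUE) {
  if (radius <= 3 * p$eps) stop("radius must exceed 3*eps")
  margin <- 6 * p$eps
  if (check_fit &&
      (radius + margin > g$r_max ||
       center_z - radius - margin < g$z_min ||
       center_z + radius + margin > g$z_max)) {
    stop("sphere does not fit in the domain with a 6*eps margin")
  }
  d <- sqrt(outer(g$r_centers^2, rep.int(1, g$nz)) +
            outer(rep.int(1, g$nr), (g$z_centers - center_z)^2))
  tanh((radius - d) / (sqrt(2) * p$eps))
}

#' Equilibrium tanh slab profile
#'
#' Flat membrane normal to z: `phi = tanh((z0 - z)/(sqrt(2) eps))` for a
#' single interface, or a bounded slab between two interfaces. Used mostly
#' as an analytic test configuration (zero bending and Gaussian energy).
#'
#' @param z0 interface position (upper interface if `z1` given).
#' @param p,g model parameters and grid.
#' @param z1 optional lower interface; if given the field is +1 between
#'   `z1` and `z0` and -1 outside, assembled as the smooth superposition
#'   `tanh((z0 - z)/c) + tanh((z - z1)/c) - 1` so that no derivative kink
#'   is introduced between the interfaces.
#' @return `nr x nz` matrix.
#' @export
tanh_slab <- function(z0, p, g, z1 = NULL) {
  z <- outer(rep.int(1, g$nr), g$z_centers)
  c2 <- sqrt(2) * p$eps
  if (is.null(z1)) {
    tanh((z0 - z) / c2)
  } else {
    tanh((z0 - z) / c2) + tanh((z - z1) / c2) - 1
  }
}

#' Union of phase-field configurations
#'
#' Pointwise maximum of the given fields. For interfaces separated by at
#' least one bilayer thickness this reproduces the union of the enclosed
#' regions exactly (plateaus are preserved); it is how the two-vesicle
#' initial state is assembled from two single spheres.
#'
#' @param fields list of `nr x nz` matrices on the same grid.
#' @return `nr x nz` matrix.
#' @export
compose_union <- function(fields) {
  if (!is.list(fields) || length(fields) < 1L) {
    stop("need at least one field")
  }
  d <- dim(fields[[1L]])
  out <- fields[[1L]]
  for (f in fields[-1L]) {
    if (!identical(dim(f), d)) stop("fields live on different grids")
    out <- pmax(out, f)
  }
  out
}

#' Auxiliary field marking the modified-modulus patch
#'
#' Builds the auxiliary field eta tagging the membrane patch whose Gaussian
#' modulus is modified: eta = +1 inside a cap-shaped region centered on the
#' symmetry axis around `contact_z` (covering both apposed membranes near
#' the contact point), -1 elsewhere, with a tanh cross-profile of width
#' `sqrt(2) eps`. The cap extent is found by bisection so that the patch
#' area fraction `P[phi, eta] / A[phi]` matches `area_fraction` within 5%.
#' The membrane field `phi` is never modified.
#'
#' @param phi membrane phase field.
#' @param contact_z axial position of the contact point.
#' @param area_fraction requested patch fraction of the total area, in
#'   `[0, 1]`.
#' @param p,g model parameters and grid.
#' @return eta field, `nr x nz` matrix.
#' @export
init_patch_field <- function(phi, contact_z, area_fraction, p, g) {
  .check_field(phi, g)
  if (!is.finite(area_fraction) || area_fraction < 0 || area_fraction > 1) {
    stop("area_fraction must be in [0, 1]")
  }
  if (area_fraction == 0) {
    return(matrix(-1, g$nr, g$nz))
  }
  A <- area_functional(phi, p, g)
  if (A <= 0) stop("phi has no membrane area to place a patch on")
  # distance from the contact point on the axis
  d <- sqrt(outer(g$r_centers^2, rep.int(1, g$nz)) +
            outer(rep.int(1, g$nr), (g$z_centers - contact_z)^2))
  eta_of <- function(rho) tanh((rho - d) / (sqrt(2) * p$eps))
  frac_of <- function(rho) {
    patch_area_functional(phi, eta_of(rho), p, g) / A
  }
  lo <- 0
  hi <- sqrt(g$r_max^2 + (g$z_max - g$z_min)^2)
  if (frac_of(hi) < area_fraction * 0.95) {
    if (area_fraction >= 0.99) {
      return(matrix(1, g$nr, g$nz))
    }
    stop("requested area_fraction unreachable for this configuration")
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (frac_of(mid) < area_fraction) lo <- mid else hi <- mid
  }
  rho <- (lo + hi) / 2
  eta <- eta_of(rho)
  got <- frac_of(rho)
  if (abs(got - area_fraction) > 0.05 * max(area_fraction, 1e-12)) {
    stop(sprintf(
      "patch bisection failed: reached fraction %.4g, wanted %.4g",
      got, area_fraction))
  }
  eta
}

# Geometric signed distance to the zero level set of a field, computed
# as a distance transform against the (densified) marching-squares
# contour, signed by the field and capped at `cap`.  Unlike an atanh
# inversion of the tanh profile this is insensitive to plateau noise of
# relaxed fields, which atanh amplifies into O(10 eps) distance ripples.
# Single-sign fields map to a uniform +-cap.
.geo_signed_distance <- function(f, g, cap) {
  sgn <- sign(f + 1e-300)
  if (min(f) >= 0 || max(f) <= 0) {
    return(matrix(cap * sgn[1], nrow(f), ncol(f)))
  }
  cl <- grDevices::contourLines(g$r_centers, g$z_centers, f, levels = 0)
  rc <- rep(g$r_centers, times = ncol(f))
  zc <- rep(g$z_centers, each = nrow(f))
  d2min <- rep.int(cap^2, length(rc))
  for (li in cl) {
    x <- li$x; y <- li$y
    n <- length(x)
    if (n < 2L) next
    for (k in seq_len(n - 1L)) {
      # exact distance to the segment (vertex sampling leaves a
      # sub-cell sawtooth in the distance field that the bending
      # energy amplifies)
      ex <- x[k + 1L] - x[k]; ey <- y[k + 1L] - y[k]
      L2 <- ex * ex + ey * ey
      if (L2 == 0) next
      t <- pmin(pmax(((rc - x[k]) * ex + (zc - y[k]) * ey) / L2, 0), 1)
      d2min <- pmin(d2min,
                    (rc - (x[k] + t * ex))^2 + (zc - (y[k] + t * ey))^2)
    }
  }
  matrix(pmin(sqrt(d2min), cap), nrow(f), ncol(f)) * sgn
}

# Interpolate between two (phi, eta)-type fields at fraction w by
# blending geometric signed distances (re-tanh-ed to the equilibrium
# profile) plus a linear blend of the profile residuals.  Exactly
# reproduces the inputs at w = 0, 1 and for identical inputs.
.interp_fields <- function(f1, f2, w, p, g, cap = NULL) {
  if (is.null(cap)) cap <- 12 * p$eps
  c2 <- sqrt(2) * p$eps
  D1 <- .geo_signed_distance(f1, g, cap)
  D2 <- .geo_signed_distance(f2, g, cap)
  r1 <- f1 - tanh(D1 / c2)
  r2 <- f2 - tanh(D2 / c2)
  tanh(((1 - w) * D1 + w * D2) / c2) + (1 - w) * r1 + w * r2
}

# retained for callers that need the (capped) profile-inversion distance
.signed_distance <- function(f, eps, cap = 0.995) {
  sqrt(2) * eps * atanh(pmin(pmax(f, -cap), cap))
}

#' Initial guess for a string of images
#'
#' Builds a path of `n_images` (phi, eta) pairs connecting two endpoint
#' states. Intermediate images interpolate geometric signed-distance
#' representations of the endpoints (distance transforms to their zero
#' level sets) linearly and re-apply the tanh profile, which keeps the
#' interface width uniform along the guess (direct linear blending of phi
#' would smear interfaces). The profile residuals are blended linearly on
#' top, so identical endpoints reproduce identical interior images. The
#' endpoints themselves are copied bit-identically.
#'
#' @param endpoint_a,endpoint_b lists `list(phi = , eta = )` on a common
#'   grid.
#' @param n_images number of images N >= 3.
#' @param p,g model parameters and grid.
#' @return object of class `string_state`: list with `images` (list of
#'   `list(phi, eta)`), `n_images` and `alpha` (normalized arc length,
#'   initialized uniformly as i/(N-1)).
#' @export
init_string <- function(endpoint_a, endpoint_b, n_images, p, g) {
  if (n_images < 3) stop("n_images must be at least 3")
  .check_field(endpoint_a$phi, g); .check_field(endpoint_a$eta, g)
  .check_field(endpoint_b$phi, g); .check_field(endpoint_b$eta, g)
  c2 <- sqrt(2) * p$eps
  cap <- 12 * p$eps
  sa_phi <- .geo_signed_distance(endpoint_a$phi, g, cap)
  sb_phi <- .geo_signed_distance(endpoint_b$phi, g, cap)
  sa_eta <- .geo_signed_distance(endpoint_a$eta, g, cap)
  sb_eta <- .geo_signed_distance(endpoint_b$eta, g, cap)
  # the profile residual (plateau overshoot, relaxed-profile details) is
  # carried through the interpolation linearly, so identical endpoints
  # reproduce identical interior images
  ra_phi <- endpoint_a$phi - tanh(sa_phi / c2)
  rb_phi <- endpoint_b$phi - tanh(sb_phi / c2)
  ra_eta <- endpoint_a$eta - tanh(sa_eta / c2)
  rb_eta <- endpoint_b$eta - tanh(sb_eta / c2)
  images <- vector("list", n_images)
  images[[1L]] <- list(phi = endpoint_a$phi, eta = endpoint_a$eta)
  images[[n_images]] <- list(phi = endpoint_b$phi, eta = endpoint_b$eta)
  if (n_images > 2) {
    for (i in 2:(n_images - 1L)) {
      w <- (i - 1) / (n_images - 1)
      images[[i]] <- list(
        phi = tanh(((1 - w) * sa_phi + w * sb_phi) / c2) +
          (1 - w) * ra_phi + w * rb_phi,
        eta = tanh(((1 - w) * sa_eta + w * sb_eta) / c2) +
          (1 - w) * ra_eta + w * rb_eta)
    }
  }
  structure(
    list(images = images, n_images = as.integer(n_images),
         alpha = seq(0, 1, length.out = n_images)),
    class = "string_state")
}

#' @export
print.string_state <- function(x, ...) {
  cat(sprintf("string of %d images, alpha in [0, 1]\n", x$n_images))
  invisible(x)
}

#' Validate a membrane field
#'
#' Checks that a field is finite everywhere and stays within the physical
#' plateau range `[-1 - delta, 1 + delta]` with a small overshoot
#' tolerance.
#'
#' @param f field matrix.
#' @param delta overshoot tolerance (default 0.1).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_membrane_field <- function(f, delta = 0.1) {
  if (!all(is.finite(f))) stop("field contains non-finite values")
  if (min(f) < -1 - delta || max(f) > 1 + delta) {
    stop("field exceeds [-1, 1] beyond the overshoot tolerance")
  }
  invisible(TRUE)
}
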