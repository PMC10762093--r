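# Prolate spheroid geometry: closed forms for the reduced volume as a
# function of the aspect ratio, and a tanh phase field built from an
# approximate signed distance to the spheroid surface.

# surface area of a prolate spheroid with semi-axes (a, a, c), c > a
.spheroid_area <- function(a, c) {
  if (c <= a) return(4 * pi * a^2 * (c / a))  # not used below a sphere
  e <- sqrt(1 - (a / c)^2)
  2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
}

# reduced volume of a prolate spheroid with aspect ratio q = c/a
.spheroid_v <- function(q) {
  V <- 4 / 3 * pi * q          # a = 1
  A <- .spheroid_area(1, q)
  D <- sqrt(A / pi)
  V / (pi * D^3 / 6)
}

#' Capsule (spherocylinder) phase field
#'
#' Tanh profile around a cylinder of radius `a` and length `L` with
#' hemispherical caps, centered at the origin on the symmetry axis. The
#' two parameters are solved so that the sharp-interface area and volume
#' match `A_target` and `V_target` exactly, which makes the capsule the
#' preferred smooth initial guess for the fused state: its signed
#' distance is exact (no crease anywhere) and its neck is wide, far from
#' the pinch-off watershed.
#'
#' @param A_target,V_target sharp-interface area and volume to match.
#' @param p,g model parameters and grid.
#' @param center_z axial position of the capsule center (default 0; for
#'   half-domain setups with the symmetry plane at `z_min = 0` the
#'   half-capsule is obtained with the default).
#' @return `nr x nz` matrix.
#' @export
tanh_capsule <- function(A_target, V_target, p, g, center_z = 0) {
  amax <- sqrt(A_target / (4 * pi))
  fa <- function(a) (A_target / 2) * a - (2 / 3) * pi * a^3 - V_target
  if (fa(amax) < 0) stop("V_target too large for a capsule of this area")
  a <- stats::uniroot(fa, c(1e-9, amax))$root
  L <- (A_target - 4 * pi * a^2) / (2 * pi * a)
  if (center_z + L / 2 + a + 6 * p$eps > g$z_max ||
      a + 6 * p$eps > g$r_max) {
    stop("capsule does not fit in the domain")
  }
  .capsule_field(a, L, center_z, p, g)
}

.capsule_field <- function(a, L, center_z, p, g) {
  R <- outer(g$r_centers, rep.int(1, g$nz))
  Z <- outer(rep.int(1, g$nr), g$z_centers) - center_z
  dz <- pmax(abs(Z) - L / 2, 0)
  d <- sqrt(R^2 + dz^2)
  tanh((a - d) / (sqrt(2) * p$eps))
}

#' Prolate spheroid phase field
#'
#' Tanh profile around a prolate spheroid centered at the origin with the
#' given total area and aspect ratio solved from the requested reduced
#' volume. Used as the smooth initial guess for the fused (final) state
#' of a fusion pathway, then polished by constrained relaxation.
#'
#' @param A_target total membrane area.
#' @param v_target reduced volume in (0.65, 1); 1/sqrt(2) for the
#'   two-equal-spheres family.
#' @param p,g model parameters and grid.
#' @return `nr x nz` matrix.
#' @export
tanh_prolate <- function(A_target, v_target, p, g) {
  if (v_target >= 1 || v_target <= 0.65) {
    stop("v_target must lie in (0.65, 1) for a prolate spheroid guess")
  }
  q <- stats::uniroot(function(q) .spheroid_v(q) - v_target,
                      c(1 + 1e-9, 10))$root
  a <- sqrt(A_target / .spheroid_area(1, q))
  c <- q * a
  R <- outer(g$r_centers, rep.int(1, g$nz))
  Z <- outer(rep.int(1, g$nr), g$z_centers)
  m <- sqrt((R / a)^2 + (Z / c)^2)
  gm <- pmax(sqrt(R^2 / a^4 + Z^2 / c^4) / pmax(m, 1e-12), 1e-12)
  d <- (1 - m) / gm  # approximate signed distance, positive inside
  if (c + 6 * p$eps > g$z_max || a + 6 * p$eps > g$r_max) {
    stop("prolate spheroid does not fit in the domain")
  }
  tanh(d / (sqrt(2) * p$eps))
}
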