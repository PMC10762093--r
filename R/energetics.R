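#' Bending chemical potential Psi_B
#'
#' Pointwise quantity whose square integrates to the bending energy:
#' `Psi_B = lap(phi) - (phi^2 - 1)(phi + sqrt(2) eps m) / eps^2`.
#' It vanishes identically on the 1D equilibrium tanh profile with `m = 0`
#' and, in the sharp-interface limit, is proportional to the local mean
#' curvature deviation (M - m) on the membrane.
#'
#' @param phi phase field matrix.
#' @param p [phys_params()].
#' @param g [build_grid()] grid.
#' @return matrix of the same shape.
#' @export
psi_bending <- function(phi, p, g) {
  .check_field(phi, g)
  laplacian_cyl(phi, g) -
    (phi^2 - 1) * (phi + sqrt(2) * p$eps * p$m) / p$eps^2
}

#' Diffuse-interface bending energy
#'
#' `E_B = k (3 / (4 sqrt(2))) eps * integral Psi_B^2 dV`, which approaches
#' the Canham-Helfrich bending energy `2k integral (M - m)^2 dS` in the
#' sharp-interface limit (8 pi k for a sphere with m = 0).
#'
#' @inheritParams psi_bending
#' @return scalar energy in kBT.
#' @export
energy_bending <- function(phi, p, g) {
  psi <- psi_bending(phi, p, g)
  p$k * (3 / (4 * sqrt(2))) * p$eps * integrate_axisym(psi^2, g)
}

#' Gaussian-curvature density Psi_G
#'
#' The diffuse-interface counterpart of the Gaussian curvature integrand:
#' a combination of first, second and third derivatives of phi that, once
#' weighted by `(35 / (16 sqrt(2))) eps^3 k_G` and integrated, approaches
#' the Gaussian energy `k_G integral G dS`. It vanishes identically for
#' any unidirectional (flat-interface) field.
#'
#' @inheritParams field_gradient
#' @return matrix of the same shape.
#' @export
psi_gaussian <- function(f, g) {
  .check_field(f, g)
  fr <- deriv_r(f, g); fz <- deriv_z(f, g)
  lap <- deriv_rr(f, g) + fr / g$r_centers + deriv_zz(f, g)
  q <- fr^2 + fz^2
  qr <- deriv_r(q, g); qz <- deriv_z(q, g)
  lap_q <- deriv_rr(q, g) + qr / g$r_centers + deriv_zz(q, g)
  lap_r <- deriv_r(lap, g); lap_z <- deriv_z(lap, g)
  (qr^2 + qz^2) / 2 -
    (qr * fr + qz * fz) * lap +
    q * (lap^2 + fr * lap_r + fz * lap_z - lap_q / 2)
}

#' Local Gaussian modulus as a function of the auxiliary field
#'
#' `k_G(eta) = kG0 (1 - eta)^2 / 4`: equal to the baseline modulus `kG0`
#' where `eta = -1` (unmodified membrane) and exactly zero where
#' `eta = +1` (the modified patch).
#'
#' @param eta_value auxiliary field value(s), dimensionless.
#' @param kG0 baseline Gaussian modulus (kBT).
#' @return modulus value(s) in kBT.
#' @export
kg_of_eta <- function(eta_value, kG0) {
  kG0 * (1 - eta_value)^2 / 4
}

#' Diffuse-interface Gaussian energy with locally variable modulus
#'
#' `E_G = (35 / (16 sqrt(2))) eps^3 * integral k_G(eta) Psi_G dV`. With a
#' uniform modulus this is quantized by the Gauss-Bonnet theorem in the
#' sharp-interface limit: 4 pi k_G per spherical component, so merging two
#' spheres into one releases `-4 pi k_G` (about +251 kBT for
#' kG = -20 kBT), the topological fusion barrier this package is built to
#' interrogate.
#'
#' @param phi phase field.
#' @param eta auxiliary field (use `-1` everywhere for a uniform modulus).
#' @param p,g model parameters and grid.
#' @return scalar energy in kBT.
#' @export
energy_gaussian <- function(phi, eta, p, g) {
  .check_field(eta, g)
  psi <- psi_gaussian(phi, g)
  (35 / (16 * sqrt(2))) * p$eps^3 *
    integrate_axisym(kg_of_eta(eta, p$kG0) * psi, g)
}

#' Auxiliary-field energy
#'
#' A bending-type energy for the auxiliary field with rigidity 10^-3 k,
#' `E_A = 1e-3 k (3 / (4 sqrt(2))) eps * integral Psi_A^2 dV` with
#' `Psi_A = lap(eta) - (eta^2 - 1) eta / eps^2`, which keeps eta on the
#' equilibrium tanh cross-profile without influencing the membrane
#' energetics appreciably.
#'
#' @param eta auxiliary field.
#' @param p,g model parameters and grid.
#' @return scalar energy in kBT (nonnegative).
#' @export
energy_auxiliary <- function(eta, p, g) {
  psi <- psi_auxiliary(eta, p, g)
  1e-3 * p$k * (3 / (4 * sqrt(2))) * p$eps * integrate_axisym(psi^2, g)
}

psi_auxiliary <- function(eta, p, g) {
  .check_field(eta, g)
  laplacian_cyl(eta, g) - (eta^2 - 1) * eta / p$eps^2
}

#' Orthogonality penalty functional
#'
#' `O = integral |grad(phi) . grad(eta)|^2 dV`, driving the auxiliary-field
#' interface to cross the membrane at right angles so that eta partitions
#' the membrane surface rather than displacing it.
#'
#' @inheritParams energy_gaussian
#' @return nonnegative scalar.
#' @export
orthogonality_penalty <- function(phi, eta, g) {
  .check_field(phi, g); .check_field(eta, g)
  s <- deriv_r(phi, g) * deriv_r(eta, g) + deriv_z(phi, g) * deriv_z(eta, g)
  integrate_axisym(s^2, g)
}

#' Membrane area functional
#'
#' `A = (3 / (4 sqrt(2))) eps * integral [ (1 - phi^2)^2 / (2 eps^2) +
#' |grad phi|^2 ] dV`; converges to the membrane surface area in the
#' sharp-interface limit (4 pi R^2 for a tanh sphere).
#'
#' @inheritParams energy_bending
#' @return nonnegative scalar, units length^2.
#' @export
area_functional <- function(phi, p, g) {
  .check_field(phi, g)
  q <- deriv_r(phi, g)^2 + deriv_z(phi, g)^2
  (3 / (4 * sqrt(2))) * p$eps *
    integrate_axisym((1 - phi^2)^2 / (2 * p$eps^2) + q, g)
}

#' Enclosed volume functional
#'
#' `V = integral (1 + phi) / 2 dV`; the volume of the phi = +1 region.
#'
#' @inheritParams field_gradient
#' @return scalar between 0 and the domain measure, units length^3.
#' @export
volume_functional <- function(f, g) {
  .check_field(f, g)
  integrate_axisym((1 + f) / 2, g)
}

#' Patch area functional
#'
#' Area of the membrane portion lying in the eta = +1 zone:
#' the area integrand weighted by `(eta + 1)^2 / 4`, which is 1 on the
#' patch and 0 on the unmodified membrane.
#'
#' @inheritParams energy_gaussian
#' @return scalar in `[0, A]`, units length^2.
#' @export
patch_area_functional <- function(phi, eta, p, g) {
  .check_field(phi, g); .check_field(eta, g)
  q <- deriv_r(phi, g)^2 + deriv_z(phi, g)^2
  (3 / (4 * sqrt(2))) * p$eps *
    integrate_axisym(((eta + 1)^2 / 4) *
                       ((1 - phi^2)^2 / (2 * p$eps^2) + q), g)
}

#' Modified (augmented) total energy and its components
#'
#' Assembles the full augmented-Lagrangian energy
#' `Ebar = E_B + E_G + gamma (A - A0) + M1/2 (A - A0)^2 + dp (V - V0) +
#' M2/2 (V - V0)^2 + gamma_p (P - P0) + M3/2 (P - P0)^2 + E_A + M4 O^2`
#' and reports every component.
#'
#' @param phi,eta fields.
#' @param p [phys_params()].
#' @param cs [constraint_set()].
#' @param g grid.
#' @return object of class `energy_report`: list with `E_B`, `E_G`, `E_A`,
#'   `O_pen`, `A`, `V`, `P`, `E` (= E_B + E_G) and `E_bar`.
#' @export
total_modified_energy <- function(phi, eta, p, cs, g) {
  E_B <- energy_bending(phi, p, g)
  E_G <- energy_gaussian(phi, eta, p, g)
  E_A <- energy_auxiliary(eta, p, g)
  O <- orthogonality_penalty(phi, eta, g)
  A <- area_functional(phi, p, g)
  V <- volume_functional(phi, g)
  P <- patch_area_functional(phi, eta, p, g)
  dA <- A - cs$A0; dV <- V - cs$V0
  dP <- if (is.na(cs$P0)) 0 else P - cs$P0
  E <- E_B + E_G
  E_bar <- E +
    cs$gamma * dA + 0.5 * cs$M1 * dA^2 +
    cs$delta_p * dV + 0.5 * cs$M2 * dV^2 +
    cs$gamma_p * dP + 0.5 * cs$M3 * dP^2 +
    E_A + cs$M4 * O^2
  structure(
    list(E_B = E_B, E_G = E_G, E_A = E_A, O_pen = O,
         A = A, V = V, P = P, E = E, E_bar = E_bar),
    class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("energy report (kBT)\n")
  cat(sprintf("  E_B = %.6g  E_G = %.6g  E = %.6g\n", x$E_B, x$E_G, x$E))
  cat(sprintf("  E_A = %.3g  O = %.3g  E_bar = %.6g\n",
              x$E_A, x$O_pen, x$E_bar))
  cat(sprintf("  A = %.6g  V = %.6g  P = %.6g\n", x$A, x$V, x$P))
  invisible(x)
}
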