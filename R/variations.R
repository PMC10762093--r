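# Functional derivatives of every term of the modified energy with respect
# to phi and eta.  All derivatives are defined with respect to the
# axisymmetric volume inner product <u, v> = integral u v 2 pi r dr dz, so
# that for any smooth perturbation dphi,
#   d/dh E[phi + h dphi] |_{h=0} = integrate_axisym(dE_dphi * dphi).
# Each closed form below is validated against central finite-difference
# directional derivatives in the test suite.

#' Functional derivative of the bending energy
#'
#' Euler-Lagrange expression of the bending functional:
#' `dE_B/dphi = 2 c_B [ lap(Psi_B) - (3 phi^2 - 1 + 2 sqrt(2) eps m phi)
#' Psi_B / eps^2 ]` with `c_B = k (3/(4 sqrt(2))) eps`.
#'
#' @inheritParams psi_bending
#' @return matrix of the same shape.
#' @export
d_bending_dphi <- function(phi, p, g) {
  psi <- psi_bending(phi, p, g)
  cB <- p$k * (3 / (4 * sqrt(2))) * p$eps
  2 * cB * (laplacian_cyl(psi, g) -
              (3 * phi^2 - 1 + 2 * sqrt(2) * p$eps * p$m * phi) *
                psi / p$eps^2)
}

# Spatial derivative fields of the local Gaussian modulus k_G(eta), by
# chain rule from spectral derivatives of eta (not by differencing k_G).
.kg_derivs <- function(eta, kG0, g) {
  er <- deriv_r(eta, g); ez <- deriv_z(eta, g)
  err <- deriv_rr(eta, g); ezz <- deriv_zz(eta, g)
  erz <- deriv_z(er, g)
  one <- 1 - eta
  list(
    kg   = kG0 * one^2 / 4,
    kgr  = -kG0 * one * er / 2,
    kgz  = -kG0 * one * ez / 2,
    kgrr = kG0 * (er^2 - one * err) / 2,
    kgzz = kG0 * (ez^2 - one * ezz) / 2,
    kgrz = kG0 * (er * ez - one * erz) / 2)
}

#' Functional derivative of the Gaussian energy with respect to phi
#'
#' Axisymmetric closed form of dE_G/dphi in the presence of a locally
#' variable modulus k_G(eta(x)):
#' `(35/(8 sqrt(2))) (eps^3 / r) [ 12 k_G phi_r (phi_rz^2 - phi_rr phi_zz)
#'  + phi_r phi_z^2 kG_rr + 6 phi_r (phi_r phi_rz - phi_z phi_rr) kG_z
#'  + phi_r^3 kG_zz - 2 phi_r^2 phi_z kG_rz
#'  + (4 phi_r phi_z phi_rz + phi_rr phi_z^2 - 5 phi_r^2 phi_zz) kG_r ]`
#' where subscripts denote r/z partial derivatives (spectral) and the k_G
#' derivatives are obtained by chain rule from eta.
#'
#' @inheritParams energy_gaussian
#' @return matrix of the same shape.
#' @export
d_gaussian_dphi <- function(phi, eta, p, g) {
  .check_field(phi, g); .check_field(eta, g)
  fr <- deriv_r(phi, g); fz <- deriv_z(phi, g)
  frr <- deriv_rr(phi, g); fzz <- deriv_zz(phi, g)
  frz <- deriv_z(fr, g)
  kd <- .kg_derivs(eta, p$kG0, g)
  bracket <-
    12 * kd$kg * fr * (frz^2 - frr * fzz) +
    fr * fz^2 * kd$kgrr +
    6 * fr * (fr * frz - fz * frr) * kd$kgz +
    fr^3 * kd$kgzz +
    -2 * fr^2 * fz * kd$kgrz +
    (4 * fr * fz * frz + frr * fz^2 - 5 * fr^2 * fzz) * kd$kgr
  (35 / (8 * sqrt(2))) * p$eps^3 * bracket / g$r_centers
}

#' Functional derivative of the Gaussian energy with respect to eta
#'
#' E_G depends on eta only pointwise through the modulus, so
#' `dE_G/deta = (35/(16 sqrt(2))) eps^3 kG'(eta) Psi_G` with
#' `kG'(eta) = -kG0 (1 - eta)/2` (zero at eta = +1: the patch interior
#' exerts no force on eta through E_G).
#'
#' @inheritParams energy_gaussian
#' @return matrix of the same shape.
#' @export
d_gaussian_deta <- function(phi, eta, p, g) {
  .check_field(eta, g)
  (35 / (16 * sqrt(2))) * p$eps^3 *
    (-p$kG0 * (1 - eta) / 2) * psi_gaussian(phi, g)
}

# dA/dphi = -2 c_A [ lap(phi) + phi (1 - phi^2) / eps^2 ],
# c_A = (3/(4 sqrt(2))) eps
d_area_dphi <- function(phi, p, g) {
  cA <- (3 / (4 * sqrt(2))) * p$eps
  -2 * cA * (laplacian_cyl(phi, g) + phi * (1 - phi^2) / p$eps^2)
}

# dV/dphi = 1/2
d_volume_dphi <- function(phi) {
  matrix(0.5, nrow(phi), ncol(phi))
}

# dP/dphi = -2 c_A [ w lap(phi) + grad(w) . grad(phi)
#                    + w phi (1 - phi^2)/eps^2 ],  w = (eta + 1)^2 / 4
d_patch_dphi <- function(phi, eta, p, g) {
  cA <- (3 / (4 * sqrt(2))) * p$eps
  w <- (eta + 1)^2 / 4
  wr <- (eta + 1) / 2 * deriv_r(eta, g)
  wz <- (eta + 1) / 2 * deriv_z(eta, g)
  -2 * cA * (w * laplacian_cyl(phi, g) +
               wr * deriv_r(phi, g) + wz * deriv_z(phi, g) +
               w * phi * (1 - phi^2) / p$eps^2)
}

# dP/deta = c_A (eta + 1)/2 [ (1 - phi^2)^2/(2 eps^2) + |grad phi|^2 ]
d_patch_deta <- function(phi, eta, p, g) {
  cA <- (3 / (4 * sqrt(2))) * p$eps
  q <- deriv_r(phi, g)^2 + deriv_z(phi, g)^2
  cA * (eta + 1) / 2 * ((1 - phi^2)^2 / (2 * p$eps^2) + q)
}

# dO/dphi = -2 div( s grad(eta) ),  s = grad(phi) . grad(eta)
# (axisymmetric divergence: d_r + 1/r + d_z)
d_orth_dphi <- function(phi, eta, g) {
  s <- deriv_r(phi, g) * deriv_r(eta, g) + deriv_z(phi, g) * deriv_z(eta, g)
  a <- s * deriv_r(eta, g)
  b <- s * deriv_z(eta, g)
  -2 * (deriv_r(a, g) + a / g$r_centers + deriv_z(b, g))
}

d_orth_deta <- function(phi, eta, g) {
  d_orth_dphi(eta, phi, g)
}

# dE_A/deta = 2 c_E [ lap(Psi_A) - (3 eta^2 - 1) Psi_A / eps^2 ]
d_auxiliary_deta <- function(eta, p, g) {
  psi <- psi_auxiliary(eta, p, g)
  cE <- 1e-3 * p$k * (3 / (4 * sqrt(2))) * p$eps
  2 * cE * (laplacian_cyl(psi, g) - (3 * eta^2 - 1) * psi / p$eps^2)
}

# All derivatives and scalar functionals in one pass (shared spectral
# derivatives); the workhorse behind the public d_total_* wrappers and the
# relaxation/string drivers.
.grad_all <- function(phi, eta, p, cs, g, want_eta = TRUE) {
  fr <- deriv_r(phi, g); fz <- deriv_z(phi, g)
  frr <- deriv_rr(phi, g); fzz <- deriv_zz(phi, g)
  frz <- deriv_z(fr, g)
  lap_phi <- frr + fr / g$r_centers + fzz
  er <- deriv_r(eta, g); ez <- deriv_z(eta, g)
  err <- deriv_rr(eta, g); ezz <- deriv_zz(eta, g)
  erz <- deriv_z(er, g)

  eps2 <- p$eps^2
  cA <- (3 / (4 * sqrt(2))) * p$eps
  cB <- p$k * cA

  # scalar functionals
  q <- fr^2 + fz^2
  area_den <- (1 - phi^2)^2 / (2 * eps2) + q
  A <- cA * integrate_axisym(area_den, g)
  V <- integrate_axisym((1 + phi) / 2, g)
  w <- (eta + 1)^2 / 4
  P <- cA * integrate_axisym(w * area_den, g)
  s <- fr * er + fz * ez
  O <- integrate_axisym(s^2, g)

  # bending
  psiB <- lap_phi - (phi^2 - 1) * (phi + sqrt(2) * p$eps * p$m) / eps2
  E_B <- cB * integrate_axisym(psiB^2, g)
  dB <- 2 * cB * (laplacian_cyl(psiB, g) -
                    (3 * phi^2 - 1 + 2 * sqrt(2) * p$eps * p$m * phi) *
                      psiB / eps2)

  # gaussian (energy via Psi_G, derivative via the axisymmetric form)
  qr <- deriv_r(q, g); qz <- deriv_z(q, g)
  lap_q <- deriv_rr(q, g) + qr / g$r_centers + deriv_zz(q, g)
  lapp_r <- deriv_r(lap_phi, g); lapp_z <- deriv_z(lap_phi, g)
  psiG <- (qr^2 + qz^2) / 2 - (qr * fr + qz * fz) * lap_phi +
    q * (lap_phi^2 + fr * lapp_r + fz * lapp_z - lap_q / 2)
  one_e <- 1 - eta
  kd <- list(
    kg   = p$kG0 * one_e^2 / 4,
    kgr  = -p$kG0 * one_e * er / 2,
    kgz  = -p$kG0 * one_e * ez / 2,
    kgrr = p$kG0 * (er^2 - one_e * err) / 2,
    kgzz = p$kG0 * (ez^2 - one_e * ezz) / 2,
    kgrz = p$kG0 * (er * ez - one_e * erz) / 2)
  cG <- (35 / (16 * sqrt(2))) * p$eps^3
  E_G <- cG * integrate_axisym(kd$kg * psiG, g)
  bracket <-
    12 * kd$kg * fr * (frz^2 - frr * fzz) +
    fr * fz^2 * kd$kgrr +
    6 * fr * (fr * frz - fz * frr) * kd$kgz +
    fr^3 * kd$kgzz +
    -2 * fr^2 * fz * kd$kgrz +
    (4 * fr * fz * frz + frr * fz^2 - 5 * fr^2 * fzz) * kd$kgr
  dG <- 2 * cG * bracket / g$r_centers

  dA <- A - cs$A0; dV <- V - cs$V0
  dP <- if (is.na(cs$P0)) 0 else P - cs$P0
  wA <- cs$gamma + cs$M1 * dA
  wV <- cs$delta_p + cs$M2 * dV
  wP <- cs$gamma_p + cs$M3 * dP

  dA_dphi <- -2 * cA * (lap_phi + phi * (1 - phi^2) / eps2)
  gphi <- dB + dG + wA * dA_dphi + wV * 0.5
  if (wP != 0) {
    wr <- (eta + 1) / 2 * er
    wz <- (eta + 1) / 2 * ez
    dP_dphi <- -2 * cA * (w * lap_phi + wr * fr + wz * fz +
                            w * phi * (1 - phi^2) / eps2)
    gphi <- gphi + wP * dP_dphi
  }
  if (cs$M4 != 0) {
    a <- s * er; b <- s * ez
    dO_dphi <- -2 * (deriv_r(a, g) + a / g$r_centers + deriv_z(b, g))
    gphi <- gphi + 2 * cs$M4 * O * dO_dphi
  }

  # auxiliary-field energy (always reported); Laplacian from the already
  # computed eta derivatives
  lap_eta <- err + er / g$r_centers + ezz
  psiA <- lap_eta - (eta^2 - 1) * eta / eps2
  cE <- 1e-3 * cB
  E_A <- cE * integrate_axisym(psiA^2, g)

  geta <- NULL
  if (want_eta) {
    dG_deta <- cG * (-p$kG0 * (1 - eta) / 2) * psiG
    dA_deta <- 2 * cE * (laplacian_cyl(psiA, g) -
                           (3 * eta^2 - 1) * psiA / eps2)
    geta <- dG_deta + dA_deta
    if (wP != 0) {
      geta <- geta + wP * cA * (eta + 1) / 2 * area_den
    }
    if (cs$M4 != 0) {
      a2 <- s * fr; b2 <- s * fz
      dO_deta <- -2 * (deriv_r(a2, g) + a2 / g$r_centers +
                         deriv_z(b2, g))
      geta <- geta + 2 * cs$M4 * O * dO_deta
    }
  }

  E <- E_B + E_G
  E_bar <- E + cs$gamma * dA + 0.5 * cs$M1 * dA^2 +
    cs$delta_p * dV + 0.5 * cs$M2 * dV^2 +
    cs$gamma_p * dP + 0.5 * cs$M3 * dP^2 +
    E_A + cs$M4 * O^2

  list(gphi = gphi, geta = geta,
       A = A, V = V, P = P, O = O,
       E_B = E_B, E_G = E_G, E_A = E_A, E = E, E_bar = E_bar)
}

#' Functional derivative of the modified energy with respect to phi
#'
#' Assembles all contributions: elastic terms, augmented constraint terms
#' `(gamma + M1 (A - A0)) dA/dphi` (and likewise for V, P), and the
#' orthogonality penalty `2 M4 O dO/dphi`.
#'
#' @inheritParams total_modified_energy
#' @return matrix of the same shape as `phi`.
#' @export
d_total_dphi <- function(phi, eta, p, cs, g) {
  .check_field(phi, g); .check_field(eta, g)
  .grad_all(phi, eta, p, cs, g, want_eta = FALSE)$gphi
}

#' Functional derivative of the modified energy with respect to eta
#'
#' @inheritParams total_modified_energy
#' @return matrix of the same shape as `eta`.
#' @export
d_total_deta <- function(phi, eta, p, cs, g) {
  .check_field(phi, g); .check_field(eta, g)
  .grad_all(phi, eta, p, cs, g, want_eta = TRUE)$geta
}

#' Membrane force-density diagnostic
#'
#' The force field `f = -(dE/dphi) grad(phi)` needed to counterbalance the
#' elastic reaction of the membrane in a given configuration, computed
#' from the elastic energy `E = E_B + E_G` only (no constraint terms). It
#' vanishes on plateaus (grad phi = 0) and on equilibrium profiles, and
#' concentrates in the merging region along a fusion pathway.
#'
#' @inheritParams energy_gaussian
#' @return list with matrices `force_r` and `force_z`.
#' @export
force_density <- function(phi, eta, p, g) {
  dE <- d_bending_dphi(phi, p, g) + d_gaussian_dphi(phi, eta, p, g)
  list(force_r = -dE * deriv_r(phi, g),
       force_z = -dE * deriv_z(phi, g))
}
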