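#' Physical and model parameters
#'
#' Collects the constants of the elastic model: bending rigidity `k`,
#' baseline Gaussian modulus `kG0`, spontaneous curvature `m`, interface
#' width parameter `eps` and mobility `M` of the gradient-flow dynamics.
#' The membrane (bilayer) thickness is tied to the interface parameter as
#' `ell_me = 6 * eps`; with the conventional bilayer thickness of 5 nm this
#' gives `eps = 5/6` nm, the default. All lengths share the unit of `eps`
#' (nm by default); energies and moduli are in units of kBT.
#'
#' @param k bending rigidity (kBT). Default 20.
#' @param kG0 baseline Gaussian modulus (kBT). Default -20 (= -k).
#' @param m spontaneous curvature (1/length). Default 0.
#' @param eps interface width parameter (length). Default 5/6 (nm).
#' @param mobility mobility M of the relaxation dynamics (sets the
#'   nondimensional time scale; absorbed into the time step by default).
#' @return object of class `phys_params`.
#' @examples
#' p <- phys_params()
#' p$ell_me  # bilayer thickness, 6 * eps = 5 nm
#' @export
phys_params <- function(k = 20, kG0 = -k, m = 0, eps = 5 / 6,
                        mobility = 1) {
  if (!is.finite(eps) || eps <= 0) stop("eps must be positive")
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (!is.finite(mobility) || mobility <= 0) stop("mobility must be positive")
  structure(
    list(k = k, kG0 = kG0, m = m, eps = eps, ell_me = 6 * eps,
         mobility = mobility),
    class = "phys_params")
}

#' @export
print.phys_params <- function(x, ...) {
  cat("membrane elastic parameters\n")
  cat(sprintf("  k   = %g kBT   kG0 = %g kBT   m = %g\n", x$k, x$kG0, x$m))
  cat(sprintf("  eps = %g   ell_me = %g   mobility = %g\n",
              x$eps, x$ell_me, x$mobility))
  invisible(x)
}

#' Constraint targets, multipliers and penalties
#'
#' Augmented-Lagrangian bookkeeping for the three conserved quantities of a
#' fusion pathway: total membrane area `A0`, enclosed volume `V0` and area
#' `P0` of the patch carrying the modified Gaussian modulus. `gamma`,
#' `delta_p` and `gamma_p` are the running multiplier estimates (surface
#' tension, pressure jump and patch tension); `M1..M3` the corresponding
#' quadratic penalty constants and `M4` the penalty enforcing orthogonality
#' between the membrane field and the auxiliary field.
#'
#' @param A0,V0,P0 constraint targets (area, volume, patch area).
#' @param gamma,delta_p,gamma_p initial multiplier estimates.
#' @param M1,M2,M3,M4 nonnegative penalty constants.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(A0 = NA_real_, V0 = NA_real_, P0 = NA_real_,
                           gamma = 0, delta_p = 0, gamma_p = 0,
                           M1 = 0, M2 = 0, M3 = 0, M4 = 0) {
  if (any(c(M1, M2, M3, M4) < 0)) stop("penalty constants must be >= 0")
  structure(
    list(A0 = A0, V0 = V0, P0 = P0,
         gamma = gamma, delta_p = delta_p, gamma_p = gamma_p,
         M1 = M1, M2 = M2, M3 = M3, M4 = M4),
    class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("constraint set (augmented Lagrangian)\n")
  cat(sprintf("  targets: A0 = %g  V0 = %g  P0 = %g\n", x$A0, x$V0, x$P0))
  cat(sprintf("  multipliers: gamma = %g  delta_p = %g  gamma_p = %g\n",
              x$gamma, x$delta_p, x$gamma_p))
  cat(sprintf("  penalties: M1 = %g  M2 = %g  M3 = %g  M4 = %g\n",
              x$M1, x$M2, x$M3, x$M4))
  invisible(x)
}
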