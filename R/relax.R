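#' Settings for the semi-implicit constrained relaxation
#'
#' @param dt initial time step of the semi-implicit Euler scheme
#'   (nondimensional; mobility is absorbed into it). The stiff
#'   constant-coefficient biharmonic part of the flow is treated
#'   implicitly, so `dt` is not limited by the `h^4` explicit constraint;
#'   an automatic halving guard still shrinks it if the explicit nonlinear
#'   terms destabilize the step.
#' @param n_steps iteration budget.
#' @param tol stationarity tolerance on the max field update per unit
#'   time.
#' @param multiplier_update_every steps between augmented-Lagrangian
#'   multiplier updates (default 1: every step).
#' @param dt_min smallest time step before the guard aborts.
#' @param dt_grow factor by which dt recovers after a run of accepted
#'   steps (capped at the initial dt).
#' @param evolve_eta evolve the auxiliary field (set `FALSE` for
#'   uniform-modulus runs, where eta is a fixed parameter field).
#' @param eta_hold_cycles string-method initialization protocol: number
#'   of outer cycles during which eta is held fixed while phi sheds the
#'   curvature spikes of the interpolated initial path. The modulus map
#'   kG(eta) is unbounded below for eta > 1, so eta must not be exposed
#'   to transient curvature densities far above their relaxed values.
#' @param surgery_eb string-method robustness threshold: an interior
#'   image whose bending energy exceeds this value (in kBT) is judged to
#'   have fallen into the short-wavelength sink of the Gaussian
#'   functional and is rebuilt by signed-distance interpolation of its
#'   nearest healthy neighbours. `Inf` disables surgery.
#' @return object of class `relax_settings`.
#' @export
relax_settings <- function(dt = 2e-3, n_steps = 200L, tol = 1e-6,
                           multiplier_update_every = 1L,
                           dt_min = 1e-9, dt_grow = 1.1,
                           evolve_eta = TRUE, eta_hold_cycles = 0L,
                           surgery_eb = Inf) {
  if (dt <= 0 || tol <= 0) stop("dt and tol must be positive")
  structure(
    list(dt = dt, n_steps = as.integer(n_steps), tol = tol,
         multiplier_update_every = as.integer(multiplier_update_every),
         dt_min = dt_min, dt_grow = dt_grow,
         evolve_eta = isTRUE(evolve_eta),
         eta_hold_cycles = as.integer(eta_hold_cycles),
         surgery_eb = surgery_eb),
    class = "relax_settings")
}

#' Augmented-Lagrangian multiplier update
#'
#' One update of the running multiplier estimates:
#' `gamma <- gamma + M1 (A - A0)`, `delta_p <- delta_p + M2 (V - V0)`,
#' `gamma_p <- gamma_p + M3 (P - P0)`. Penalties are unchanged; the update
#' is a fixed point exactly when all constraints are met.
#'
#' @param cs [constraint_set()].
#' @param A,V,P current values of the area, volume and patch-area
#'   functionals.
#' @return updated `constraint_set`.
#' @export
update_multipliers <- function(cs, A, V, P) {
  cs$gamma <- cs$gamma + cs$M1 * (A - cs$A0)
  cs$delta_p <- cs$delta_p + cs$M2 * (V - cs$V0)
  if (!is.na(cs$P0)) cs$gamma_p <- cs$gamma_p + cs$M3 * (P - cs$P0)
  cs
}

# One semi-implicit Euler step of the constrained gradient flow for a
# single image.  The constant-coefficient biharmonic parts of
# dE_B/dphi and dE_A/deta (prefactors b_phi = 2 c_B, b_eta = 2e-3 c_B)
# are treated implicitly via the diagonal transform-space solve; every
# other term explicitly.  With `evolve_eta = FALSE` the auxiliary field
# is held fixed (the uniform-modulus model has no eta dynamics).
.semi_implicit_step <- function(phi, eta, p, cs, g, dt,
                                evolve_eta = TRUE) {
  gr <- .grad_all(phi, eta, p, cs, g, want_eta = evolve_eta)
  cB <- p$k * (3 / (4 * sqrt(2))) * p$eps
  b_phi <- 2 * cB
  Mdt <- p$mobility * dt
  # the scheme (I + Mdt b L) phi' = phi - Mdt (g - b L phi) reduces to
  # phi' = phi - Mdt (I + Mdt b L)^{-1} g: one smoothing transform of
  # the gradient per field
  phi_new <- phi - Mdt * helmholtz_solve(gr$gphi, Mdt * b_phi, g)
  if (evolve_eta) {
    b_eta <- 2e-3 * cB
    eta_new <- eta - Mdt * helmholtz_solve(gr$geta, Mdt * b_eta, g)
  } else {
    eta_new <- eta
  }
  list(phi = phi_new, eta = eta_new, gr = gr)
}

#' Constrained gradient-flow relaxation of a single image
#'
#' Evolves one (phi, eta) pair down the gradient of the modified energy
#' with the semi-implicit Euler scheme, updating the augmented-Lagrangian
#' multipliers along the way. An energy guard halves the time step
#' whenever a step raises the modified energy (and reverts the step);
#' repeated failure down to `dt_min` aborts with a diagnostic.
#'
#' @param phi,eta fields on grid `g`.
#' @param p [phys_params()].
#' @param cs [constraint_set()] with targets set.
#' @param s [relax_settings()].
#' @param g grid.
#' @param trace_every if positive, record a trace row every this many
#'   steps.
#' @return list with `phi`, `eta`, `constraints` (updated multipliers),
#'   `report` (final [total_modified_energy()] report), `converged`,
#'   `steps`, `dt` (final step size) and `trace` (data frame of step,
#'   E_bar and constraint residuals).
#' @export
relax_image <- function(phi, eta, p, cs, s, g, trace_every = 0L) {
  .check_field(phi, g); .check_field(eta, g)
  dt <- s$dt
  E_prev <- .grad_all(phi, eta, p, cs, g, want_eta = FALSE)$E_bar
  if (!is.finite(E_prev)) stop("non-finite energy in initial state")
  trace <- list()
  converged <- FALSE
  step <- 0L
  streak <- 0L
  while (step < s$n_steps) {
    step <- step + 1L
    st <- .semi_implicit_step(phi, eta, p, cs, g, dt,
                              evolve_eta = s$evolve_eta)
    if (!all(is.finite(st$phi)) || !all(is.finite(st$eta))) {
      stop("relaxation diverged (non-finite fields) at step ", step)
    }
    gr <- st$gr
    # energy after the step, under the *current* multipliers
    E_new <- .grad_all(st$phi, st$eta, p, cs, g, want_eta = FALSE)$E_bar
    if (!is.finite(E_new) || E_new > E_prev + 1e-8 * (1 + abs(E_prev))) {
      dt <- dt / 2
      streak <- 0L
      if (dt < s$dt_min) {
        stop("relaxation diverged: dt fell below dt_min at step ", step,
             " (E_bar ", format(E_new), " after ", format(E_prev), ")")
      }
      step <- step - 1L
      next
    }
    disp <- max(max(abs(st$phi - phi)), max(abs(st$eta - eta)))
    phi <- st$phi; eta <- st$eta
    E_prev <- E_new
    streak <- streak + 1L
    if (streak >= 10L && dt < s$dt) {
      dt <- min(dt * s$dt_grow, s$dt)
      streak <- 0L
    }
    if (step %% s$multiplier_update_every == 0L) {
      gr2 <- .grad_all(phi, eta, p, cs, g, want_eta = FALSE)
      cs <- update_multipliers(cs, gr2$A, gr2$V, gr2$P)
      # multipliers changed: refresh the reference energy
      E_prev <- .grad_all(phi, eta, p, cs, g, want_eta = FALSE)$E_bar
    }
    if (trace_every > 0L && step %% trace_every == 0L) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, dt = dt, E_bar = E_prev,
        resA = abs(gr$A - cs$A0) / cs$A0,
        resV = abs(gr$V - cs$V0) / cs$V0,
        resP = if (is.na(cs$P0)) NA_real_ else
          abs(gr$P - cs$P0) / max(cs$P0, 1e-12))
    }
    if (disp / dt < s$tol) { converged <- TRUE; break }
  }
  report <- total_modified_energy(phi, eta, p, cs, g)
  list(phi = phi, eta = eta, constraints = cs, report = report,
       converged = converged, steps = step, dt = dt,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}
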