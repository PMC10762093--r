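#' Distance between two string images
#'
#' Metric induced by the combined norm of the (phi, eta) pair,
#' `||(phi, eta)|| = sqrt(||phi||_2^2 + ||eta||_2^2)`, with the L2 norms
#' taken over the axisymmetric volume measure.
#'
#' @param a,b lists `list(phi = , eta = )` on grid `g`.
#' @param g grid.
#' @return nonnegative scalar.
#' @export
string_distance <- function(a, b, g) {
  .check_field(a$phi, g); .check_field(b$phi, g)
  dphi <- a$phi - b$phi
  deta <- a$eta - b$eta
  sqrt(integrate_axisym(dphi^2 + deta^2, g))
}

# Consecutive-image distances of a string
.string_dists <- function(s, g) {
  vapply(seq_len(s$n_images - 1L), function(i) {
    string_distance(s$images[[i]], s$images[[i + 1L]], g)
  }, numeric(1))
}

# Natural-cubic-spline interpolation weights: row j of the returned
# matrix gives the weights applied to the knot values at `x` to evaluate
# the interpolant at `xout[j]`.  Interpolation is linear in the data, so
# the weights are obtained by interpolating the canonical basis vectors.
.spline_weights <- function(x, xout) {
  n <- length(x)
  W <- matrix(0, length(xout), n)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- 1
    W[, k] <- if (n > 2) {
      stats::spline(x, e, xout = xout, method = "natural")$y
    } else {
      stats::approx(x, e, xout = xout, rule = 2)$y
    }
  }
  W
}

#' Equal-arc-length reparametrization of a string
#'
#' Recomputes the cumulative arc length of the string in the combined
#' (phi, eta) metric and re-interpolates every image (piecewise-cubic in
#' arc length, pointwise per grid cell) so that consecutive images are
#' equidistant. Endpoints are left untouched. The interpolation is
#' iterated until the relative spread of consecutive distances drops
#' below `spread_tol` (chord length along the interpolated path is a
#' nonlinear function of the parameter, so one pass is not exact).
#'
#' @param s [init_string()] string state.
#' @param g grid.
#' @param spread_tol target relative spread `(max - min)/mean` of
#'   consecutive distances.
#' @param max_iter iteration cap.
#' @return reparametrized `string_state` with updated `alpha`.
#' @export
reparametrize <- function(s, g, spread_tol = 1e-3, max_iter = 30L) {
  N <- s$n_images
  if (N < 3L) stop("need at least 3 images")
  for (iter in seq_len(max_iter)) {
    d <- .string_dists(s, g)
    total <- sum(d)
    if (!is.finite(total)) stop("non-finite image distances in string")
    if (total == 0) return(s)
    spread <- (max(d) - min(d)) / mean(d)
    if (spread < spread_tol) break
    cum <- c(0, cumsum(d)) / total
    # collapse duplicate knots (zero-length segments)
    keep <- c(TRUE, diff(cum) > 1e-14)
    x <- cum[keep]
    idx <- which(keep)
    targets <- seq(0, 1, length.out = N)
    W <- .spline_weights(x, targets)
    npix <- length(s$images[[1L]]$phi)
    PM <- matrix(0, npix, length(idx))
    EM <- matrix(0, npix, length(idx))
    for (j in seq_along(idx)) {
      PM[, j] <- as.vector(s$images[[idx[j]]]$phi)
      EM[, j] <- as.vector(s$images[[idx[j]]]$eta)
    }
    # cubic interpolation can overshoot between widely separated images;
    # bound it to the range spanned by the data, capped strictly inside
    # the divergence threshold of the evolver so a clamped image can
    # always take a (small) stable step
    clo <- max(-1.8, min(PM)); chi <- min(1.8, max(PM))
    newP <- pmin(pmax(PM %*% t(W), clo), chi)
    clo <- max(-1.8, min(EM)); chi <- min(1.8, max(EM))
    newE <- pmin(pmax(EM %*% t(W), clo), chi)
    dims <- dim(s$images[[1L]]$phi)
    old1 <- s$images[[1L]]; oldN <- s$images[[N]]
    for (i in seq_len(N)) {
      s$images[[i]] <- list(
        phi = matrix(newP[, i], dims[1], dims[2]),
        eta = matrix(newE[, i], dims[1], dims[2]))
    }
    s$images[[1L]] <- old1
    s$images[[N]] <- oldN
  }
  d <- .string_dists(s, g)
  s$alpha <- c(0, cumsum(d)) / sum(d)
  s
}

#' Evolve a string with the zero-temperature string method
#'
#' Simplified string method: each outer cycle relaxes every image a few
#' semi-implicit gradient-flow steps under the modified energy (with
#' per-image augmented-Lagrangian multipliers sharing common targets and
#' penalties), then reparametrizes the string to equal arc length.
#' Endpoints evolve freely and settle into their own minima. Convergence
#' is monitored as the maximum image displacement per outer cycle in the
#' combined metric, divided by the accumulated time step.
#'
#' @param s string state.
#' @param p [phys_params()].
#' @param cs [constraint_set()] template (targets + penalties); each
#'   image carries its own multiplier estimates initialized from it.
#' @param settings [relax_settings()]; `n_steps` is the number of inner
#'   steps per image per outer cycle.
#' @param n_outer number of outer cycles.
#' @param g grid.
#' @param verbose print a progress line per cycle.
#' @return evolved `string_state`, with attributes `constraints`
#'   (per-image multiplier sets), `convergence` (per-cycle metric) and
#'   `converged`.
#' @export
evolve_string <- function(s, p, cs, settings, n_outer, g,
                          verbose = FALSE) {
  N <- s$n_images
  cs_list <- attr(s, "constraints")
  if (is.null(cs_list)) cs_list <- rep(list(cs), N)
  dt_i <- rep(settings$dt, N)    # per-image adaptive step
  streak_i <- rep(0L, N)
  eb_i <- rep(NA_real_, N)
  ebar_i <- rep(NA_real_, N)     # per-image energy under own multipliers
  n_surgery <- 0L
  conv <- numeric(0)
  bad <- function(f) !all(is.finite(f)) || max(abs(f)) > 2
  # modified energy of a gradient report under given multipliers (the
  # descent guard must compare energies at *fixed* multipliers: dual
  # ascent legitimately raises E_bar while residuals persist)
  ebar_with <- function(gr, ci) {
    dA <- gr$A - ci$A0; dV <- gr$V - ci$V0
    dP <- if (is.na(ci$P0)) 0 else gr$P - ci$P0
    gr$E + ci$gamma * dA + 0.5 * ci$M1 * dA^2 +
      ci$delta_p * dV + 0.5 * ci$M2 * dV^2 +
      ci$gamma_p * dP + 0.5 * ci$M3 * dP^2 +
      gr$E_A + ci$M4 * gr$O^2
  }
  for (cycle in seq_len(n_outer)) {
    old_images <- s$images
    E_tot <- 0
    for (i in seq_len(N)) {
      tries <- 0L
      repeat {
        phi <- s$images[[i]]$phi; eta <- s$images[[i]]$eta
        ci <- cs_list[[i]]
        ok <- TRUE
        ev_eta <- settings$evolve_eta &&
          cycle > settings$eta_hold_cycles
        for (k in seq_len(settings$n_steps)) {
          st <- .semi_implicit_step(phi, eta, p, ci, g, dt_i[i],
                                    evolve_eta = ev_eta)
          phi <- st$phi; eta <- st$eta
          if (bad(phi) || bad(eta)) { ok <- FALSE; break }
          if (k %% settings$multiplier_update_every == 0L) {
            gr <- .grad_all(phi, eta, p, ci, g, want_eta = FALSE)
            ci <- update_multipliers(ci, gr$A, gr$V, gr$P)
          }
        }
        if (ok) {
          gr <- .grad_all(phi, eta, p, ci, g, want_eta = FALSE)
          # strict energy guard (at fixed cycle-start multipliers) for
          # the endpoints only: they are never touched by
          # reparametrization, so any rise signals a marginally
          # unstable step or augmented-Lagrangian ringing. Interior
          # images are legitimately carried uphill by the
          # reparametrization.
          rise_ok <- TRUE
          if (i == 1L || i == N) {
            e_now <- ebar_with(gr, cs_list[[i]])
            rise_ok <- is.na(ebar_i[i]) || tries >= 6L ||
              e_now <= ebar_i[i] + 0.02 * (1 + abs(ebar_i[i]))
          }
          if (rise_ok) break
        }
        tries <- tries + 1L
        dt_i[i] <- dt_i[i] / 2
        streak_i[i] <- 0L
        if (dt_i[i] < settings$dt_min) {
          stop("string evolution diverged at image ", i,
               " (cycle ", cycle, "): dt below dt_min")
        }
      }
      E_tot <- E_tot + gr$E_bar
      eb_i[i] <- gr$E_B
      ebar_i[i] <- gr$E_bar
      s$images[[i]] <- list(phi = phi, eta = eta)
      cs_list[[i]] <- ci
      streak_i[i] <- streak_i[i] + 1L
      if (streak_i[i] >= 10L && dt_i[i] < settings$dt) {
        dt_i[i] <- min(2 * dt_i[i], settings$dt)
        streak_i[i] <- 0L
      }
    }
    # image surgery: rebuild interior images that fell into the
    # short-wavelength Gaussian sink (diagnosed by a blown-up bending
    # energy) from their nearest healthy neighbours
    sick <- which(eb_i > settings$surgery_eb)
    sick <- sick[sick > 1L & sick < N]
    if (length(sick)) {
      healthy <- setdiff(seq_len(N), sick)
      for (i in sick) {
        j1 <- max(healthy[healthy < i])
        j2 <- min(healthy[healthy > i])
        # rebuilding across a wide gap of sick images recreates the
        # pathology; only local repairs are useful
        if (j2 - j1 > 3L) next
        w <- (i - j1) / (j2 - j1)
        s$images[[i]] <- list(
          phi = .interp_fields(s$images[[j1]]$phi, s$images[[j2]]$phi,
                               w, p, g),
          eta = .interp_fields(s$images[[j1]]$eta, s$images[[j2]]$eta,
                               w, p, g))
        dt_i[i] <- settings$dt
        streak_i[i] <- 0L
        ebar_i[i] <- NA_real_
        cs_list[[i]] <- cs
        n_surgery <- n_surgery + 1L
      }
    }
    # light equalization only: aggressive per-cycle reparametrization
    # injects interpolation error faster than a few gradient-flow steps
    # can dissipate it
    s <- reparametrize(s, g, spread_tol = 0.05, max_iter = 2L)
    metric <- max(vapply(seq_len(N), function(i) {
      string_distance(old_images[[i]], s$images[[i]], g)
    }, numeric(1))) / (settings$dt * settings$n_steps)
    conv <- c(conv, metric)
    if (verbose) {
      message(sprintf(
        "cycle %4d  E_tot %.6g  dt [%.3g, %.3g]  conv %.3g",
        cycle, E_tot, min(dt_i), max(dt_i), metric))
    }
    if (metric < settings$tol) break
  }
  attr(s, "constraints") <- cs_list
  attr(s, "convergence") <- conv
  attr(s, "n_surgery") <- n_surgery
  attr(s, "converged") <- length(conv) > 0 &&
    conv[length(conv)] < settings$tol
  s
}

# Interior extrema of a discrete profile with a plateau (prominence)
# tolerance: ripples smaller than tol are not classified.
.find_extrema <- function(y, tol = 0.01) {
  N <- length(y)
  minima <- integer(0); maxima <- integer(0)
  dir <- 0L
  ext_i <- 1L; ext_v <- y[1]
  for (i in 2:N) {
    if (dir >= 0L) {
      if (y[i] >= ext_v) {
        ext_i <- i; ext_v <- y[i]
        if (y[i] > min(y[1:i]) + tol) dir <- 1L
      } else if (y[i] < ext_v - tol) {
        if (dir > 0L && ext_i > 1L && ext_i < N) {
          maxima <- c(maxima, ext_i)
        }
        dir <- -1L; ext_i <- i; ext_v <- y[i]
      }
    } else {
      if (y[i] <= ext_v) {
        ext_i <- i; ext_v <- y[i]
      } else if (y[i] > ext_v + tol) {
        if (ext_i > 1L && ext_i < N) minima <- c(minima, ext_i)
        dir <- 1L; ext_i <- i; ext_v <- y[i]
      }
    }
  }
  list(minima = minima, saddles = maxima)
}

#' Energy profile and critical points along a string
#'
#' Computes the per-image elastic energy `E = E_B + E_G`, the profile
#' `dE(alpha) = E - E[image 1]`, classifies interior minima and saddles
#' (discrete extrema with a plateau tolerance that ignores numerical
#' ripples, e.g. along neutral-equilibrium stretches), and reads off the
#' energy barriers as saddle minus preceding minimum (the preceding
#' minimum being the nearest classified minimum before the saddle, or the
#' initial state).
#'
#' @param s string state (ideally converged).
#' @param p,g model parameters and grid.
#' @param cs constraint template used for the per-image reports.
#' @param tol plateau tolerance (kBT) for extremum classification.
#' @return object of class `mep_result`: list with `alpha`, `dE`,
#'   `minima`, `saddles` (data frames of index and alpha), `barriers`,
#'   `reports` (per-image energy data frame).
#' @export
mep_profile <- function(s, p, cs, g, tol = 0.01) {
  N <- s$n_images
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    im <- s$images[[i]]
    rep_i <- total_modified_energy(im$phi, im$eta, p, cs, g)
    rows[[i]] <- data.frame(
      index = i, alpha = s$alpha[i],
      E_B = rep_i$E_B, E_G = rep_i$E_G, E_A = rep_i$E_A,
      A = rep_i$A, V = rep_i$V, P = rep_i$P,
      E = rep_i$E, E_bar = rep_i$E_bar)
  }
  reports <- do.call(rbind, rows)
  dE <- reports$E - reports$E[1]
  dE_bar <- reports$E_bar - reports$E_bar[1]
  ext <- .find_extrema(dE, tol)
  barriers <- numeric(0)
  if (length(ext$saddles)) {
    for (sdl in ext$saddles) {
      prev_min <- ext$minima[ext$minima < sdl]
      base <- if (length(prev_min)) dE[max(prev_min)] else dE[1]
      barriers <- c(barriers, dE[sdl] - base)
    }
  } else {
    barriers <- dE[N]
  }
  structure(
    list(alpha = s$alpha, dE = dE, dE_bar = dE_bar,
         minima = data.frame(index = ext$minima,
                             alpha = s$alpha[ext$minima]),
         saddles = data.frame(index = ext$saddles,
                              alpha = s$alpha[ext$saddles]),
         barriers = barriers, reports = reports),
    class = "mep_result")
}

#' @export
print.mep_result <- function(x, ...) {
  cat(sprintf("minimal energy pathway, %d images\n", length(x$alpha)))
  if (nrow(x$minima)) {
    cat("  interior minima at alpha:",
        paste(sprintf("%.3f", x$minima$alpha), collapse = ", "), "\n")
  } else cat("  no interior minima\n")
  if (nrow(x$saddles)) {
    cat("  saddles at alpha:",
        paste(sprintf("%.3f", x$saddles$alpha), collapse = ", "), "\n")
  }
  cat("  barriers (kBT):",
      paste(sprintf("%.3g", x$barriers), collapse = ", "), "\n")
  invisible(x)
}
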