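# Quasi-static equilibration: energy minimization under vitelline
# confinement, and the adiabatic basal-stiffness schedule.
#
# The confinement |x| <= R_vit is enforced exactly by parameterizing each
# vertex in polar coordinates (r, theta) about the embryo centre, so the
# shell becomes the box constraint r <= R_vit and the projection onto the
# feasible disc is a radial clamp. The energy landscape is stiff (strong
# area penalties) and passes through genuinely unstable configurations as
# the tissue buckles, so the solver is second order: a quick L-BFGS-B
# descent phase followed by a modified-Newton loop that replaces Hessian
# eigenvalues by their absolute values (which descends along negative-
# curvature directions), with an active-set treatment of shell contacts and
# a final spectral stability check that kicks the state off saddle points.

polar_from_conf <- function(conf) {
  P <- rbind(conf$apical, conf$basal)
  c(sqrt(P[, 1]^2 + P[, 2]^2), atan2(P[, 2], P[, 1]))
}

conf_from_polar <- function(z, n) {
  m <- 2L * n
  r <- z[seq_len(m)]; th <- z[m + seq_len(m)]
  x <- r * cos(th); y <- r * sin(th)
  structure(list(apical = cbind(x[seq_len(n)], y[seq_len(n)]),
                 basal = cbind(x[n + seq_len(n)], y[n + seq_len(n)])),
            class = "vf_configuration")
}

# Infinity norm of the Cartesian-equivalent projected gradient in polar
# coordinates: radial components with the outward push at shell contacts
# zeroed, tangential components divided by the radius.
polar_pg_norm <- function(z, g, R, m, slack = 1e-9) {
  r <- z[seq_len(m)]
  gr <- g[seq_len(m)]
  gr <- ifelse((r >= R - slack & gr < 0) | (r <= -R + slack & gr > 0), 0, gr)
  max(abs(gr), abs(g[m + seq_len(m)]) / pmax(abs(r), 1))
}

# Average a configuration with its mirror image about the ventral midline
# (x = 0 axis); exact mirror symmetry afterwards.
symmetrize_configuration <- function(conf) {
  refl <- function(P) {
    idx <- mirror_vertex_index(nrow(P))
    Q <- P[idx, , drop = FALSE]
    Q[, 1] <- -Q[, 1]
    Q
  }
  conf$apical <- 0.5 * (conf$apical + refl(conf$apical))
  conf$basal <- 0.5 * (conf$basal + refl(conf$basal))
  conf
}

default_tolerance <- function(geom) 1e-6 * 5000 * mean(geom$rest_apical)

# Problem descriptions for the solver core: plain polar coordinates (full
# space) or the mirror-symmetric subspace. Each provides energy/gradient/
# Hessian callables, box bounds (radii bounded by the shell), the index set
# of radial coordinates and, for each angular coordinate, the index of the
# radius it belongs to (for Cartesian-equivalent gradient norms).
make_problem_full <- function(sys) {
  m <- 2L * sys$n
  list(
    E = function(z) .polar_energy_cpp(z, sys),
    g = function(z) .polar_grad_cpp(z, sys),
    H = function(z) .polar_hess_cpp(z, sys),
    lower = c(rep(-sys$R, m), rep(-Inf, m)),
    upper = c(rep(sys$R, m), rep(Inf, m)),
    r_idx = seq_len(m),
    th_r = seq_len(m),
    R = sys$R
  )
}

make_problem_sym <- function(sys) {
  h <- sys$n %/% 2L
  nr <- h + 1L
  nth <- h - 1L
  list(
    E = function(z) .sym_energy_cpp(z, sys),
    g = function(z) .sym_grad_cpp(z, sys),
    H = function(z) .sym_hess_cpp(z, sys),
    lower = c(rep(-sys$R, 2L * nr), rep(-Inf, 2L * nth)),
    upper = c(rep(sys$R, 2L * nr), rep(Inf, 2L * nth)),
    r_idx = seq_len(2L * nr),
    th_r = c(1L + seq_len(nth), nr + 1L + seq_len(nth)),
    R = sys$R
  )
}

# Cartesian-equivalent infinity norm of the projected gradient: radial
# components with the blocked push at an active bound zeroed, angular
# components divided by their radius.
problem_pg_norm <- function(z, g, prob) {
  ri <- prob$r_idx
  gr <- g[ri]
  at_hi <- z[ri] >= prob$upper[ri] - 1e-9
  at_lo <- z[ri] <= prob$lower[ri] + 1e-9
  gr <- ifelse((at_hi & gr < 0) | (at_lo & gr > 0), 0, gr)
  gth <- g[-ri]
  max(abs(gr), abs(gth) / pmax(abs(z[prob$th_r]), 1))
}

clamp_z <- function(z, prob) {
  ri <- prob$r_idx
  z[ri] <- pmin(pmax(z[ri], prob$lower[ri]), prob$upper[ri])
  z
}

# One modified-Newton descent leg from z to a stationary point (projected
# gradient below tol) or until the iteration budget runs out. Where the
# free-coordinate Hessian is positive definite a Cholesky-factored Newton
# step is taken; where it is indefinite the eigenvalues are replaced by
# their absolute values, which turns negative-curvature directions into
# descent directions. A trust radius caps the step and adapts to line-
# search outcomes. At a stationary point the lowest free eigenvalue and its
# mode are recorded for the stability verdict (saddle detection).
newton_leg <- function(z, prob, tol, max_newton) {
  N <- length(z)
  trace <- numeric(0)
  eig_min <- NA_real_
  eig_vec <- NULL
  pg <- Inf
  it <- 0L
  cap <- 1
  while (it < max_newton) {
    it <- it + 1L
    g <- prob$g(z)
    E0 <- prob$E(z)
    if (!is.finite(E0)) stop("energy is not finite")
    pg <- problem_pg_norm(z, g, prob)
    ri <- prob$r_idx
    active_r <- (z[ri] >= prob$upper[ri] - 1e-9 & g[ri] < 0) |
      (z[ri] <= prob$lower[ri] + 1e-9 & g[ri] > 0)
    free <- rep(TRUE, N)
    free[ri] <- !active_r
    H <- prob$H(z)
    Hf <- H[free, free, drop = FALSE]
    gf <- g[free]
    if (pg <= tol) {
      eg <- eigen(Hf, symmetric = TRUE)
      eig_min <- eg$values[length(eg$values)]
      if (eig_min < -1e-8 * max(abs(eg$values))) {
        v <- numeric(N); v[free] <- eg$vectors[, length(eg$values)]
        eig_vec <- v
      } else eig_vec <- NULL
      break
    }
    dscale <- mean(abs(diag(Hf)))
    ch <- tryCatch(chol(Hf + (1e-9 * dscale) * diag(nrow(Hf))),
                   error = function(e) NULL)
    vneg <- NULL
    s <- if (!is.null(ch)) {
      -backsolve(ch, forwardsolve(t(ch), gf))
    } else {
      eg <- eigen(Hf, symmetric = TRUE)
      lam <- pmax(abs(eg$values), 1e-7 * max(abs(eg$values)))
      if (eg$values[length(eg$values)] < -1e-8 * max(abs(eg$values)))
        vneg <- eg$vectors[, length(eg$values)]
      -as.vector(eg$vectors %*% (crossprod(eg$vectors, gf) / lam))
    }
    smax <- max(abs(s))
    if (smax > cap) s <- s * (cap / smax)
    step <- numeric(N); step[free] <- s
    t1 <- 1
    accepted <- FALSE
    while (t1 >= 1e-12) {
      zt <- clamp_z(z + t1 * step, prob)
      Et <- prob$E(zt)
      if (is.finite(Et) && Et <= E0 + 1e-4 * sum(g * (zt - z))) {
        accepted <- TRUE
        break
      }
      t1 <- t1 / 2
    }
    if (!accepted) break  # no descent possible at floating-point resolution
    if (t1 == 1) {
      # expansion: inside a long valley the Newton step is conservative, so
      # extrapolate along the same direction while the energy keeps falling
      while (t1 < 64) {
        z2 <- clamp_z(z + 2 * t1 * step, prob)
        E2 <- prob$E(z2)
        if (!is.finite(E2) || E2 >= Et) break
        t1 <- 2 * t1
        zt <- z2
        Et <- E2
      }
    }
    cap <- if (t1 >= 1) min(cap * 2, 10) else max(cap * t1, 1e-3)
    z <- zt
    # where the Hessian is indefinite, also descend explicitly along the
    # most negative mode: the gradient can be nearly orthogonal to it, and
    # the curvature-scaled step along it is then vanishingly small
    if (!is.null(vneg)) {
      vstep <- numeric(N); vstep[free] <- vneg
      for (sgn in c(1, -1)) {
        tau <- 0.25
        while (tau <= 32) {
          z2 <- clamp_z(z + sgn * tau * vstep, prob)
          E2 <- prob$E(z2)
          if (!is.finite(E2) || E2 >= Et) break
          Et <- E2
          z <- z2
          tau <- 2 * tau
        }
      }
    }
    trace <- c(trace, Et)
  }
  list(z = z, trace = trace, pg = pg, eig_min = eig_min, eig_vec = eig_vec,
       n_iter = it)
}

# Solver core on an abstract problem (full space or symmetric subspace):
# alternate cheap first-order descent (L-BFGS-B chunks, which handle the
# long traversals) with modified-Newton legs (which traverse indefinite
# regions and certify stability), plus saddle kicks along unstable modes.
minimize_core <- function(z, prob, tol, max_iter) {
  legs <- list()
  total_iter <- 0L
  kicks <- 0L
  leg <- NULL
  repeat {
    # first-order rounds: keep restarting L-BFGS-B while it still buys
    # meaningful energy decrease (it rides long relaxation cascades at a
    # fraction of the Newton cost), then switch to Newton
    for (round in 1:10) {
      E_before <- prob$E(z)
      lb <- stats::optim(clamp_z(z, prob), prob$E, prob$g,
                         method = "L-BFGS-B",
                         lower = prob$lower, upper = prob$upper,
                         control = list(maxit = 1000L, factr = 1e4,
                                        pgtol = 0, lmm = 25))
      total_iter <- total_iter + lb$counts[["function"]]
      if (lb$value <= E_before) {
        z <- lb$par
        legs <- c(legs, list(lb$value))
      }
      if (E_before - lb$value <= 1e-5 * max(1, abs(E_before)) ||
          total_iter >= max_iter) break
    }

    # a Newton iteration costs roughly 25 gradient evaluations (finite-
    # difference Hessian), so it consumes the budget at that rate
    budget <- max(80L, min(250L, (max_iter - total_iter) %/% 25L))
    leg <- newton_leg(z, prob, tol, budget)
    z <- leg$z
    total_iter <- total_iter + 25L * leg$n_iter
    legs <- c(legs, list(leg$trace))
    if (leg$pg <= tol && is.null(leg$eig_vec)) break      # stable minimum
    if (leg$pg <= tol && !is.null(leg$eig_vec)) {
      if (kicks >= 8L || total_iter >= max_iter) break    # give up kicking
      kicks <- kicks + 1L
      best <- NULL
      for (sgn in c(1, -1)) {
        zk <- clamp_z(z + sgn * 0.5 * leg$eig_vec, prob)
        lk <- newton_leg(zk, prob, tol, 80L)
        total_iter <- total_iter + 25L * lk$n_iter
        if (is.null(best) || prob$E(lk$z) < prob$E(best$z)) best <- lk
      }
      if (prob$E(best$z) < prob$E(z) - 1e-12 * max(1, abs(prob$E(z)))) {
        z <- best$z
        legs <- c(legs, list(best$trace))
        next
      }
      break  # kicks do not improve: accept as (marginally) stable
    }
    if (total_iter >= max_iter) break
  }
  list(z = z, legs = legs, n_iter = total_iter,
       eig_min = if (is.null(leg)) NA_real_ else leg$eig_min)
}

# Half-state (mirror-symmetric subspace) from a symmetric configuration.
sym_state_from_conf <- function(conf, n) {
  h <- n %/% 2L
  idx <- seq_len(h + 1L)
  rA <- sqrt(rowSums(conf$apical[idx, , drop = FALSE]^2))
  rB <- sqrt(rowSums(conf$basal[idx, , drop = FALSE]^2))
  thA <- atan2(conf$apical[2:h, 2], conf$apical[2:h, 1])
  thB <- atan2(conf$basal[2:h, 2], conf$basal[2:h, 1])
  c(rA, rB, thA, thB)
}

#' Minimize the energy of a configuration under vitelline confinement
#'
#' Finds a locally stable equilibrium of the vertex-model energy with the
#' vitelline shell as a hard inequality: vertices may detach inward but can
#' never leave the disc of radius `vitelline_radius`. The solver is a
#' quasi-Newton descent phase followed by a curvature-corrected Newton
#' iteration; when the iterate lands on a saddle (a direction of negative
#' curvature remains, as happens at the buckling transition of the
#' compressed ring), the state is kicked along the unstable mode and
#' re-minimized, taking the lower-energy branch. Convergence is declared
#' when the infinity norm of the projected gradient (outward radial
#' components at shell contacts removed) drops below `tol`.
#'
#' Under mirror-symmetric parameters the converged state is symmetrized
#' (averaged with its mirror image about the ventral midline) and
#' re-polished, which suppresses drift into tilted furrows seeded by
#' floating-point noise; disable for deliberately asymmetric perturbations.
#'
#' @param start Starting `vf_configuration` (or an `embryo_geometry`, whose
#'   rest configuration is used).
#' @param geom The `embryo_geometry`.
#' @param ann A [tissue_annotation()]; defaults to the one implied by `p`.
#' @param p A [model_params()] object.
#' @param tol Projected-gradient infinity-norm tolerance; default
#'   `1e-6 * 5000 * a0` (the default contractility energy scale).
#' @param max_iter Iteration-unit budget across all descent legs: one unit
#'   per first-order gradient evaluation, 25 units per Newton iteration
#'   (its relative cost). Default 100000; post-inhibition relaxation
#'   cascades in soft-lateral regimes may need several times more.
#' @param symmetrize Mirror-symmetrize the converged state (default TRUE).
#' @return An object of class `equilibrium_state` with fields
#'   `configuration`, `Kb_value`, `converged`, `grad_norm`, `n_iter`,
#'   `energy`, `eig_min` (smallest free Hessian eigenvalue) and
#'   `energy_trace` (accepted iterate energies of the final descent leg,
#'   non-increasing; earlier legs in `energy_legs`).
#' @export
minimize_energy <- function(start, geom, ann = annotation_from_params(geom$n_cells, p),
                            p = model_params(), tol = default_tolerance(geom),
                            max_iter = 100000L, symmetrize = TRUE) {
  sys <- build_system(geom, ann, p)
  conf <- as_configuration(start)
  n <- sys$n; m <- 2L * n

  if (symmetrize) {
    # minimize within the mirror-symmetric subspace: equivalent to
    # symmetrizing after every step, with half the unknowns and no
    # spurious tilt modes
    conf <- symmetrize_configuration(conf)
    prob <- make_problem_sym(sys)
    res <- minimize_core(sym_state_from_conf(conf, n), prob, tol, max_iter)
    z <- .sym_expand_cpp(res$z, n)
  } else {
    prob <- make_problem_full(sys)
    res <- minimize_core(polar_from_conf(conf), prob, tol, max_iter)
    z <- res$z
  }

  conf <- conf_from_polar(z, n)
  g <- .polar_grad_cpp(z, sys)
  pg <- polar_pg_norm(z, g, sys$R, m)
  converged <- pg <= 2 * tol
  if (!converged)
    warning(sprintf("minimization not converged: |pg| = %.3g > tol = %.3g",
                    pg, tol))
  E <- .polar_energy_cpp(z, sys)
  legs <- res$legs
  structure(list(configuration = conf, Kb_value = p$Kb, converged = converged,
                 grad_norm = pg, n_iter = res$n_iter, energy = E,
                 eig_min = res$eig_min,
                 energy_trace = if (length(legs)) legs[[length(legs)]]
                 else numeric(0),
                 energy_legs = legs),
            class = "equilibrium_state")
}

default_kb_schedule <- function() 2^(10:0)

#' Run the adiabatic basal-stiffness schedule
#'
#' Lowers the basal spring constant stepwise (default: twofold reductions
#' from 2^10 to 2^0, eleven values) and equilibrates the model at each
#' value, each minimization warm-started from the previous equilibrium. The
#' resulting sequence of equilibrium states traces the quasi-static furrow
#' trajectory, including the lengthening--shortening behaviour of the
#' constricting cells.
#'
#' @param geom An `embryo_geometry`.
#' @param ann A [tissue_annotation()]; defaults to the one implied by `p`.
#' @param p A [model_params()] object; `p$Kb` is overridden by the schedule.
#' @param schedule Strictly decreasing, positive basal stiffness values.
#' @param tol,max_iter,symmetrize Passed to [minimize_energy()].
#' @param verbose Print one line per schedule state.
#' @return An object of class `trajectory`: fields `states` (list of
#'   `equilibrium_state`), `kb_values`, `schedule`, `params`, `geom`, `ann`,
#'   `perturbation` (NULL for an unperturbed run).
#' @export
run_schedule <- function(geom, ann = annotation_from_params(geom$n_cells, p),
                         p = model_params(), schedule = default_kb_schedule(),
                         tol = default_tolerance(geom), max_iter = 100000L,
                         symmetrize = TRUE, verbose = FALSE) {
  if (any(diff(schedule) >= 0) || any(schedule <= 0))
    stop("schedule must be strictly decreasing and positive")
  states <- vector("list", length(schedule))
  conf <- as_configuration(geom)
  for (k in seq_along(schedule)) {
    p$Kb <- schedule[k]
    st <- minimize_energy(conf, geom, ann, p, tol = tol, max_iter = max_iter,
                          symmetrize = symmetrize)
    states[[k]] <- st
    conf <- st$configuration
    if (verbose)
      message(sprintf("Kb = %6.0f  E = %14.4f  |pg| = %9.3g  iter = %d  D = %.2f",
                      schedule[k], st$energy, st$grad_norm, st$n_iter,
                      invagination_depth(st, geom)))
  }
  structure(list(states = states, kb_values = schedule, schedule = schedule,
                 params = p, geom = geom, ann = ann, perturbation = NULL),
            class = "trajectory")
}

#' Continue a schedule from an intermediate state under new parameters
#'
#' Re-runs the remaining schedule entries starting from state `from_index`
#' under `p_override`, re-equilibrating at the final basal stiffness if the
#' starting state is already the last one. Used to encode in-silico
#' perturbations (for instance zeroing contractility at a chosen
#' intermediate equilibrium).
#'
#' @param traj A `trajectory`.
#' @param from_index State index (1-based) at which the override takes
#'   effect.
#' @param p_override The [model_params()] governing the continuation.
#' @param tol,max_iter,symmetrize Passed to [minimize_energy()].
#' @return A new `trajectory` whose states up to `from_index` are shared
#'   with `traj` and whose `perturbation` field records the override.
#' @export
continue_schedule <- function(traj, from_index, p_override,
                              tol = default_tolerance(traj$geom),
                              max_iter = 400000L, symmetrize = TRUE) {
  ns <- length(traj$states)
  if (from_index < 1L || from_index > ns)
    stop("from_index out of range")
  schedule <- traj$schedule
  remaining <- if (from_index < length(schedule))
    schedule[(from_index + 1L):length(schedule)]
  else schedule[length(schedule)]
  geom <- traj$geom
  ann <- annotation_from_params(geom$n_cells, p_override)
  conf <- traj$states[[from_index]]$configuration
  new_states <- vector("list", length(remaining))
  for (k in seq_along(remaining)) {
    p_override$Kb <- remaining[k]
    st <- minimize_energy(conf, geom, ann, p_override, tol = tol,
                          max_iter = max_iter, symmetrize = symmetrize)
    new_states[[k]] <- st
    conf <- st$configuration
  }
  structure(list(states = c(traj$states[seq_len(from_index)], new_states),
                 kb_values = c(schedule[seq_len(from_index)], remaining),
                 schedule = schedule, params = p_override, geom = geom,
                 ann = ann,
                 perturbation = list(from_index = from_index,
                                     params = p_override)),
            class = "trajectory")
}
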