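# In-silico perturbation experiments: acute removal of contractility at
# intermediate equilibrium states, compression on/off, parameter sweeps and
# constriction-domain perturbations.

#' Classify the tissue response to a perturbation
#'
#' Quasi-static analogue of the experimental relaxed / paused / invaginated
#' classes: the final invagination depth is compared with that of the
#' unperturbed reference run. `relaxed` if `D_final < thresholds[1] * D_ref`,
#' `invaginated` if `D_final > thresholds[2] * D_ref`, `paused` otherwise.
#'
#' @param final Final `equilibrium_state` of the perturbed run.
#' @param initial Initial state (unused by the depth rule; kept so the
#'   classification sees the whole comparison triplet).
#' @param reference_final Final state of the unperturbed reference run.
#' @param geom The `embryo_geometry`.
#' @param thresholds Fractions of the reference depth separating the classes
#'   (default `c(0.2, 0.8)`).
#' @return One of `"relaxed"`, `"paused"`, `"invaginated"`.
#' @export
classify_response <- function(final, initial, reference_final, geom,
                              thresholds = c(0.2, 0.8)) {
  D_ref <- invagination_depth(reference_final, geom)
  if (D_ref <= 0) stop("reference run shows no furrow (D_ref <= 0)")
  D_final <- invagination_depth(final, geom)
  if (D_final < thresholds[1] * D_ref) "relaxed"
  else if (D_final > thresholds[2] * D_ref) "invaginated"
  else "paused"
}

#' Acute in-silico inhibition of actomyosin at an intermediate state
#'
#' Models optogenetic inhibition: starting from state `k` of an unperturbed
#' trajectory, apical contractility (`mu0`) and the myosin-dependent active
#' lateral spring (`KL_active`) are set to zero and the remaining basal-
#' stiffness schedule is run to completion. The final state is classified
#' against the unperturbed final state.
#'
#' @param base An unperturbed `trajectory`.
#' @param k State index (1-based) at which contractility is removed; the
#'   base state at `k` must be converged.
#' @param thresholds Classification thresholds, see [classify_response()].
#' @param tol,max_iter Solver settings for the continuation.
#' @return An object of class `experiment_result` with fields `spec`,
#'   `trajectory`, `response`, `D_final`, `D_ref`.
#' @export
inhibit_at_state <- function(base, k, thresholds = c(0.2, 0.8),
                             tol = default_tolerance(base$geom),
                             max_iter = 400000L) {
  if (k < 1L || k > length(base$states)) stop("k out of range")
  if (!base$states[[k]]$converged)
    stop("base trajectory state ", k, " is not converged")
  p2 <- base$params
  p2$mu0 <- 0
  p2$KL_active <- 0
  cont <- continue_schedule(base, k, p2, tol = tol, max_iter = max_iter)
  final <- cont$states[[length(cont$states)]]
  ref_final <- base$states[[length(base$states)]]
  response <- classify_response(final, base$states[[1L]], ref_final,
                                base$geom, thresholds)
  structure(list(
    spec = list(kind = "inhibit_contractility", inhibit_at = k,
                params = base$params),
    trajectory = cont,
    response = response,
    D_final = invagination_depth(final, base$geom),
    D_ref = invagination_depth(ref_final, base$geom)
  ), class = "experiment_result")
}

#' Find the transitional schedule state
#'
#' The smallest state index whose inhibition still yields an invaginated
#' final state; `NA` when no index qualifies (no mechanical bistability).
#' With `method = "scan"` every index is tested in order, returning the
#' full relaxed/invaginated pattern; `method = "bisect"` exploits the
#' dichotomy of the response (relaxed below the transition, invaginated at
#' and above it) to locate the transition with O(log n) inhibition runs.
#'
#' @param base An unperturbed, converged `trajectory`.
#' @param ks State indices to test (default: all; `"scan"` only).
#' @param method `"scan"` or `"bisect"`.
#' @param thresholds Classification thresholds.
#' @param tol,max_iter Solver settings for the continuations.
#' @return List with `k_star` (integer index or `NA`), `ks`, `responses`
#'   and `D_final` over the tested indices.
#' @export
find_transition <- function(base, ks = seq_along(base$states),
                            method = c("scan", "bisect"),
                            thresholds = c(0.2, 0.8),
                            tol = default_tolerance(base$geom),
                            max_iter = 400000L) {
  method <- match.arg(method)
  probe <- function(k) inhibit_at_state(base, k, thresholds = thresholds,
                                        tol = tol, max_iter = max_iter)
  if (method == "scan") {
    responses <- character(length(ks))
    D_final <- numeric(length(ks))
    for (j in seq_along(ks)) {
      res <- probe(ks[j])
      responses[j] <- res$response
      D_final[j] <- res$D_final
    }
    inv <- which(responses == "invaginated")
    return(list(k_star = if (length(inv)) ks[min(inv)] else NA_integer_,
                ks = ks, responses = responses, D_final = D_final))
  }
  ns <- length(base$states)
  tested_k <- integer(0); tested_r <- character(0); tested_D <- numeric(0)
  eval_k <- function(k) {
    res <- probe(k)
    tested_k <<- c(tested_k, k)
    tested_r <<- c(tested_r, res$response)
    tested_D <<- c(tested_D, res$D_final)
    res$response
  }
  if (eval_k(ns) != "invaginated") {
    return(list(k_star = NA_integer_, ks = tested_k, responses = tested_r,
                D_final = tested_D))
  }
  lo <- 1L; hi <- ns  # invariant: hi invaginated, lo..hi-1 undetermined
  if (eval_k(lo) == "invaginated") {
    hi <- lo
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (eval_k(mid) == "invaginated") hi <- mid else lo <- mid
    }
  }
  ord <- order(tested_k)
  list(k_star = hi, ks = tested_k[ord], responses = tested_r[ord],
       D_final = tested_D[ord])
}

#' Sweep the ectodermal shortening fraction
#'
#' For each `deltaL`, runs the full schedule, locates the transitional state
#' and records the final depth after late inhibition (inhibition at the
#' transitional state itself). Bistable means a transitional state exists.
#'
#' @param values Shortening fractions to test.
#' @param geom An `embryo_geometry`.
#' @param p Baseline [model_params()].
#' @param tol,max_iter Solver settings.
#' @return A `data.frame` with columns `deltaL`, `k_star`, `D_ref`,
#'   `D_final_late`, `bistable`.
#' @export
sweep_deltaL <- function(values = c(0, 0.05, 0.10, 0.20),
                         geom = build_initial_geometry(),
                         p = model_params(),
                         tol = default_tolerance(geom), max_iter = 400000L) {
  if (any(values < 0 | values >= 1)) stop("deltaL values must lie in [0, 1)")
  rows <- lapply(values, function(dL) {
    p$deltaL <- dL
    base <- run_schedule(geom, p = p, tol = tol, max_iter = max_iter)
    tr <- find_transition(base, method = "bisect", tol = tol,
                          max_iter = max_iter)
    late_k <- if (is.na(tr$k_star)) length(base$states) else tr$k_star
    data.frame(deltaL = dL, k_star = tr$k_star,
               D_ref = invagination_depth(
                 base$states[[length(base$states)]], geom),
               D_final_late = tr$D_final[match(late_k, tr$ks)],
               bistable = !is.na(tr$k_star))
  })
  do.call(rbind, rows)
}

#' Sweep the active and passive lateral spring constants
#'
#' Grid over `KL_active` x `KL_passive` in the constriction domain. For
#' each grid cell: run the full schedule, record whether the unperturbed
#' final furrow is morphologically normal (depth of at least
#' `normal_depth_min`), find the transitional state and record the
#' late-inhibition response and depth.
#'
#' @param KL_active_values,KL_passive_values Grid values (>= 0).
#' @param geom An `embryo_geometry`.
#' @param p Baseline [model_params()].
#' @param normal_depth_min Minimum unperturbed final depth (um) for the
#'   morphology to count as a normal furrow (default 40).
#' @param tol,max_iter Solver settings.
#' @return A `data.frame` with columns `KL_active`, `KL_passive`, `D_ref`,
#'   `normal_morphology`, `k_star`, `response_late`, `D_final_late`.
#' @export
sweep_lateral <- function(KL_active_values = c(0, 2),
                          KL_passive_values = c(0.2, 2, 20),
                          geom = build_initial_geometry(),
                          p = model_params(), normal_depth_min = 40,
                          tol = default_tolerance(geom), max_iter = 400000L) {
  grid <- expand.grid(KL_active = KL_active_values,
                      KL_passive = KL_passive_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p$KL_active <- grid$KL_active[i]
    p$KL_passive <- grid$KL_passive[i]
    base <- run_schedule(geom, p = p, tol = tol, max_iter = max_iter)
    D_ref <- invagination_depth(base$states[[length(base$states)]], geom)
    tr <- find_transition(base, method = "bisect", tol = tol,
                          max_iter = max_iter)
    late <- if (is.na(tr$k_star)) list(response = NA_character_,
                                       D = NA_real_)
    else list(response = tr$responses[match(tr$k_star, tr$ks)],
              D = tr$D_final[match(tr$k_star, tr$ks)])
    data.frame(KL_active = grid$KL_active[i],
               KL_passive = grid$KL_passive[i],
               D_ref = D_ref,
               normal_morphology = D_ref >= normal_depth_min,
               k_star = tr$k_star,
               response_late = late$response,
               D_final_late = late$D)
  })
  do.call(rbind, rows)
}

#' Perturb the apical constriction pattern
#'
#' Two developmental perturbations of the contractility profile:
#' `narrow_sigma` shrinks the width of the Gaussian (fewer constricting
#' cells); `alternate_cells` silences every other cell of the 18-cell
#' mesoderm domain (uncoordinated constriction). The full schedule is run
#' under the modified profile, with or without ectodermal compression.
#' The alternating pattern is not mirror-symmetric, so symmetrization is
#' disabled for it.
#'
#' @param mode `"narrow_sigma"` or `"alternate_cells"`.
#' @param with_compression Keep the ectodermal shortening of `p` (TRUE) or
#'   set `deltaL = 0` (FALSE).
#' @param geom An `embryo_geometry`.
#' @param p Baseline [model_params()].
#' @param sigma_narrow Gaussian width used by `narrow_sigma` (default 1.5,
#'   half the baseline width).
#' @param tol,max_iter Solver settings.
#' @return An `experiment_result` with the trajectory and final depth
#'   `D_final` of the perturbed, uninhibited run.
#' @export
perturb_constriction <- function(mode = c("narrow_sigma", "alternate_cells"),
                                 with_compression = TRUE,
                                 geom = build_initial_geometry(),
                                 p = model_params(), sigma_narrow = 1.5,
                                 tol = default_tolerance(geom),
                                 max_iter = 400000L) {
  mode <- match.arg(mode)
  symmetrize <- TRUE
  if (!with_compression) p$deltaL <- 0
  if (mode == "narrow_sigma") {
    p$sigma <- sigma_narrow
  } else {
    n <- geom$n_cells
    domain <- c((n - p$half_width + 1L):n, seq_len(p$half_width))
    phi <- integer(n)
    phi[domain[seq(1L, length(domain), by = 2L)]] <- 1L
    p$phi_override <- phi
    symmetrize <- FALSE
  }
  base <- run_schedule(geom, p = p, tol = tol, max_iter = max_iter,
                       symmetrize = symmetrize)
  final <- base$states[[length(base$states)]]
  structure(list(
    spec = list(kind = mode, with_compression = with_compression,
                params = p),
    trajectory = base,
    response = NA_character_,
    D_final = invagination_depth(final, geom),
    D_ref = NA_real_
  ), class = "experiment_result")
}
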