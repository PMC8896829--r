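# Mechanical energy of the cell ring and its analytic gradient.
#
# E = sum_i phi_i mu_i a_i^2                          (apical contractility)
#   + sum_i [ Ka (a_i - a0)^2 + Kb (b_i - b0)^2 ]     (apical/basal elasticity)
#   + sum_edges K_lat (l - l0)^2                      (passive lateral)
#   + sum_{constriction edges} KL_active l^2          (active lateral, rest 0)
#   + sum_i Kv (V_i - V0)^2 + KY (Vyolk - V0yolk)^2   (area penalties)
#
# Lengths a, b, l are apical/basal/lateral edge lengths; V are shoelace areas
# of the cell quadrilaterals, Vyolk the area of the basal polygon. The
# vitelline confinement is not part of the energy (it is a hard constraint
# enforced by the minimizer), so the energy is translation invariant.

#' Model parameters
#'
#' All spring constants of the vertex model, with the defaults used for the
#' baseline furrow simulations: apical `Ka = 30`, ectodermal lateral
#' `Kl = 20`, basal `Kb` (schedule-controlled, here its initial value 2^10),
#' contractility amplitude `mu0 = 5000` with Gaussian width `sigma = 3`,
#' cell-area penalty `Kv = 5000` and yolk-area penalty `KY = 1`. Lateral
#' edges of the constriction domain carry an active zero-rest-length spring
#' `KL_active` (default 2; 0 gives the purely passive base model) and a
#' passive spring `KL_passive` (default 20). `deltaL` is the fractional
#' apicobasal rest-length reduction applied to ectodermal lateral edges to
#' generate in-plane compression (default 0.20).
#'
#' The constants are dimensionless; lengths are micrometres, so energies are
#' in arbitrary units.
#'
#' @param Ka,Kl,Kb,mu0,sigma,Kv,KY,KL_active,KL_passive Spring constants and
#'   contractility profile parameters, all >= 0 (`sigma` > 0).
#' @param deltaL Fractional ectodermal lateral rest-length reduction in
#'   `[0, 1)`.
#' @param half_width Mesodermal cells on each side of the ventral midline
#'   (default 9, giving the 18-cell constriction domain).
#' @param phi_override Optional explicit 0/1 contractility indicator within
#'   the mesoderm domain (see [tissue_annotation()]).
#' @param boundary_lateral Whether the two mesoderm--ectoderm boundary
#'   lateral edges belong to the constriction domain for the lateral force
#'   terms (`"mesoderm"`, default) or to the ectoderm (`"ectoderm"`).
#' @param shorten_cells Which ectodermal cells receive the `deltaL`
#'   shortening: `"all"` (default; every non-mesodermal cell) or `"sixty"`
#'   (excludes the one ectodermal cell flanking the mesoderm on each side,
#'   leaving 60 of the 62 with the default geometry).
#' @return An object of class `model_params`.
#' @export
model_params <- function(Ka = 30, Kl = 20, Kb = 2^10, mu0 = 5000, sigma = 3,
                         Kv = 5000, KY = 1, KL_active = 2, KL_passive = 20,
                         deltaL = 0.20, half_width = 9L, phi_override = NULL,
                         boundary_lateral = c("mesoderm", "ectoderm"),
                         shorten_cells = c("all", "sixty")) {
  vals <- c(Ka = Ka, Kl = Kl, Kb = Kb, mu0 = mu0, Kv = Kv, KY = KY,
            KL_active = KL_active, KL_passive = KL_passive)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad)) stop("parameters must be finite and >= 0: ",
                        paste(bad, collapse = ", "))
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(deltaL) || deltaL < 0 || deltaL >= 1)
    stop("deltaL must lie in [0, 1)")
  structure(list(Ka = Ka, Kl = Kl, Kb = Kb, mu0 = mu0, sigma = sigma,
                 Kv = Kv, KY = KY, KL_active = KL_active,
                 KL_passive = KL_passive, deltaL = deltaL,
                 half_width = as.integer(half_width),
                 phi_override = phi_override,
                 boundary_lateral = match.arg(boundary_lateral),
                 shorten_cells = match.arg(shorten_cells)),
            class = "model_params")
}

#' Derive the tissue annotation implied by a parameter set
#'
#' @param n_cells Number of cells in the ring.
#' @param p A [model_params()] object.
#' @return A [tissue_annotation()] object.
#' @export
annotation_from_params <- function(n_cells, p) {
  tissue_annotation(n_cells, half_width = p$half_width, mu0 = p$mu0,
                    sigma = p$sigma, phi_override = p$phi_override)
}

#' Vertex configuration of a geometry
#'
#' A configuration is the positional state of the model: the apical and
#' basal vertex coordinate matrices. Edge lengths and areas are derived from
#' it with [edge_lengths()], [cell_areas()] and [yolk_area()].
#'
#' @param geom An `embryo_geometry` (or an existing configuration, returned
#'   unchanged).
#' @return An object of class `vf_configuration` with `apical` and `basal`
#'   n x 2 coordinate matrices.
#' @export
as_configuration <- function(geom) {
  if (inherits(geom, "vf_configuration")) return(geom)
  structure(list(apical = geom$apical, basal = geom$basal),
            class = "vf_configuration")
}

#' Edge lengths of a configuration
#'
#' @param conf A `vf_configuration`.
#' @param type One of `"apical"`, `"basal"`, `"lateral"`.
#' @return Numeric vector of edge lengths (um), one per cell for apical and
#'   basal edges (the edge of cell i joins ring positions i and i+1), one
#'   per ring position for lateral edges.
#' @export
edge_lengths <- function(conf, type = c("apical", "basal", "lateral")) {
  type <- match.arg(type)
  A <- conf$apical; B <- conf$basal
  n <- nrow(A); nx <- ring_next(n)
  d <- switch(type,
              apical = A[nx, , drop = FALSE] - A,
              basal = B[nx, , drop = FALSE] - B,
              lateral = A - B)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

# Signed shoelace area of a polygon given as an n x 2 matrix (counter-
# clockwise positive).
polygon_area <- function(P) {
  n <- nrow(P); nx <- ring_next(n)
  0.5 * sum(P[, 1] * P[nx, 2] - P[nx, 1] * P[, 2])
}

#' Cell areas of a configuration
#'
#' Signed shoelace area of each cell quadrilateral
#' (apical i, apical i+1, basal i+1, basal i), positive for the initial
#' counter-clockwise orientation.
#'
#' @param conf A `vf_configuration`.
#' @return Numeric vector of per-cell areas (um^2).
#' @export
cell_areas <- function(conf) {
  A <- conf$apical; B <- conf$basal
  n <- nrow(A); nx <- ring_next(n)
  x1 <- A[, 1]; y1 <- A[, 2]
  x2 <- A[nx, 1]; y2 <- A[nx, 2]
  x3 <- B[nx, 1]; y3 <- B[nx, 2]
  x4 <- B[, 1]; y4 <- B[, 2]
  0.5 * (x1 * y2 - x2 * y1 + x2 * y3 - x3 * y2 +
           x3 * y4 - x4 * y3 + x4 * y1 - x1 * y4)
}

#' Yolk area of a configuration
#'
#' Signed area enclosed by the basal polygon.
#'
#' @param conf A `vf_configuration`.
#' @return Yolk area (um^2).
#' @export
yolk_area <- function(conf) polygon_area(conf$basal)

#' Apply apicobasal rest-length shortening to ectodermal lateral edges
#'
#' Scales the rest length of the targeted lateral edges by `1 - deltaL`,
#' leaving every other rest quantity unchanged. Because cell area is
#' conserved by the penalty terms, apicobasal shortening widens the cells in
#' the plane of the epithelium, which generates in-plane compression.
#'
#' @param geom An `embryo_geometry`.
#' @param deltaL Fractional rest-length reduction in `[0, 1)`.
#' @param ann A [tissue_annotation()] used to reject mesodermal targets.
#' @param targets Indices of lateral edges to shorten; defaults to all
#'   non-mesodermal lateral edges.
#' @return The modified `embryo_geometry`.
#' @export
apply_ectoderm_shortening <- function(geom, deltaL = 0.20,
                                      ann = tissue_annotation(geom$n_cells),
                                      targets = NULL) {
  if (!is.finite(deltaL) || deltaL < 0 || deltaL >= 1)
    stop("deltaL must lie in [0, 1)")
  if (is.null(targets)) targets <- which(!ann$meso_lateral)
  if (any(ann$meso_lateral[targets]))
    stop("targets must not include mesodermal lateral edges")
  geom$rest_lateral[targets] <- (1 - deltaL) * geom$rest_lateral[targets]
  geom
}

# Lateral edges receiving the deltaL shortening under a parameter set:
# edges both of whose adjoining cells are in the shortened-cell set.
shortened_lateral_edges <- function(geom, ann, p) {
  n <- geom$n_cells
  target_cells <- ann$phi * 0L
  target_cells[ann$ectoderm_indices] <- 1L
  if (p$shorten_cells == "sixty") {
    prev <- ring_prev(n); nxt <- ring_next(n)
    meso <- integer(n); meso[ann$mesoderm] <- 1L
    flank <- target_cells == 1L & (meso[prev] == 1L | meso[nxt] == 1L)
    target_cells[flank] <- 0L
  }
  prev <- ring_prev(n)
  which(target_cells == 1L & target_cells[prev] == 1L)
}

# Precompute everything the energy evaluation needs for fixed geometry,
# annotation and parameters: rest quantities (with deltaL applied), per-edge
# spring constants, contractility weights.
build_system <- function(geom, ann, p) {
  n <- geom$n_cells
  meso_edge <- if (p$boundary_lateral == "mesoderm") ann$meso_lateral else {
    prev <- ring_prev(n)
    meso <- integer(n); meso[ann$mesoderm] <- 1L
    meso == 1L & meso[prev] == 1L
  }
  rest_l <- geom$rest_lateral
  sh <- shortened_lateral_edges(geom, ann, p)
  rest_l[sh] <- (1 - p$deltaL) * rest_l[sh]
  list(
    n = n,
    nx = ring_next(n),
    pv = ring_prev(n),
    w = ann$phi * ann$mu,             # phi_i * mu_i per cell
    Ka = p$Ka, Kb = p$Kb, Kv = p$Kv, KY = p$KY,
    K_lat = ifelse(meso_edge, p$KL_passive, p$Kl),
    K_act = ifelse(meso_edge, p$KL_active, 0),
    rest_a = geom$rest_apical,
    rest_b = geom$rest_basal,
    rest_l = rest_l,
    V0 = geom$rest_area,
    V0y = geom$rest_yolk,
    R = geom$vitelline_radius
  )
}

# Core evaluation: energy, per-term breakdown and analytic gradient for a
# configuration, given a precomputed system. Returns list(E, terms, gA, gB).
vf_energy_grad <- function(A, B, sys, gradient = TRUE) {
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("non-finite vertex coordinates")
  n <- sys$n; nx <- sys$nx; pv <- sys$pv
  eAx <- A[nx, 1] - A[, 1]; eAy <- A[nx, 2] - A[, 2]
  a <- sqrt(eAx^2 + eAy^2)
  eBx <- B[nx, 1] - B[, 1]; eBy <- B[nx, 2] - B[, 2]
  b <- sqrt(eBx^2 + eBy^2)
  eLx <- A[, 1] - B[, 1]; eLy <- A[, 2] - B[, 2]
  l <- sqrt(eLx^2 + eLy^2)

  x1 <- A[, 1]; y1 <- A[, 2]
  x2 <- A[nx, 1]; y2 <- A[nx, 2]
  x3 <- B[nx, 1]; y3 <- B[nx, 2]
  x4 <- B[, 1]; y4 <- B[, 2]
  V <- 0.5 * (x1 * y2 - x2 * y1 + x2 * y3 - x3 * y2 +
                x3 * y4 - x4 * y3 + x4 * y1 - x1 * y4)
  Vy <- 0.5 * sum(B[, 1] * B[nx, 2] - B[nx, 1] * B[, 2])

  terms <- c(
    apical_contractility = sum(sys$w * a^2),
    apical_elastic = sys$Ka * sum((a - sys$rest_a)^2),
    basal_elastic = sys$Kb * sum((b - sys$rest_b)^2),
    lateral_passive = sum(sys$K_lat * (l - sys$rest_l)^2),
    lateral_active = sum(sys$K_act * l^2),
    cell_area_penalty = sys$Kv * sum((V - sys$V0)^2),
    yolk_penalty = sys$KY * (Vy - sys$V0y)^2
  )
  E <- sum(terms)
  if (!gradient) return(list(E = E, terms = terms, V = V, Vy = Vy))

  gAx <- numeric(n); gAy <- numeric(n)
  gBx <- numeric(n); gBy <- numeric(n)

  # Apical edges: contractility (d a^2 = 2 e) plus elasticity.
  ca <- 2 * sys$w + 2 * sys$Ka * (a - sys$rest_a) / a
  gAx[nx] <- ca * eAx; gAy[nx] <- ca * eAy
  gAx <- gAx - ca * eAx; gAy <- gAy - ca * eAy
  # Basal edges.
  cb <- 2 * sys$Kb * (b - sys$rest_b) / b
  gBx[nx] <- gBx[nx] + cb * eBx; gBy[nx] <- gBy[nx] + cb * eBy
  gBx <- gBx - cb * eBx; gBy <- gBy - cb * eBy
  # Lateral edges: passive + active (zero-rest spring: d l^2 = 2 e).
  cl <- 2 * sys$K_lat * (l - sys$rest_l) / l + 2 * sys$K_act
  gAx <- gAx + cl * eLx; gAy <- gAy + cl * eLy
  gBx <- gBx - cl * eLx; gBy <- gBy - cl * eLy

  # Cell-area penalty: shoelace gradient of each quadrilateral.
  q <- 2 * sys$Kv * (V - sys$V0)
  gAx <- gAx + q * 0.5 * (y2 - y4); gAy <- gAy + q * 0.5 * (x4 - x2)
  gAx[nx] <- gAx[nx] + q * 0.5 * (y3 - y1)
  gAy[nx] <- gAy[nx] + q * 0.5 * (x1 - x3)
  gBx[nx] <- gBx[nx] + q * 0.5 * (y4 - y2)
  gBy[nx] <- gBy[nx] + q * 0.5 * (x2 - x4)
  gBx <- gBx + q * 0.5 * (y1 - y3); gBy <- gBy + q * 0.5 * (x3 - x1)

  # Yolk penalty: shoelace gradient of the basal polygon.
  qy <- 2 * sys$KY * (Vy - sys$V0y)
  gBx <- gBx + qy * 0.5 * (B[nx, 2] - B[pv, 2])
  gBy <- gBy + qy * 0.5 * (B[pv, 1] - B[nx, 1])

  list(E = E, terms = terms, V = V, Vy = Vy,
       gA = cbind(gAx, gAy, deparse.level = 0),
       gB = cbind(gBx, gBy, deparse.level = 0))
}

#' Total mechanical energy of a configuration
#'
#' @param conf A `vf_configuration`.
#' @param geom The `embryo_geometry` holding the rest quantities.
#' @param ann A [tissue_annotation()]; defaults to the one implied by `p`.
#' @param p A [model_params()] object.
#' @return Scalar energy (arbitrary units).
#' @export
total_energy <- function(conf, geom, ann = annotation_from_params(geom$n_cells, p),
                         p = model_params()) {
  sys <- build_system(geom, ann, p)
  vf_energy_grad(conf$apical, conf$basal, sys, gradient = FALSE)$E
}

#' Per-term energy breakdown
#'
#' Splits the total energy into its seven contributions:
#' `apical_contractility`, `apical_elastic`, `basal_elastic`,
#' `lateral_passive`, `lateral_active`, `cell_area_penalty`,
#' `yolk_penalty`. The terms sum to [total_energy()].
#'
#' @inheritParams total_energy
#' @return Named numeric vector of the seven term energies.
#' @export
energy_breakdown <- function(conf, geom, ann = annotation_from_params(geom$n_cells, p),
                             p = model_params()) {
  sys <- build_system(geom, ann, p)
  vf_energy_grad(conf$apical, conf$basal, sys, gradient = FALSE)$terms
}

#' Analytic energy gradient
#'
#' Gradient of [total_energy()] with respect to every vertex coordinate.
#'
#' @inheritParams total_energy
#' @return List with `apical` and `basal` n x 2 gradient matrices.
#' @export
energy_gradient <- function(conf, geom, ann = annotation_from_params(geom$n_cells, p),
                            p = model_params()) {
  sys <- build_system(geom, ann, p)
  res <- vf_energy_grad(conf$apical, conf$basal, sys)
  list(apical = res$gA, basal = res$gB)
}

#' Lateral shortening force in the constriction domain
#'
#' Diagnostic force law for a lateral edge of a constricting cell: the
#' myosin-dependent active spring (rest length zero) contributes
#' `KL_active * l` and the passive elastic spring `KL_passive * (l - l0)`.
#'
#' @param l Current lateral edge length (um, >= 0).
#' @param l0 Rest length (um).
#' @param KL_active,KL_passive Active and passive spring constants.
#' @return Force (arbitrary units per um).
#' @export
lateral_shortening_force <- function(l, l0, KL_active = 2, KL_passive = 20) {
  stopifnot(all(l >= 0))
  KL_active * l + KL_passive * (l - l0)
}
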