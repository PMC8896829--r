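# Tissue- and cell-level readouts on simulated states.

#' Invagination depth of a state
#'
#' Distance between the vitelline shell and the apex of the ventral-most
#' point of the tissue: `D = vitelline_radius - |apical midline vertex|`,
#' where the midline vertex is the apical vertex shared by the two
#' midline-adjacent cells. Zero on the initial configuration (apices sit on
#' the shell), positive as the furrow internalizes.
#'
#' @param s An `equilibrium_state` (or a `vf_configuration`).
#' @param geom The `embryo_geometry`.
#' @return Invagination depth D (um, >= 0).
#' @export
invagination_depth <- function(s, geom) {
  conf <- if (inherits(s, "equilibrium_state")) s$configuration else
    as_configuration(s)
  apex <- conf$apical[1L, ]
  geom$vitelline_radius - sqrt(sum(apex^2))
}

#' Per-cell shape metrics of a state
#'
#' One row per cell: apical, basal and mean lateral edge length, shoelace
#' area, and tilt, the angle between the cell's apicobasal axis (basal
#' midpoint to apical midpoint) and the local radial direction through the
#' cell centroid. Tilt is zero for the initial radial wedges.
#'
#' @param s An `equilibrium_state` or `vf_configuration`.
#' @param geom The `embryo_geometry`.
#' @return A `data.frame` with columns `cell`, `apical`, `basal`, `lateral`,
#'   `area`, `tilt`.
#' @export
cell_shape_metrics <- function(s, geom) {
  conf <- if (inherits(s, "equilibrium_state")) s$configuration else
    as_configuration(s)
  n <- geom$n_cells; nx <- ring_next(n)
  A <- conf$apical; B <- conf$basal
  lat <- edge_lengths(conf, "lateral")
  apical_mid <- 0.5 * (A + A[nx, , drop = FALSE])
  basal_mid <- 0.5 * (B + B[nx, , drop = FALSE])
  centroid <- 0.25 * (A + A[nx, , drop = FALSE] + B + B[nx, , drop = FALSE])
  axis <- apical_mid - basal_mid
  cosang <- rowSums(axis * centroid) /
    (sqrt(rowSums(axis^2)) * sqrt(rowSums(centroid^2)))
  tilt <- acos(pmin(1, pmax(-1, cosang)))
  data.frame(
    cell = seq_len(n),
    apical = edge_lengths(conf, "apical"),
    basal = edge_lengths(conf, "basal"),
    lateral = 0.5 * (lat + lat[nx]),
    area = cell_areas(conf),
    tilt = tilt
  )
}

# Angle of each cell centroid from the ventral midline direction (0, -1),
# in degrees [0, 180], plus the side of the midline it falls on.
cell_midline_angles <- function(conf, n) {
  nx <- ring_next(n)
  centroid <- 0.25 * (conf$apical + conf$apical[nx, , drop = FALSE] +
                        conf$basal + conf$basal[nx, , drop = FALSE])
  cosang <- -centroid[, 2] / sqrt(rowSums(centroid^2))
  list(angle = acos(pmin(1, pmax(-1, cosang))) * 180 / pi,
       side = ifelse(centroid[, 1] < 0, "left", "right"))
}

#' Cross-section area of a sector of the cell layer
#'
#' Sum of the areas of the cells whose centroid lies within an angular
#' window measured from the ventral midline, on one side of the embryo.
#' Windows are half-open `[lo, hi)` except that 180 degrees is included in a
#' window ending there, so a set of windows partitioning (0, 180] tiles the
#' whole cell layer.
#'
#' @param s An `equilibrium_state` or `vf_configuration`.
#' @param geom The `embryo_geometry`.
#' @param angle_window Numeric `c(lo, hi)` in degrees from the midline,
#'   within `[0, 180]`, `lo < hi`.
#' @param side `"left"` or `"right"` of the midline.
#' @return Sector area (um^2).
#' @export
ectoderm_sector_area <- function(s, geom, angle_window = c(60, 90),
                                 side = c("left", "right")) {
  side <- match.arg(side)
  if (length(angle_window) != 2L || diff(angle_window) <= 0 ||
      angle_window[1] < 0 || angle_window[2] > 180)
    stop("angle_window must be an increasing pair within [0, 180]")
  conf <- if (inherits(s, "equilibrium_state")) s$configuration else
    as_configuration(s)
  am <- cell_midline_angles(conf, geom$n_cells)
  sel <- am$side == side & am$angle >= angle_window[1] &
    (am$angle < angle_window[2] |
       (angle_window[2] == 180 & am$angle <= 180))
  sum(cell_areas(conf)[sel])
}

#' Count apically constricting cells
#'
#' Number of cells whose apical edge length in the final state of a
#' trajectory has dropped below `threshold_fraction` of its initial value.
#' With the Gaussian contractility profile (sigma = 3) restricted to the
#' 18-cell mesoderm domain, the baseline simulation constricts 12 cells at
#' the ventral-most region.
#'
#' @param traj A `trajectory`.
#' @param threshold_fraction Fraction of the initial apical length below
#'   which a cell counts as constricting (default 0.5).
#' @return Integer count.
#' @export
count_constricting_cells <- function(traj, threshold_fraction = 0.5) {
  final <- traj$states[[length(traj$states)]]
  a <- edge_lengths(final$configuration, "apical")
  sum(a < threshold_fraction * traj$geom$rest_apical)
}

#' Per-state tissue metrics of a trajectory
#'
#' @param traj A `trajectory`.
#' @return A `data.frame` with one row per state: `state_index`, `Kb`,
#'   `energy`, `converged`, `grad_norm`, `n_iter`, `D`, `yolk_area`,
#'   `min_apical`, `max_area_dev` (max relative cell-area deviation from
#'   rest).
#' @export
trajectory_metrics <- function(traj) {
  geom <- traj$geom
  rows <- lapply(seq_along(traj$states), function(k) {
    st <- traj$states[[k]]
    V <- cell_areas(st$configuration)
    data.frame(
      state_index = k,
      Kb = traj$kb_values[k],
      energy = st$energy,
      converged = st$converged,
      grad_norm = st$grad_norm,
      n_iter = st$n_iter,
      D = invagination_depth(st, geom),
      yolk_area = yolk_area(st$configuration),
      min_apical = min(edge_lengths(st$configuration, "apical")),
      max_area_dev = max(abs(V - geom$rest_area) / geom$rest_area)
    )
  })
  do.call(rbind, rows)
}

#' Per-cell long-format metrics of a trajectory
#'
#' @param traj A `trajectory`.
#' @return A `data.frame` with `n_states * n_cells` rows: `state_index`,
#'   `Kb` plus the [cell_shape_metrics()] columns.
#' @export
trajectory_cell_metrics <- function(traj) {
  rows <- lapply(seq_along(traj$states), function(k) {
    cbind(state_index = k, Kb = traj$kb_values[k],
          cell_shape_metrics(traj$states[[k]], traj$geom))
  })
  do.call(rbind, rows)
}
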