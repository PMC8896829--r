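# Synthetic embryo cross-section: a ring of wedge cells between the vitelline
# shell (apical side) and the yolk (basal side). All lengths in micrometres.

#' Geometry parameters for the embryo cross-section
#'
#' Defines the synthetic initial geometry of the model: a ring of `n_cells`
#' congruent wedge-shaped cells spanning the gap between an outer circle of
#' radius `vitelline_radius` (the rigid eggshell, where the apical surfaces
#' sit) and an inner circle of radius `vitelline_radius - cell_length` (the
#' yolk boundary, where the basal surfaces sit).
#'
#' The physical dimensions correspond to a cellularization-stage
#' \emph{Drosophila} embryo cross-section: shell radius about 90 um and
#' apicobasal cell length about 35 um.
#'
#' @param n_cells Even integer number of cells in the ring (>= 8).
#' @param vitelline_radius Radius of the vitelline shell, um.
#' @param cell_length Initial apicobasal cell length, um; must be smaller
#'   than `vitelline_radius` so a yolk region remains.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(n_cells = 80L, vitelline_radius = 90,
                            cell_length = 35) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 8L || n_cells %% 2L != 0L)
    stop("n_cells must be an even integer >= 8")
  if (!is.finite(vitelline_radius) || vitelline_radius <= 0)
    stop("vitelline_radius must be positive")
  if (!is.finite(cell_length) || cell_length <= 0 ||
      cell_length >= vitelline_radius)
    stop("cell_length must lie in (0, vitelline_radius): degenerate yolk")
  structure(list(n_cells = n_cells, vitelline_radius = vitelline_radius,
                 cell_length = cell_length),
            class = "geometry_params")
}

#' Build the initial embryo geometry
#'
#' Places `n_cells` apical vertices on the vitelline circle and `n_cells`
#' basal vertices on the concentric yolk circle, at equally spaced angles.
#' The ventral midline points along the negative y axis and coincides with
#' the lateral edge between the last and the first cell; cells are numbered
#' counter-clockwise from that boundary. Rest lengths and rest areas are set
#' to the constructed values, so the initial configuration is the exact
#' zero-energy state of the unloaded elastic system.
#'
#' Cell `i` is the quadrilateral (apical i, apical i+1, basal i+1, basal i)
#' (indices wrap around the ring); lateral edge `i` joins apical and basal
#' vertex `i` and is shared by cells `i - 1` and `i`, stored once.
#'
#' @param p A [geometry_params()] object.
#' @return An object of class `embryo_geometry` with vertex coordinates,
#'   rest quantities and the ring topology.
#' @export
build_initial_geometry <- function(p = geometry_params()) {
  stopifnot(inherits(p, "geometry_params"))
  n <- p$n_cells
  R <- p$vitelline_radius
  r <- R - p$cell_length
  theta <- -pi / 2 + 2 * pi * (seq_len(n) - 1L) / n
  apical <- cbind(R * cos(theta), R * sin(theta))
  basal <- cbind(r * cos(theta), r * sin(theta))
  geom <- structure(list(
    n_cells = n,
    apical = apical,
    basal = basal,
    vitelline_radius = R,
    cell_length = p$cell_length,
    params = p
  ), class = "embryo_geometry")
  conf <- as_configuration(geom)
  geom$rest_apical <- edge_lengths(conf, "apical")
  geom$rest_basal <- edge_lengths(conf, "basal")
  geom$rest_lateral <- edge_lengths(conf, "lateral")
  geom$rest_area <- cell_areas(conf)
  geom$rest_yolk <- yolk_area(conf)
  geom
}

# Ring index helpers: next / previous position around the ring (1-based).
ring_next <- function(n) c(seq_len(n)[-1L], 1L)
ring_prev <- function(n) c(n, seq_len(n)[-n])

# Vertex/cell index that position i maps to under reflection about the
# ventral midline (the x = 0 axis).
mirror_vertex_index <- function(n) c(1L, rev(seq_len(n)[-1L]))
mirror_cell_index <- function(n) rev(seq_len(n))

#' Mesoderm membership indicator
#'
#' Marks the `half_width` cells on each side of the ventral midline as
#' mesoderm (indicator 1), all other cells as ectoderm (indicator 0). With
#' the defaults (80 cells, half-width 9) this is the 18-cell constriction
#' domain.
#'
#' @param n_cells Number of cells in the ring.
#' @param half_width Number of mesodermal cells on each side of the midline.
#' @return Integer vector of 0/1 of length `n_cells`.
#' @export
mesoderm_mask <- function(n_cells = 80L, half_width = 9L) {
  n_cells <- as.integer(n_cells); half_width <- as.integer(half_width)
  if (2L * half_width >= n_cells)
    stop("2 * half_width must be smaller than n_cells")
  phi <- integer(n_cells)
  phi[seq_len(half_width)] <- 1L
  phi[n_cells - seq_len(half_width) + 1L] <- 1L
  phi
}

# Circular offset of each cell centre from the ventral midline, in cell
# widths. The midline falls on the boundary between the two cells that flank
# it, so offsets are half-integers (0.5, 1.5, ...).
cell_midline_offsets <- function(n_cells) {
  d <- seq_len(n_cells) - 0.5
  pmin(d, n_cells - d)
}

#' Gaussian apical contractility profile
#'
#' Per-cell contractility weights \eqn{\phi_i \mu_i} with
#' \eqn{\mu_i = \mu_0 \exp(-d_i^2 / (2\sigma^2))}, where \eqn{d_i} is the
#' offset of cell i from the ventral midline in cell widths. The profile
#' peaks at the midline and is zero outside the mesoderm, so only mesodermal
#' cells constrict apically. Because the cell count is even, the Gaussian is
#' centred on the boundary between the two midline-adjacent cells and the
#' offsets are half-integers, which keeps the profile mirror-symmetric.
#'
#' @param mu0 Contractility amplitude (>= 0).
#' @param sigma Width of the Gaussian, in cell widths (> 0).
#' @param phi Mesoderm indicator, as from [mesoderm_mask()].
#' @return Numeric vector of per-cell weights, same length as `phi`.
#' @export
contractility_profile <- function(mu0 = 5000, sigma = 3, phi = mesoderm_mask()) {
  if (!is.finite(mu0) || mu0 < 0) stop("mu0 must be >= 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  d <- cell_midline_offsets(length(phi))
  as.numeric(phi) * mu0 * exp(-d^2 / (2 * sigma^2))
}

#' Tissue annotation: mesoderm domain and contractility weights
#'
#' Bundles the mesoderm indicator, the Gaussian contractility weights, and
#' the classification of lateral edges. A lateral edge is mesodermal when at
#' least one of its two adjoining cells is mesodermal, so the two
#' mesoderm--ectoderm boundary edges count as mesodermal (they belong to the
#' constriction domain for the lateral force terms).
#'
#' @param n_cells Number of cells in the ring.
#' @param half_width Mesodermal cells on each side of the midline.
#' @param mu0,sigma Contractility amplitude and Gaussian width, see
#'   [contractility_profile()].
#' @param phi_override Optional explicit 0/1 indicator replacing the
#'   contiguous mesoderm mask inside the contractility weights (used for
#'   uncoordinated-constriction experiments); the mesodermal edge
#'   classification still follows the contiguous domain.
#' @return An object of class `tissue_annotation` with fields `phi`, `mu`,
#'   `mesoderm`, `ectoderm_indices`, `meso_lateral`.
#' @export
tissue_annotation <- function(n_cells = 80L, half_width = 9L, mu0 = 5000,
                              sigma = 3, phi_override = NULL) {
  phi_domain <- mesoderm_mask(n_cells, half_width)
  phi <- if (is.null(phi_override)) phi_domain else {
    stopifnot(length(phi_override) == n_cells, all(phi_override %in% c(0L, 1L)))
    if (any(phi_override == 1L & phi_domain == 0L))
      stop("phi_override may only activate cells inside the mesoderm domain")
    as.integer(phi_override)
  }
  mu <- contractility_profile(mu0, sigma, phi)
  prev <- ring_prev(n_cells)
  meso_lateral <- phi_domain == 1L | phi_domain[prev] == 1L
  structure(list(
    phi = phi,
    mu = mu,
    mesoderm = which(phi_domain == 1L),
    ectoderm_indices = which(phi_domain == 0L),
    meso_lateral = meso_lateral,
    half_width = as.integer(half_width),
    mu0 = mu0,
    sigma = sigma
  ), class = "tissue_annotation")
}

#' Relative disc-closure error of a configuration
#'
#' The cell quadrilaterals and the basal (yolk) polygon tile the region
#' enclosed by the apical polygon exactly, so the sum of all cell areas plus
#' the yolk area must equal the apical-polygon area. Returns the relative
#' mismatch of this telescoping identity (zero up to floating-point error).
#'
#' @param conf A configuration, see [as_configuration()].
#' @return Relative closure error (dimensionless).
#' @export
disc_closure_error <- function(conf) {
  total <- sum(cell_areas(conf)) + yolk_area(conf)
  outer <- polygon_area(conf$apical)
  abs(total - outer) / outer
}
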