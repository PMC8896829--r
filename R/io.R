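# Configuration files, trajectory serialization and summary figures.
# Configs are YAML (or JSON); trajectories are JSON archives with doubles
# written at 17 significant digits so arrays round-trip bit-exactly.

TRAJECTORY_FORMAT_VERSION <- "furrowsim-trajectory-1"

config_defaults <- function() {
  list(
    geometry = list(n_cells = 80L, vitelline_radius = 90, cell_length = 35),
    model = as.list(model_params())[
      c("Ka", "Kl", "Kb", "mu0", "sigma", "Kv", "KY", "KL_active",
        "KL_passive", "deltaL", "half_width", "boundary_lateral",
        "shorten_cells")],
    schedule = default_kb_schedule(),
    solver = list(tol = NA_real_, max_iter = 20000L, symmetrize = TRUE),
    output_dir = ".",
    log_level = "info"
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration and merges it over the defaults: the
#' printed parameter-table values for the model, the standard geometry and
#' the default basal-stiffness schedule. Unknown keys raise an error listing
#' every offending key, so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML/JSON file; an empty file yields the defaults.
#' @return A validated `run_config` list with elements `geometry`, `model`,
#'   `schedule`, `solver`, `output_dir`, `log_level`, plus realized
#'   `geometry_params` and `model_params` objects under `objects`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Validate and complete a configuration list
#'
#' @param raw A (possibly partial) configuration list.
#' @return A completed `run_config`; errors name every unknown or invalid
#'   key.
#' @export
validate_config <- function(raw = list()) {
  defaults <- config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (sec in names(raw)) {
    if (sec %in% c("geometry", "model", "solver")) {
      sub_bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
      if (length(sub_bad))
        stop("unknown config keys: ",
             paste(paste0(sec, ".", sub_bad), collapse = ", "))
      cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  gp <- do.call(geometry_params, cfg$geometry)
  mp <- do.call(model_params, cfg$model)
  if (any(diff(cfg$schedule) >= 0) || any(cfg$schedule <= 0))
    stop("invalid config key: schedule (must be strictly decreasing, > 0)")
  cfg$objects <- list(geometry = gp, model = mp)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' @param cfg A `run_config` (or partial configuration list).
#' @param path Destination YAML file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg$objects <- NULL
  class(cfg) <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

state_to_list <- function(st) {
  list(apical = st$configuration$apical, basal = st$configuration$basal,
       Kb_value = st$Kb_value, converged = st$converged,
       grad_norm = st$grad_norm, n_iter = st$n_iter, energy = st$energy,
       energy_trace = st$energy_trace)
}

state_from_list <- function(x) {
  conf <- structure(list(apical = do.call(rbind, lapply(x$apical, unlist)),
                         basal = do.call(rbind, lapply(x$basal, unlist))),
                    class = "vf_configuration")
  structure(list(configuration = conf, Kb_value = x$Kb_value,
                 converged = x$converged, grad_norm = x$grad_norm,
                 n_iter = x$n_iter, energy = x$energy,
                 energy_trace = unlist(x$energy_trace)),
            class = "equilibrium_state")
}

#' Write a trajectory archive
#'
#' Serializes a trajectory (per-state vertex arrays, basal stiffness,
#' energies, convergence metadata, parameters and geometry) to a JSON
#' archive. Doubles are written with 17 significant digits, so vertex
#' arrays survive a write/read cycle bit-for-bit.
#'
#' @param traj A `trajectory`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  payload <- list(
    format = TRAJECTORY_FORMAT_VERSION,
    geometry = list(
      n_cells = traj$geom$n_cells,
      vitelline_radius = traj$geom$vitelline_radius,
      cell_length = traj$geom$cell_length
    ),
    params = traj$params[!vapply(traj$params, is.null, logical(1))],
    kb_values = traj$kb_values,
    schedule = traj$schedule,
    perturbation = if (is.null(traj$perturbation)) NULL else list(
      from_index = traj$perturbation$from_index,
      params = traj$perturbation$params[
        !vapply(traj$perturbation$params, is.null, logical(1))]
    ),
    states = lapply(traj$states, state_to_list)
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

params_from_list <- function(x) do.call(model_params, x)

#' Read a trajectory archive
#'
#' @param path A file written by [write_trajectory()].
#' @return The reconstructed `trajectory`.
#' @export
read_trajectory <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("corrupt trajectory archive: ",
                                               conditionMessage(e)))
  if (is.null(payload$format) || payload$format != TRAJECTORY_FORMAT_VERSION)
    stop("trajectory archive version mismatch: expected ",
         TRAJECTORY_FORMAT_VERSION, ", found ",
         if (is.null(payload$format)) "<none>" else payload$format)
  gp <- geometry_params(payload$geometry$n_cells,
                        payload$geometry$vitelline_radius,
                        payload$geometry$cell_length)
  geom <- build_initial_geometry(gp)
  p <- params_from_list(payload$params)
  ann <- annotation_from_params(geom$n_cells, p)
  structure(list(
    states = lapply(payload$states, state_from_list),
    kb_values = unlist(payload$kb_values),
    schedule = unlist(payload$schedule),
    params = p, geom = geom, ann = ann,
    perturbation = if (is.null(payload$perturbation)) NULL else list(
      from_index = payload$perturbation$from_index,
      params = params_from_list(payload$perturbation$params))
  ), class = "trajectory")
}

draw_cross_section <- function(st, geom, main = "") {
  conf <- st$configuration
  n <- geom$n_cells; nx <- ring_next(n)
  R <- geom$vitelline_radius
  plot(NA, xlim = c(-R, R) * 1.05, ylim = c(-R, R) * 1.05, asp = 1,
       xlab = "x (um)", ylab = "y (um)", main = main)
  tt <- seq(0, 2 * pi, length.out = 361)
  lines(R * cos(tt), R * sin(tt), col = "grey50", lty = 2)
  for (i in seq_len(n)) {
    xs <- c(conf$apical[i, 1], conf$apical[nx[i], 1],
            conf$basal[nx[i], 1], conf$basal[i, 1])
    ys <- c(conf$apical[i, 2], conf$apical[nx[i], 2],
            conf$basal[nx[i], 2], conf$basal[i, 2])
    polygon(xs, ys, border = "grey20", col = "grey90", lwd = 0.5)
  }
}

#' Render summary figures for an experiment result
#'
#' Writes two deterministic PNG panels: the final cross-section polygons and
#' the invagination depth across the schedule states. Plot failures are
#' reported as warnings, never as errors.
#'
#' @param result An `experiment_result` (or a bare `trajectory`).
#' @param path Base path; `_section.png` and `_depth.png` are appended.
#' @return Character vector of the files written, invisibly.
#' @export
render_summary <- function(result, path) {
  traj <- if (inherits(result, "trajectory")) result else result$trajectory
  geom <- traj$geom
  files <- paste0(path, c("_section.png", "_depth.png"))
  ok <- tryCatch({
    grDevices::png(files[1], width = 600, height = 600)
    draw_cross_section(traj$states[[length(traj$states)]], geom,
                       main = "final cross-section")
    grDevices::dev.off()
    D <- vapply(traj$states, invagination_depth, numeric(1), geom = geom)
    grDevices::png(files[2], width = 600, height = 400)
    plot(seq_along(D), D, type = "b", pch = 19,
         xlab = "schedule state", ylab = "invagination depth D (um)")
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warning("summary rendering failed: ", conditionMessage(e))
    FALSE
  })
  invisible(if (ok) files else character(0))
}

#' Write the per-state and per-cell metrics tables of a trajectory
#'
#' @param traj A `trajectory`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Paths of the two CSV files written, invisibly.
#' @export
write_metrics_csv <- function(traj, dir, prefix = "trajectory") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tissue <- file.path(dir, paste0(prefix, "_tissue_metrics.csv"))
  cells <- file.path(dir, paste0(prefix, "_cell_metrics.csv"))
  utils::write.csv(trajectory_metrics(traj), tissue, row.names = FALSE)
  utils::write.csv(trajectory_cell_metrics(traj), cells, row.names = FALSE)
  invisible(c(tissue, cells))
}
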