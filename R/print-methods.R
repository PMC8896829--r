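#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf("Embryo cross-section: %d cells, shell radius %.4g um, cell length %.4g um\n",
              x$n_cells, x$vitelline_radius, x$cell_length))
  invisible(x)
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat(sprintf("Embryo geometry: %d cells (%d vertices), shell radius %.4g um\n",
              x$n_cells, 2L * x$n_cells, x$vitelline_radius))
  cat(sprintf("  rest lengths a0 = %.3f, b0 = %.3f, l0 = %.3f um; V0 = %.2f um^2\n",
              x$rest_apical[1], x$rest_basal[1], x$rest_lateral[1],
              x$rest_area[1]))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Vertex-model parameters:\n")
  cat(sprintf("  Ka = %g, Kl = %g, Kb = %g, Kv = %g, KY = %g\n",
              x$Ka, x$Kl, x$Kb, x$Kv, x$KY))
  cat(sprintf("  contractility mu0 = %g, sigma = %g (mesoderm half-width %d)\n",
              x$mu0, x$sigma, x$half_width))
  cat(sprintf("  lateral KL_active = %g, KL_passive = %g; ectoderm deltaL = %g\n",
              x$KL_active, x$KL_passive, x$deltaL))
  invisible(x)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("Equilibrium state at Kb = %g: E = %.6g, |pg| = %.3g, %s (%d iteration units)\n",
              x$Kb_value, x$energy, x$grad_norm,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Quasi-static trajectory: %d states, Kb %g -> %g%s\n",
              length(x$states), x$kb_values[1],
              x$kb_values[length(x$kb_values)],
              if (is.null(x$perturbation)) "" else
                sprintf(" (perturbed from state %d)",
                        x$perturbation$from_index)))
  D <- vapply(x$states, invagination_depth, numeric(1), geom = x$geom)
  cat(sprintf("  invagination depth: %.2f -> %.2f um; all converged: %s\n",
              D[1], D[length(D)],
              all(vapply(x$states, `[[`, logical(1), "converged"))))
  invisible(x)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment (%s): response = %s, D_final = %.2f um",
              x$spec$kind, x$response, x$D_final))
  if (is.finite(x$D_ref)) cat(sprintf(" (reference %.2f um)", x$D_ref))
  cat("\n")
  invisible(x)
}
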