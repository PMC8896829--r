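# Shared fixtures. Heavy trajectories are computed lazily and cached for the
# whole test run, so every test file sees the same equilibria without
# recomputing them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_geom <- function() fixture("geom", build_initial_geometry())

# Unperturbed compressed run with the printed defaults (deltaL = 0.2,
# KL_active = 2, KL_passive = 20).
baseline_trajectory <- function() {
  fixture("baseline", run_schedule(default_geom(), p = model_params()))
}

# Inhibition scan over every schedule state of the baseline run.
baseline_transition <- function() {
  fixture("baseline_transition",
          find_transition(baseline_trajectory(), max_iter = 120000L))
}

# Uncompressed control (deltaL = 0). The scan budget is capped: an
# under-resolved relaxation cascade can only overestimate the residual
# depth, so every "relaxed" call obtained under the cap is conservative.
nocompression_trajectory <- function() {
  fixture("nocompression",
          run_schedule(default_geom(), p = model_params(deltaL = 0)))
}

nocompression_transition <- function() {
  fixture("nocompression_transition",
          find_transition(nocompression_trajectory(), max_iter = 40000L))
}

# Short unloaded schedule (no contractility, no compression).
unloaded_trajectory <- function() {
  fixture("unloaded_traj",
          run_schedule(default_geom(),
                       p = model_params(mu0 = 0, deltaL = 0, KL_active = 0),
                       schedule = c(4, 2, 1)))
}

# Two-state compressed run used by the serialization tests.
tiny_trajectory <- function() {
  fixture("tiny_traj",
          run_schedule(default_geom(),
                       p = model_params(mu0 = 500, deltaL = 0.05),
                       schedule = c(1024, 512)))
}

# Random feasible configurations near the rest state, for property tests.
random_configuration <- function(geom, scale = 0.2) {
  conf <- as_configuration(geom)
  n <- geom$n_cells
  conf$apical <- conf$apical * (1 - scale / geom$vitelline_radius) +
    matrix(stats::rnorm(2 * n, 0, scale), n, 2)
  conf$basal <- conf$basal + matrix(stats::rnorm(2 * n, 0, scale), n, 2)
  conf
}

# A fabricated equilibrium state whose apical midline vertex sits at a
# chosen depth below the shell (for classification-rule tests).
state_with_depth <- function(geom, depth) {
  conf <- as_configuration(geom)
  r <- geom$vitelline_radius - depth
  conf$apical[1, ] <- c(0, -r)
  structure(list(configuration = conf, Kb_value = 1, converged = TRUE,
                 grad_norm = 0, n_iter = 0L, energy = 0,
                 energy_trace = numeric(0)),
            class = "equilibrium_state")
}
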