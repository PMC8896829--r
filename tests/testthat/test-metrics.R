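test_that("invagination depth is zero on the rest state and tracks the apex", {
  geom <- default_geom()
  expect_equal(invagination_depth(as_configuration(geom), geom), 0)
  expect_equal(invagination_depth(state_with_depth(geom, 25), geom), 25)
})

test_that("rest-state cell shape metrics are radial wedges", {
  geom <- default_geom()
  m <- cell_shape_metrics(as_configuration(geom), geom)
  expect_equal(nrow(m), 80L)
  expect_equal(m$apical, geom$rest_apical)
  expect_equal(m$basal, geom$rest_basal)
  expect_equal(m$lateral, geom$rest_lateral)
  expect_equal(m$area, geom$rest_area)
  expect_lt(max(m$tilt), 1e-6)
})

test_that("sector areas are symmetric at rest and tile the cell layer", {
  geom <- default_geom()
  conf <- as_configuration(geom)
  left <- ectoderm_sector_area(conf, geom, c(60, 90), "left")
  right <- ectoderm_sector_area(conf, geom, c(60, 90), "right")
  expect_equal(left, right)
  # partition closure: windows tiling (0, 180] on both sides recover the
  # whole cell-layer area
  windows <- list(c(0, 45), c(45, 60), c(60, 90), c(90, 120), c(120, 180))
  total <- 0
  for (w in windows) for (s in c("left", "right"))
    total <- total + ectoderm_sector_area(conf, geom, w, s)
  expect_lt(abs(total - sum(cell_areas(conf))) / total, 1e-9)
  expect_error(ectoderm_sector_area(conf, geom, c(90, 60), "left"),
               "increasing")
})

test_that("constriction counting is monotone in its threshold", {
  traj <- baseline_trajectory()
  n_strict <- count_constricting_cells(traj, 0.4)
  n_mid <- count_constricting_cells(traj, 0.5)
  n_loose <- count_constricting_cells(traj, 1.0)
  expect_true(n_strict <= n_mid && n_mid <= n_loose)
  expect_gte(n_loose, n_mid)
})

test_that("no cell constricts without contractility", {
  traj <- unloaded_trajectory()
  expect_equal(count_constricting_cells(traj), 0L)
})

test_that("baseline equilibria keep cell areas within the soft-penalty band", {
  traj <- baseline_trajectory()
  m <- trajectory_metrics(traj)
  expect_true(all(m$converged))
  expect_true(all(m$max_area_dev <= 0.05))
  expect_true(all(m$D >= 0))
  expect_equal(m$Kb, 2^(10:0))
})

test_that("mirror-symmetric parameters give mirror-symmetric cell metrics", {
  traj <- baseline_trajectory()
  final <- traj$states[[length(traj$states)]]
  m <- cell_shape_metrics(final, traj$geom)
  mirror <- rev(seq_len(80L))
  for (col in c("apical", "basal", "lateral", "area")) {
    expect_lt(max(abs(m[[col]] - m[[col]][mirror])), 1e-4)
  }
})

test_that("the most constricted apex lies inside the mesoderm domain", {
  traj <- baseline_trajectory()
  final <- traj$states[[length(traj$states)]]
  m <- cell_shape_metrics(final, traj$geom)
  ann <- traj$ann
  expect_true(which.min(m$apical) %in% ann$mesoderm)
})

test_that("per-state and per-cell metric tables have the bookkeeping shape", {
  traj <- baseline_trajectory()
  tm <- trajectory_metrics(traj)
  cm <- trajectory_cell_metrics(traj)
  expect_equal(nrow(tm), length(traj$states))
  expect_equal(nrow(cm), length(traj$states) * 80L)
})
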