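test_that("initial geometry is a ring of congruent wedges inside the shell", {
  geom <- default_geom()
  expect_equal(geom$n_cells, 80L)
  expect_equal(nrow(geom$apical) + nrow(geom$basal), 160L)
  # 4.5 degree wedges: equal angular spacing of the lateral edges
  th <- atan2(geom$apical[, 2], geom$apical[, 1])
  dth <- diff(sort(th))
  expect_equal(dth, rep(2 * pi / 80, 79), tolerance = 1e-12)
  # all vertices on or inside the shell
  r <- sqrt(rowSums(rbind(geom$apical, geom$basal)^2))
  expect_true(all(r <= geom$vitelline_radius + 1e-12))
  # equal wedges: rest quantities have negligible relative spread
  for (q in list(geom$rest_apical, geom$rest_basal, geom$rest_lateral,
                 geom$rest_area)) {
    expect_lt(diff(range(q)) / mean(q), 1e-10)
  }
})

test_that("cells and yolk tile the enclosed cross-section exactly", {
  for (p in list(geometry_params(), geometry_params(8L, 10, 4),
                 geometry_params(24L, 50, 20))) {
    geom <- build_initial_geometry(p)
    expect_lt(disc_closure_error(as_configuration(geom)), 1e-10)
  }
})

test_that("initial geometry is mirror-symmetric about the ventral midline", {
  geom <- build_initial_geometry(geometry_params(24L, 50, 20))
  idx <- furrowsim:::mirror_vertex_index(24L)
  for (P in list(geom$apical, geom$basal)) {
    Q <- P[idx, ]
    Q[, 1] <- -Q[, 1]
    expect_equal(Q, P, tolerance = 1e-12)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(geometry_params(cell_length = 90), "degenerate yolk")
  expect_error(geometry_params(cell_length = 95), "degenerate yolk")
  expect_error(geometry_params(n_cells = 7L), "even")
  expect_error(geometry_params(n_cells = 6L), "even")
})

test_that("mesoderm mask marks half_width cells on each side of the midline", {
  phi <- mesoderm_mask(80L, 9L)
  expect_equal(sum(phi), 18L)
  expect_equal(which(phi == 1L), c(1:9, 72:80))
  # dorsal-most cells are ectodermal
  expect_equal(phi[40:41], c(0L, 0L))
  # minimal case: only the two midline-flanking cells
  expect_equal(which(mesoderm_mask(8L, 1L) == 1L), c(1L, 8L))
  expect_error(mesoderm_mask(8L, 4L), "smaller")
})

test_that("contractility profile is a midline-centred Gaussian on the mesoderm", {
  phi <- mesoderm_mask(80L, 9L)
  mu <- contractility_profile(5000, 3, phi)
  # closed form at the half-integer offsets
  expect_equal(mu[1], 5000 * exp(-0.5^2 / (2 * 9)))
  expect_equal(mu[5], 5000 * exp(-4.5^2 / (2 * 9)))
  expect_equal(mu[which(phi == 0L)], rep(0, 62))
  expect_equal(mu, mu[rev(seq_along(mu))])  # mirror symmetry
  expect_true(all(diff(mu[1:9]) < 0))       # maximal next to the midline
  expect_equal(contractility_profile(0, 3, phi), rep(0, 80))
})

test_that("annotation classifies boundary lateral edges as mesodermal", {
  ann <- tissue_annotation(80L)
  expect_equal(sum(ann$meso_lateral), 19L)  # 17 interior + 2 boundary edges
  expect_equal(length(ann$ectoderm_indices), 62L)
  expect_true(all(ann$mu[ann$phi == 0L] == 0))
})
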