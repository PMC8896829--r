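test_that("rest configuration of the unloaded system has zero energy and gradient", {
  geom <- default_geom()
  conf <- as_configuration(geom)
  p0 <- model_params(mu0 = 0, deltaL = 0, KL_active = 0)
  expect_equal(total_energy(conf, geom, p = p0), 0)
  g <- energy_gradient(conf, geom, p = p0)
  expect_lt(max(abs(rbind(g$apical, g$basal))), 1e-9)
})

test_that("energy at the unrelaxed rest state matches direct term-by-term substitution", {
  geom <- default_geom()
  conf <- as_configuration(geom)
  ann <- tissue_annotation(80L)
  a0 <- geom$rest_apical
  l0 <- geom$rest_lateral

  # contractility only (no compression, no active springs): sum of the 18
  # Gaussian weights times a0^2
  p <- model_params(deltaL = 0, KL_active = 0)
  expect_equal(total_energy(conf, geom, p = p),
               sum(ann$phi * ann$mu * a0^2))

  # deltaL = 0.2 at the unrelaxed rest state: the 61 ectodermal lateral
  # springs are stretched by exactly 0.2 * l0
  p <- model_params(deltaL = 0.2, mu0 = 0, KL_active = 0)
  bd <- energy_breakdown(conf, geom, p = p)
  n_ecto_edges <- sum(!ann$meso_lateral)
  expect_equal(n_ecto_edges, 61L)
  expect_equal(bd[["lateral_passive"]],
               20 * n_ecto_edges * (0.2 * l0[1])^2)
  expect_equal(sum(bd) - bd[["lateral_passive"]], 0)

  # active zero-rest-length springs on the 19 constriction-domain edges
  p <- model_params(deltaL = 0, mu0 = 0, KL_active = 2)
  bd <- energy_breakdown(conf, geom, p = p)
  expect_equal(bd[["lateral_active"]], 2 * 19 * l0[1]^2)
})

test_that("elastic terms are quadratic in the deviation", {
  geom <- default_geom()
  conf <- as_configuration(geom)
  # lateral passive energy at the rest state scales as deltaL^2
  e <- vapply(c(0.1, 0.2, 0.4), function(dL) {
    energy_breakdown(conf, geom,
                     p = model_params(deltaL = dL, mu0 = 0,
                                      KL_active = 0))[["lateral_passive"]]
  }, numeric(1))
  expect_equal(e[2] / e[1], 4, tolerance = 1e-12)
  expect_equal(e[3] / e[2], 4, tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences on random states", {
  geom <- default_geom()
  set.seed(42)
  p <- model_params()
  ann <- annotation_from_params(80L, p)
  h <- 1e-5
  n_states <- 110L
  worst <- 0
  for (rep in seq_len(n_states)) {
    conf <- random_configuration(geom, scale = 0.3)
    g <- energy_gradient(conf, geom, ann, p)
    G <- rbind(g$apical, g$basal)
    gmax <- max(abs(G))
    # probe a few random coordinates per state
    for (probe in seq_len(4L)) {
      i <- sample.int(160L, 1L)
      j <- sample.int(2L, 1L)
      cp <- conf; cm <- conf
      if (i <= 80L) {
        cp$apical[i, j] <- cp$apical[i, j] + h
        cm$apical[i, j] <- cm$apical[i, j] - h
      } else {
        cp$basal[i - 80L, j] <- cp$basal[i - 80L, j] + h
        cm$basal[i - 80L, j] <- cm$basal[i - 80L, j] - h
      }
      fd <- (total_energy(cp, geom, ann, p) -
               total_energy(cm, geom, ann, p)) / (2 * h)
      worst <- max(worst, abs(fd - G[i, j]) / gmax)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("compiled energy kernel agrees with the reference R implementation", {
  geom <- default_geom()
  set.seed(7)
  for (p in list(model_params(), model_params(mu0 = 0, deltaL = 0.05),
                 model_params(KL_active = 0, KL_passive = 2))) {
    ann <- annotation_from_params(80L, p)
    sys <- furrowsim:::build_system(geom, ann, p)
    conf <- random_configuration(geom, scale = 0.5)
    rr <- furrowsim:::vf_energy_grad(conf$apical, conf$basal, sys)
    cc <- .energy_grad_cpp(conf$apical, conf$basal, sys)
    expect_equal(cc$E, rr$E)
    expect_equal(cc$terms, rr$terms)
    expect_equal(unname(cc$gA), unname(rr$gA))
    expect_equal(unname(cc$gB), unname(rr$gB))
  }
})

test_that("energy is translation invariant and term-wise non-negative", {
  geom <- default_geom()
  set.seed(11)
  p <- model_params()
  ann <- annotation_from_params(80L, p)
  for (rep in 1:5) {
    conf <- random_configuration(geom, scale = 0.4)
    shifted <- conf
    shift <- stats::rnorm(2, 0, 5)
    shifted$apical <- sweep(conf$apical, 2, shift, "+")
    shifted$basal <- sweep(conf$basal, 2, shift, "+")
    e1 <- total_energy(conf, geom, ann, p)
    e2 <- total_energy(shifted, geom, ann, p)
    expect_lt(abs(e1 - e2) / max(1, abs(e1)), 1e-9)
    expect_true(all(energy_breakdown(conf, geom, ann, p) >= 0))
  }
})

test_that("energy breakdown sums to the total energy", {
  geom <- default_geom()
  set.seed(3)
  p <- model_params()
  conf <- random_configuration(geom)
  bd <- energy_breakdown(conf, geom, p = p)
  tot <- total_energy(conf, geom, p = p)
  expect_lt(abs(sum(bd) - tot) / max(1, abs(tot)), 1e-9)
})

test_that("rest-state energy is non-decreasing in the shortening fraction", {
  geom <- default_geom()
  conf <- as_configuration(geom)
  e <- vapply(seq(0, 0.5, by = 0.05), function(dL) {
    total_energy(conf, geom, p = model_params(deltaL = dL))
  }, numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("non-finite coordinates are rejected", {
  geom <- default_geom()
  conf <- as_configuration(geom)
  conf$apical[3, 1] <- NaN
  expect_error(total_energy(conf, geom, p = model_params()), "finite")
})

test_that("ectodermal shortening rescales exactly the targeted rest lengths", {
  geom <- default_geom()
  ann <- tissue_annotation(80L)
  g0 <- apply_ectoderm_shortening(geom, 0, ann)
  expect_equal(g0$rest_lateral, geom$rest_lateral)
  g2 <- apply_ectoderm_shortening(geom, 0.2, ann)
  ect <- !ann$meso_lateral
  expect_equal(g2$rest_lateral[ect], 0.8 * geom$rest_lateral[ect])
  expect_equal(g2$rest_lateral[!ect], geom$rest_lateral[!ect])
  expect_equal(g2$rest_apical, geom$rest_apical)
  expect_equal(g2$rest_area, geom$rest_area)
  g5 <- apply_ectoderm_shortening(geom, 0.05, ann)
  expect_equal(g5$rest_lateral[ect], 0.95 * geom$rest_lateral[ect])
  expect_error(apply_ectoderm_shortening(geom, 0.2, ann, targets = c(1L, 20L)),
               "mesodermal")
})

test_that("the printed lateral force law evaluates by direct substitution", {
  expect_equal(lateral_shortening_force(10, 8, 2, 20), 60)
  expect_equal(lateral_shortening_force(8, 8, 0, 20), 0)
  expect_equal(lateral_shortening_force(8, 8, 2, 20), 16)
})

test_that("parameter validation names the offending constants", {
  expect_error(model_params(Ka = -1), "Ka")
  expect_error(model_params(deltaL = 1), "deltaL")
  expect_error(model_params(sigma = 0), "sigma")
})
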