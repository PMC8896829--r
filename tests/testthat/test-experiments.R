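test_that("response classification follows the depth-fraction rule", {
  geom <- default_geom()
  ref <- state_with_depth(geom, 61)
  init <- state_with_depth(geom, 0)
  expect_equal(classify_response(state_with_depth(geom, 0), init, ref, geom),
               "relaxed")
  expect_equal(classify_response(state_with_depth(geom, 61), init, ref, geom),
               "invaginated")
  expect_equal(classify_response(state_with_depth(geom, 30.5), init, ref,
                                 geom), "paused")
  expect_error(classify_response(state_with_depth(geom, 10), init, init,
                                 geom), "D_ref")
})

test_that("early inhibition relaxes, late inhibition stays invaginated", {
  tr <- baseline_transition()
  expect_equal(tr$responses[1], "relaxed")
  expect_equal(tr$responses[length(tr$responses)], "invaginated")
  expect_false(is.na(tr$k_star))
  base <- baseline_trajectory()
  D_ref <- invagination_depth(base$states[[length(base$states)]], base$geom)
  expect_lt(tr$D_final[1], 0.2 * D_ref)
  expect_gt(tr$D_final[length(tr$D_final)], 0.8 * D_ref)
})

test_that("the transition index is insensitive to the classification thresholds", {
  tr <- baseline_transition()
  base <- baseline_trajectory()
  D_ref <- invagination_depth(base$states[[length(base$states)]], base$geom)
  for (hi in c(0.75, 0.8, 0.85)) {
    k_star_thr <- tr$ks[min(which(tr$D_final > hi * D_ref))]
    expect_equal(k_star_thr, tr$k_star)
  }
  # relaxed calls are equally stable over the low threshold band
  for (lo in c(0.15, 0.2, 0.25)) {
    relaxed_thr <- tr$D_final < lo * D_ref
    expect_equal(relaxed_thr, tr$responses == "relaxed")
  }
})

test_that("bisection locates the same transition as the full scan", {
  base <- baseline_trajectory()
  tr_scan <- baseline_transition()
  tr_bis <- find_transition(base, method = "bisect", max_iter = 200000L)
  expect_equal(tr_bis$k_star, tr_scan$k_star)
})

test_that("inhibition requires a converged base state and a valid index", {
  base <- baseline_trajectory()
  expect_error(inhibit_at_state(base, 0), "out of range")
  expect_error(inhibit_at_state(base, 99), "out of range")
  broken <- base
  broken$states[[2]]$converged <- FALSE
  expect_error(inhibit_at_state(broken, 2), "not converged")
})

test_that("an unchanged Gaussian width reproduces the baseline run", {
  res <- perturb_constriction("narrow_sigma", with_compression = TRUE,
                              geom = default_geom(), sigma_narrow = 3)
  base <- baseline_trajectory()
  D_base <- invagination_depth(base$states[[length(base$states)]],
                               base$geom)
  expect_equal(res$D_final, D_base, tolerance = 1e-6)
})

test_that("alternating-cell inhibition activates 9 of the 18 mesodermal cells", {
  p <- model_params()
  n <- 80L
  domain <- c((n - p$half_width + 1L):n, seq_len(p$half_width))
  phi <- integer(n)
  phi[domain[seq(1L, length(domain), by = 2L)]] <- 1L
  expect_equal(sum(phi), 9L)
  expect_true(all(which(phi == 1L) %in% c(1:9, 72:80)))
  ann <- tissue_annotation(n, phi_override = phi)
  expect_equal(sum(ann$mu > 0), 9L)
  # overriding outside the mesoderm domain is rejected
  bad <- integer(n); bad[40] <- 1L
  expect_error(tissue_annotation(n, phi_override = bad), "mesoderm domain")
})
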