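test_that("Poisson log-likelihood and KL distance satisfy their identities", {
  m <- array(c(1, 2, 3), c(3, 1, 1))
  # at the MLE xbar = m: L = sum m ln m - sum m
  expect_equal(poisson_loglik(m, m), (0 + 2 * log(2) + 3 * log(3)) - 6)
  expect_equal(kl_distance(m, m), 0)
  # all-zero template: L = -sum(xbar)
  z <- array(0, c(3, 1, 1))
  xb <- array(c(0.5, 1, 2), c(3, 1, 1))
  expect_equal(poisson_loglik(z, xb), -3.5)
  set.seed(21)
  const <- sum(m * log(m)) - sum(m)
  for (i in 1:20) {
    x <- array(runif(3, 0.1, 5), c(3, 1, 1))
    # MLE optimality and Gibbs inequality
    expect_lte(poisson_loglik(m, x), poisson_loglik(m, m))
    expect_gte(kl_distance(m, x), 0)
    # algebraic identity L + KL = sum(m ln m - m)
    expect_lt(abs(poisson_loglik(m, x) + kl_distance(m, x) - const), 1e-9)
  }
  expect_error(poisson_loglik(m, -xb), "nonnegative")
})

test_that("scalar EM fixed point is reached in one iteration", {
  grid <- vox_grid(c(1, 1, 1), 1)
  a <- prob_atlas(grid, array(1, c(1, 1, 1, 1)))
  t1 <- tissue_map(grid, array(1L, c(1, 1, 1)), 1)
  d1 <- density_map(grid, array(1, c(1, 1, 1)))
  op <- system_operator(a, t1, d1, fwhm_mm = 0)
  m <- template_image(grid, array(7, c(1, 1, 1)), 0)
  fit <- osl_mapem(m, op, config = estimation_config(n_iter = 1))
  expect_equal(fit$theta, 7, tolerance = 1e-12)
})

test_that("beta = 0 OSL MAP-EM equals an independent dense MLEM per iteration", {
  sc <- make_block_scene(n = 6, n_regions = 3, n_classes = 2, soft = 2)
  op <- system_operator(sc$atlas, sc$tissues, sc$density, fwhm_mm = 0)
  set.seed(5)
  m <- array(rpois(6^3, 3), c(6, 6, 6))
  M <- dense_basis_matrix(sc$atlas, sc$tissues, sc$density)
  oracle <- dense_mlem_theta(m, M, n_iter = 25)
  for (it in c(1, 5, 25)) {
    fit <- osl_mapem(template_image(sc$grid, m, 0), op,
                     config = estimation_config(beta = 0, n_iter = it,
                                                convergence_tol = 0))
    expect_lt(max(abs(fit$theta - oracle[it, ]) / pmax(oracle[it, ], 1e-300)),
              1e-12)
  }
})

test_that("objective trace is non-decreasing at beta = 0 and counts are preserved", {
  sc <- make_block_scene(n = 8, n_regions = 3, n_classes = 2, soft = 2)
  op <- system_operator(sc$atlas, sc$tissues, sc$density, fwhm_mm = 4)
  set.seed(9)
  true_theta <- runif(op$index$n_params, 0.5, 2)
  m <- array(rpois(8^3, as.vector(op_forward(op, true_theta)) * 20) / 20,
             c(8, 8, 8))
  fit <- osl_mapem(template_image(sc$grid, m, 4), op,
                   config = estimation_config(beta = 0, n_iter = 200,
                                              convergence_tol = 0))
  obj <- fit$trace$objective
  expect_true(all(diff(obj) >= -1e-9 * abs(obj[-1])))
  # EM count preservation with a mass-preserving H
  tot <- sum(op_forward(op, fit$theta))
  expect_equal(tot, sum(m), tolerance = 1e-3)
  # nonnegativity and frozen zeros
  expect_true(all(fit$theta >= 0))
})

test_that("zero-sensitivity parameters stay frozen at exactly zero", {
  sc <- make_block_scene(n = 6, n_regions = 2, n_classes = 2)
  t_all1 <- tissue_map(sc$grid, array(1L, c(6, 6, 6)), 2)  # class 2 empty
  op <- system_operator(sc$atlas, t_all1, sc$density, fwhm_mm = 0)
  set.seed(2)
  m <- array(rpois(6^3, 4), c(6, 6, 6))
  fit <- osl_mapem(template_image(sc$grid, m, 0), op,
                   config = estimation_config(n_iter = 50))
  frozen <- op_sensitivity(op) == 0
  expect_true(any(frozen))
  expect_identical(fit$theta[frozen], rep(0, sum(frozen)))
  expect_true(all(fit$theta[!frozen] > 0))
})

test_that("degenerate inputs are rejected with clear errors", {
  sc <- make_block_scene(n = 4, n_regions = 2, n_classes = 1)
  op <- system_operator(sc$atlas, sc$tissues, sc$density, fwhm_mm = 0)
  z <- template_image(sc$grid, array(0, c(4, 4, 4)), 0)
  expect_error(osl_mapem(z, op), "all-zero template")
  m <- template_image(sc$grid, array(1, c(4, 4, 4)), 0)
  expect_error(osl_mapem(m, op, NULL, estimation_config(beta = 1)),
               "weights are required")
})

test_that("map_objective reduces to the log-likelihood when beta = 0 or theta constant", {
  sc <- make_block_scene(n = 6, n_regions = 3, n_classes = 1, soft = 2)
  op <- system_operator(sc$atlas, sc$tissues, sc$density, fwhm_mm = 0)
  w <- compute_weights(compute_centroids(sc$atlas, sc$tissues, sc$density,
                                         op$index), op$index)
  m <- array(1, c(6, 6, 6))
  th <- runif(3, 0.5, 2)
  expect_equal(map_objective(m, op, w, 0, th),
               poisson_loglik(m, op_forward(op, th)))
  thc <- rep(1.3, 3)
  expect_equal(map_objective(m, op, w, 1000, thc),
               map_objective(m, op, w, 0, thc))
})

test_that("tidy and glance summarize a fit", {
  sc <- make_block_scene(n = 6, n_regions = 2, n_classes = 2)
  op <- system_operator(sc$atlas, sc$tissues, sc$density, fwhm_mm = 0)
  set.seed(4)
  m <- array(rpois(6^3, 5), c(6, 6, 6))
  fit <- osl_mapem(template_image(sc$grid, m, 0), op,
                   config = estimation_config(n_iter = 20))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_named(td, c("region", "class", "region_id", "class_id", "uptake",
                     "sensitivity", "frozen"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_iter, fit$n_iter_run)
})
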