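test_that("projection geometry: symmetry, chord lengths, linearity", {
  # point source at centre peaks at the central radial bin for all angles
  sc0 <- scanner_model(n_angles = 12, n_radial_bins = 31, bin_size_mm = 2,
                       psf_fwhm_mm = 0)
  n <- 31
  pt <- array(0, c(n, n, 1)); pt[16, 16, 1] <- 1
  y <- project_phantom(pt, sc0, 2)
  for (ai in 1:12) expect_equal(which.max(y[, ai, 1]), 16)

  # uniform disc profile approximates the analytic chord length 2*sqrt(r^2-s^2)
  scd <- scanner_model(n_angles = 4, n_radial_bins = 96, bin_size_mm = 2,
                       psf_fwhm_mm = 0)
  ng <- 192; v <- 1; r_mm <- 40
  cx <- (seq_len(ng) - (ng + 1) / 2) * v
  disc <- array(as.numeric(outer(cx^2, cx^2, "+") <= r_mm^2), c(ng, ng, 1))
  yd <- project_phantom(disc, scd, v)
  s <- (seq_len(96) - 97 / 2) * 2
  chord <- ifelse(abs(s) < r_mm, 2 * sqrt(pmax(r_mm^2 - s^2, 0)), 0)
  ctr <- abs(s) < 0.8 * r_mm
  for (ai in 1:4)
    expect_lt(max(abs(yd[ctr, ai, 1] - chord[ctr]) / chord[ctr]), 0.02)

  # linearity: double the activity, double the expectation
  sc <- scanner_model(12, 31, 2, psf_fwhm_mm = 4.3)
  x <- array(runif(n * n), c(n, n, 1))
  expect_equal(project_phantom(2 * x, sc, 2), 2 * project_phantom(x, sc, 2),
               tolerance = 1e-12)
})

test_that("attenuation factors follow the exponential line integral", {
  sc <- scanner_model(8, 120, 2, psf_fwhm_mm = 0)
  n <- 120; v <- 2
  expect_equal(attenuation_factors(array(0, c(n, n, 1)), sc, v),
               array(1, c(120, 8, 1)))
  # uniform cylinder mu = 0.096/cm, diameter 200 mm: central ray
  # a = exp(-0.096 * 20) = exp(-1.92)
  cx <- (seq_len(n) - (n + 1) / 2) * v
  cyl <- array(as.numeric(outer(cx^2, cx^2, "+") <= 100^2) * 0.096,
               c(n, n, 1))
  a <- attenuation_factors(cyl, sc, v)
  expect_equal(a[60, 1, 1], exp(-1.92), tolerance = 0.02)
  expect_true(all(a > 0 & a <= 1))
  # monotone in mu
  a2 <- attenuation_factors(2 * cyl, sc, v)
  expect_true(all(a2 <= a + 1e-12))
  expect_error(attenuation_factors(-cyl, sc, v), "nonnegative")
})

test_that("count sampling is seeded, calibrated and zero-preserving", {
  ybar <- array(runif(500), c(25, 20, 1))
  ybar[1:5] <- 0
  s1 <- sample_counts(ybar, 1e5, seed = 42)
  s2 <- sample_counts(ybar, 1e5, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts,
                         sample_counts(ybar, 1e5, seed = 43)$counts))
  # total within 5 sigma of the target expectation
  expect_lt(abs(sum(s1$counts) - 1e5), 5 * sqrt(1e5))
  expect_true(all(s1$counts[1:5] == 0))
  # sampling must not disturb the session RNG
  set.seed(1); before <- .Random.seed
  invisible(sample_counts(ybar, 1e3, seed = 7))
  expect_identical(before, .Random.seed)
})

test_that("projector and backprojector are exact adjoints", {
  sc <- scanner_model(24, 40, 2, psf_fwhm_mm = 4.3)
  set.seed(31)
  for (i in 1:20) {
    x <- array(runif(40 * 40 * 2), c(40, 40, 2))
    y <- array(runif(40 * 24 * 2), c(40, 24, 2))
    lhs <- sum(project_phantom(x, sc, 2) * y)
    rhs <- sum(x * petphantom:::backproject(y, sc, 40, 40, 2, 2))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("MLEM recovers a point source and never decreases the likelihood", {
  sc <- scanner_model(48, 48, 2, psf_fwhm_mm = 4.3, background_fraction = 0)
  n <- 48
  pt <- array(0, c(n, n, 1)); pt[18, 30, 1] <- 1
  # noiseless data: use expected sinogram directly as counts
  ybar <- project_phantom(pt, sc, 2)
  sino <- structure(list(counts = ybar * 1e4, attn = NULL, background = 0,
                         norm = 1e4, dims = c(n, n, 1), voxel_size_mm = 2,
                         seed = NA, scanner = sc),
                    class = "sinogram_data")
  rec <- mlem(sino, 50)
  ll <- rec$trace$loglik
  expect_true(all(diff(ll) >= -1e-9 * abs(ll[-1])))
  img <- rec$image[, , 1]
  com <- c(sum(row(img) * img), sum(col(img) * img)) / sum(img)
  expect_lt(max(abs(com - c(18, 30))), 1)
  # all-zero counts drive the image to zero
  sino0 <- sino; sino0$counts[] <- 0
  rec0 <- mlem(sino0, 10)
  expect_lt(max(rec0$image), 1e-6)
})

test_that("Bowsher selection picks the most similar neighbours deterministically", {
  # interior voxels select exactly k = 40 in a 5x5x5 window
  set.seed(8)
  g <- array(rnorm(14^3), c(14, 14, 14))
  w <- bowsher_weights(g, k = 40, window = 5)
  interior <- array(FALSE, c(14, 14, 14))
  interior[3:12, 3:12, 3:12] <- TRUE
  expect_true(all(w$n_selected[as.vector(interior)] == 40))
  expect_true(all(w$n_selected >= 26))   # worst corner: 3x3x3 - 1
  expect_true(any(w$boundary_flagged))
  expect_true(Matrix::isSymmetric(w$W))

  # constant guide: ties resolved by spatial distance (closest k chosen)
  gc <- array(1, c(9, 9, 9))
  wc <- bowsher_weights(gc, k = 6, window = 5)
  B <- methods::as(wc$selection, "TsparseMatrix")
  v <- lin_idx(c(9, 9, 9), 5, 5, 5)
  # with k = 6 and all-equal similarity the 6 face neighbours are selected
  face <- c(lin_idx(c(9, 9, 9), 4, 5, 5), lin_idx(c(9, 9, 9), 6, 5, 5),
            lin_idx(c(9, 9, 9), 5, 4, 5), lin_idx(c(9, 9, 9), 5, 6, 5),
            lin_idx(c(9, 9, 9), 5, 5, 4), lin_idx(c(9, 9, 9), 5, 5, 6))
  expect_setequal(B@j[B@i + 1 == v] + 1, face)

  # two-region guide: selection never crosses the boundary when enough
  # same-region neighbours exist; matches brute force
  g2 <- array(0, c(7, 7, 7)); g2[5:7, , ] <- 10
  w2 <- bowsher_weights(g2, k = 10, window = 5)
  B2 <- methods::as(w2$selection, "TsparseMatrix")
  for (vox in list(c(3, 4, 4), c(6, 4, 4), c(4, 4, 4))) {
    v <- lin_idx(c(7, 7, 7), vox[1], vox[2], vox[3])
    sel <- B2@j[B2@i + 1 == v] + 1
    oracle <- brute_bowsher_one(g2, vox, 10, 5)
    expect_setequal(sel, lin_idx(c(7, 7, 7), oracle$x, oracle$y, oracle$z))
    # all selected neighbours share the centre's guide value
    expect_true(all(g2[sel] == g2[v]))
  }
  expect_error(bowsher_weights(g2, k = 124, window = 5), "window")
})

test_that("guided MAP reduces to MLEM at beta 0 and denoises with a matched guide", {
  spec <- scene_spec(shape = c(32, 32, 4), voxel_size_mm = 3, n_regions = 3,
                     n_classes = 2, seed = 5)
  pw <- generate_piecewise_phantom(4, spec)
  sc <- scanner_model(48, 48, 3, psf_fwhm_mm = 4.3)
  sino <- simulate_acquisition(pw$phantom$activity, sc, 3,
                               mu_map = array(0.096, spec$shape) *
                                 (pw$labels > 0),
                               total_counts = 1e5, seed = 2)
  guide <- array(c(0, 1, 0.55)[pw$labels + 1L], spec$shape)
  w <- bowsher_weights(guide, k = 40, window = 5)
  rec_ml <- mlem(sino, 25)
  rec_b0 <- map_lange(sino, w, beta = 0, delta = 1, n_iter = 25)
  expect_identical(rec_b0$image, rec_ml$image)
  # matched guide, moderate beta: within-region SD strictly below MLEM's
  delta <- 0.2 * max(rec_ml$image)
  rec_map <- map_lange(sino, w, beta = 0.03, delta = delta, n_iter = 25)
  gm <- pw$labels == 1
  expect_lt(sd(rec_map$image[gm]), sd(rec_ml$image[gm]))
  # large-delta limit: the Lange run approaches a directly coded
  # quadratic-prior OSL run at matched iterations
  big_delta <- 1e6 * max(rec_ml$image)
  rec_lange <- map_lange(sino, w, beta = 0.02, delta = big_delta, n_iter = 15)
  W <- methods::as(w$W, "CsparseMatrix")
  ii <- W@i + 1L; jj <- rep.int(seq_len(ncol(W)), diff(W@p)); ww <- W@x
  quad_grad <- function(x) {
    contrib <- 2 * ww * (x[ii] - x[jj])
    g <- numeric(length(x))
    acc <- rowsum(contrib, ii, reorder = FALSE)
    g[as.integer(rownames(acc))] <- acc[, 1]
    array(g, dim = dim(x))
  }
  rec_quad <- petphantom:::recon_osl(sino, 15, prior_grad = quad_grad,
                                     beta = 0.02)
  scale <- max(rec_quad$image)
  expect_lt(max(abs(rec_lange$image - rec_quad$image)) / scale, 0.01)
})
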