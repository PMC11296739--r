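# Fixtures are generated in code; the oracles below are written
# independently of the package internals they check (explicit loops and
# dense matrices, no reuse of the operator code paths).

# -- tiny hand-built scene ---------------------------------------------------

# labelled-block scene: hard labels, optional soft (blurred) atlas
make_block_scene <- function(n = 6, n_regions = 3, n_classes = 2,
                             voxel_size = 2, density = NULL, soft = 0,
                             pad = 0) {
  grid <- vox_grid(c(n, n, n), voxel_size)
  lab <- array(0L, c(n, n, n))
  lo <- 1 + pad; hi <- n - pad
  cuts <- round(seq(lo, hi + 1, length.out = n_regions + 1))
  for (r in seq_len(n_regions))
    lab[cuts[r]:(cuts[r + 1] - 1), lo:hi, lo:hi] <- r
  cls <- array(rep(rep(seq_len(n_classes), length.out = n), each = n),
               c(n, n, n))  # stripes along y
  cls <- aperm(cls, c(2, 1, 3))
  if (soft > 0) {
    prob <- array(0, c(n, n, n, n_regions))
    for (r in seq_len(n_regions))
      prob[, , , r] <- smooth_volume(array(as.numeric(lab == r), c(n, n, n)),
                                     soft, voxel_size)
    atlas <- prob_atlas(grid, prob)
  } else {
    atlas <- atlas_from_labels(grid, lab, n_regions)
  }
  if (is.null(density)) {
    set.seed(99)
    density <- array(exp(0.2 * rnorm(n^3)), c(n, n, n))
  }
  list(grid = grid, atlas = atlas,
       tissues = tissue_map(grid, cls, n_classes),
       density = density_map(grid, density),
       region_labels = lab)
}

# -- dense independent oracles ----------------------------------------------

# dense DTA basis matrix by explicit elementwise products
dense_basis_matrix <- function(atlas, tissues, density) {
  J <- atlas$n_regions * tissues$n_classes
  nv <- prod(atlas$grid$shape)
  M <- matrix(0, nv, J)
  j <- 0
  for (r in seq_len(atlas$n_regions)) {
    for (cl in seq_len(tissues$n_classes)) {
      j <- j + 1
      M[, j] <- as.vector(atlas$prob[, , , r]) *
        as.vector(tissues$labels == cl) * as.vector(density$density)
    }
  }
  M
}

# dense renormalized-Gaussian blur matrix: S = C / rowSums(C), with C the
# Kronecker product of per-axis zero-padded convolution matrices
dense_blur_matrix <- function(shape, voxel_size, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / rep_len(voxel_size, 3)
  axis_mat <- function(n, sg) {
    if (sg <= 0) return(diag(n))
    r <- max(1, ceiling(4 * sg))
    k <- exp(-(-r:r)^2 / (2 * sg^2)); k <- k / sum(k)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) for (o in -r:r) {
      j <- i + o
      if (j >= 1 && j <= n) K[i, j] <- K[i, j] + k[o + r + 1]
    }
    K
  }
  Kx <- axis_mat(shape[1], sigma[1])
  Ky <- axis_mat(shape[2], sigma[2])
  Kz <- axis_mat(shape[3], sigma[3])
  C <- kronecker(Kz, kronecker(Ky, Kx))   # voxel order: x fastest
  C / rowSums(C)
}

# plain MLEM on theta against a dense model matrix, mirroring the package's
# stated conventions (0/0 := 0 ratio, eps floor, scale-matched uniform init)
dense_mlem_theta <- function(m, M, n_iter, eps = 1e-12) {
  mv <- as.vector(m)
  s <- colSums(M)
  free <- s > 0
  theta <- rep(1, ncol(M)); theta[!free] <- 0
  theta <- theta * sum(mv) / sum(M %*% theta)
  out <- matrix(0, n_iter, ncol(M))
  for (it in seq_len(n_iter)) {
    xbar <- as.vector(M %*% theta)
    ratio <- numeric(length(mv))
    pos <- mv > 0
    ratio[pos] <- mv[pos] / pmax(xbar[pos], eps)
    num <- as.vector(crossprod(M, ratio))
    theta[free] <- theta[free] * num[free] / s[free]
    out[it, ] <- theta
  }
  out
}

# brute-force penalty value: explicit double loop
brute_penalty <- function(theta, xi) {
  U <- 0
  for (j in seq_along(theta))
    for (k in seq_along(theta))
      U <- U + xi[j, k] * (theta[j] - theta[k])^2
  U
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# brute-force Bowsher selection for one voxel (1-based index vector)
brute_bowsher_one <- function(guide, vox, k, window) {
  d <- dim(guide)
  hw <- (window - 1) / 2
  cand <- expand.grid(dx = -hw:hw, dy = -hw:hw, dz = -hw:hw)
  cand <- cand[rowSums(cand != 0) > 0, ]
  cand$order <- seq_len(nrow(cand))
  cand$x <- vox[1] + cand$dx; cand$y <- vox[2] + cand$dy
  cand$z <- vox[3] + cand$dz
  cand <- cand[cand$x >= 1 & cand$x <= d[1] & cand$y >= 1 & cand$y <= d[2] &
                 cand$z >= 1 & cand$z <= d[3], ]
  cand$diff <- abs(guide[cbind(cand$x, cand$y, cand$z)] -
                     guide[vox[1], vox[2], vox[3]])
  cand$dist2 <- cand$dx^2 + cand$dy^2 + cand$dz^2
  cand <- cand[order(cand$diff, cand$dist2, cand$order), ]
  head(cand, k)
}

# linear voxel index helper
lin_idx <- function(d, x, y, z) x + (y - 1) * d[1] + (z - 1) * d[1] * d[2]

# the ill-posed tiny-region scene used for the regularization-necessity
# checks: soft overlapping atlas, 4-voxel third region, heavy blur
make_tiny_region_scene <- function(noise_seed, counts_per_voxel = 5) {
  n <- 16
  grid <- vox_grid(c(n, n, n), 2)
  lab <- array(0L, c(n, n, n))
  lab[3:14, 3:14, 3:14] <- 1L
  lab[9:14, 3:14, 3:14] <- 2L
  lab[8, 8, 8] <- 3L; lab[8, 9, 8] <- 3L; lab[9, 8, 8] <- 3L
  lab[8, 8, 9] <- 3L
  prob <- array(0, c(n, n, n, 3))
  for (r in 1:3)
    prob[, , , r] <- smooth_volume(array(as.numeric(lab == r), c(n, n, n)),
                                   6, 2)
  atlas <- prob_atlas(grid, prob)
  tissues <- tissue_map(grid, array(as.integer(lab > 0), c(n, n, n)), 1)
  density <- density_map(grid, array(1, c(n, n, n)))
  op <- system_operator(atlas, tissues, density, fwhm_mm = 10)
  theta_true <- c(1, 1.3, 1.1)
  xbar <- op_forward(op, theta_true)
  set.seed(noise_seed)
  m <- array(rpois(n^3, as.vector(xbar * counts_per_voxel)) /
               counts_per_voxel, c(n, n, n))
  list(op = op, template = template_image(grid, m, 10),
       theta_true = theta_true,
       weights = compute_weights(
         compute_centroids(atlas, tissues, density, op$index), op$index))
}
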