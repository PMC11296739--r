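#' Parameter index: (region, class) <-> flat index
#'
#' The uptake-parameter vector theta holds one value per (atlas region,
#' tissue class) combination; with 95 regions and 8 classes this gives the
#' canonical 760 parameters. The flat index runs class-fastest:
#' `j = (r - 1) * n_classes + c`.
#'
#' @param n_regions,n_classes Positive integer counts.
#' @return A `param_index` object with `n_params = n_regions * n_classes`.
#' @export
param_index <- function(n_regions, n_classes) {
  n_regions <- as.integer(n_regions); n_classes <- as.integer(n_classes)
  stopifnot(n_regions >= 1L, n_classes >= 1L)
  structure(list(n_regions = n_regions, n_classes = n_classes,
                 n_params = n_regions * n_classes),
            class = "param_index")
}

#' @rdname param_index
#' @param index A `param_index`.
#' @param r,c Region and class indices (1-based).
#' @export
param_flat <- function(index, r, c) {
  stopifnot(all(r >= 1L), all(r <= index$n_regions),
            all(c >= 1L), all(c <= index$n_classes))
  (r - 1L) * index$n_classes + c
}

#' @rdname param_index
#' @param j Flat parameter index (1-based).
#' @export
param_unflat <- function(index, j) {
  stopifnot(all(j >= 1L), all(j <= index$n_params))
  r <- (j - 1L) %/% index$n_classes + 1L
  c <- (j - 1L) %% index$n_classes + 1L
  cbind(region = r, class = c)
}

#' One basis column of the DTA matrix
#'
#' The basis function for parameter (r, c) is the elementwise product of the
#' region's probability map, the binary tissue-class mask and the density
#' volume: `prob_r * 1[labels == c] * density`. An all-zero column is a valid
#' (empty) combination.
#'
#' @param atlas [prob_atlas()].
#' @param tissues [tissue_map()].
#' @param density [density_map()].
#' @param r,c Region and tissue-class index (1-based).
#' @return Nonnegative 3-D array on the shared grid.
#' @export
build_basis_column <- function(atlas, tissues, density, r, c) {
  stopifnot_same_grid(atlas$grid, tissues$grid, density$grid)
  stopifnot(r >= 1L, r <= atlas$n_regions, c >= 1L, c <= tissues$n_classes)
  atlas$prob[, , , r] * (tissues$labels == c) * density$density
}

# Sparse nvox x n_params stack of all DTA basis columns.
build_basis_matrix <- function(atlas, tissues, density, index) {
  stopifnot_same_grid(atlas$grid, tissues$grid, density$grid)
  stopifnot(index$n_regions == atlas$n_regions,
            index$n_classes == tissues$n_classes)
  nv <- n_voxels(atlas$grid)
  ii <- vector("list", index$n_params)
  xx <- vector("list", index$n_params)
  lab <- as.vector(tissues$labels)
  dens <- as.vector(density$density)
  for (r in seq_len(atlas$n_regions)) {
    pr <- as.vector(atlas$prob[, , , r])
    for (c in seq_len(tissues$n_classes)) {
      j <- param_flat(index, r, c)
      v <- pr * (lab == c) * dens
      nz <- which(v > 0)
      ii[[j]] <- nz
      xx[[j]] <- v[nz]
    }
  }
  jj <- rep.int(seq_len(index$n_params), lengths(ii))
  Matrix::sparseMatrix(i = unlist(ii), j = jj, x = unlist(xx),
                       dims = c(nv, index$n_params))
}

#' Mass-weighted world-space centroids of all basis columns
#'
#' For each (region, class) parameter, the centroid is the mean world
#' coordinate of its basis column, weighted by the column's values (density-
#' weighted by default; `weighting = "binary"` uses the column's support
#' instead). Zero-mass columns are flagged invalid. Centroids are in world mm
#' so that penalty weights are resolution independent.
#'
#' @inheritParams build_basis_column
#' @param index [param_index()].
#' @param weighting `"mass"` (basis values; default) or `"binary"` (support
#'   indicator).
#' @return A `region_centroids` object: `xyz` (`n_params x 3`, mm), `mass`,
#'   `valid`.
#' @export
compute_centroids <- function(atlas, tissues, density, index,
                              weighting = c("mass", "binary")) {
  weighting <- match.arg(weighting)
  B <- build_basis_matrix(atlas, tissues, density, index)
  if (weighting == "binary") B@x <- rep_len(1, length(B@x))
  W <- grid_world_coords(atlas$grid)
  mass <- Matrix::colSums(B)
  num <- as.matrix(Matrix::crossprod(B, W))
  xyz <- num / ifelse(mass > 0, mass, 1)
  xyz[mass == 0, ] <- NA_real_
  structure(list(xyz = xyz, mass = as.numeric(mass), valid = mass > 0,
                 index = index, weighting = weighting),
            class = "region_centroids")
}
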