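#' Voxel grid geometry
#'
#' A `vox_grid` describes the geometry shared by all volumes in a phantom
#' scene: the voxel counts per axis, the voxel size in mm, and the 4x4 affine
#' mapping 0-based voxel indices to world coordinates in mm.
#'
#' @param shape Integer 3-vector of voxel counts `(nx, ny, nz)`, all >= 1.
#' @param voxel_size_mm Numeric 3-vector (or scalar, recycled) of voxel edge
#'   lengths in mm, all > 0.
#' @param affine Optional 4x4 voxel-index-to-world-mm matrix. Defaults to a
#'   diagonal scaling by `voxel_size_mm` with the world origin at the grid
#'   centre, so world coordinates are symmetric about zero.
#' @return A `vox_grid` object.
#' @export
vox_grid <- function(shape, voxel_size_mm, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three voxel counts, all >= 1")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be positive and finite")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    # centre the world origin on the grid centre
    affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat("<vox_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' World coordinates of every voxel centre
#'
#' @param grid A [vox_grid()].
#' @return An `n_voxels x 3` matrix of world coordinates in mm, in R's
#'   column-major voxel order (x fastest).
#' @export
grid_world_coords <- function(grid) {
  idx <- as.matrix(expand.grid(x = seq_len(grid$shape[1]) - 1,
                               y = seq_len(grid$shape[2]) - 1,
                               z = seq_len(grid$shape[3]) - 1))
  w <- cbind(idx, 1) %*% t(grid$affine)
  w[, 1:3, drop = FALSE]
}

#' Compare two grids for equality within tolerance
#'
#' Shapes must match exactly; affine entries to a relative tolerance (scaled
#' by the largest absolute affine entry).
#'
#' @param a,b [vox_grid()] objects.
#' @param tol Relative tolerance on affine entries (default `1e-4`).
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  if (!all(a$shape == b$shape)) return(FALSE)
  scale <- max(abs(a$affine), abs(b$affine), 1)
  max(abs(a$affine - b$affine)) <= tol * scale
}

stopifnot_same_grid <- function(..., tol = 1e-4) {
  grids <- list(...)
  for (i in seq_along(grids)[-1]) {
    if (!grids_equal(grids[[1]], grids[[i]], tol = tol))
      stop("volumes are not on a common grid; resample upstream")
  }
  invisible(grids[[1]])
}
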