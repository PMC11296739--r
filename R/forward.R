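#' Matrix-free system operator x = H D T A theta
#'
#' Combines the probabilistic atlas (A), tissue-class masks (T), cell-body
#' density (D) and a Gaussian resolution kernel (H) into a single linear
#' operator from uptake-parameter space to image space, together with its
#' exact adjoint and the sensitivity vector (column sums of HDTA). The DTA
#' basis stack is held as one sparse matrix; H distributes over the basis
#' sum, so each forward application costs one sparse product plus one
#' smoothing pass.
#'
#' @param atlas [prob_atlas()].
#' @param tissues [tissue_map()].
#' @param density [density_map()].
#' @param fwhm_mm FWHM (mm) of the Gaussian resolution model H; 0 means
#'   H = identity.
#' @return A `system_operator` with fields `index` ([param_index()]), `grid`,
#'   `sensitivity` (cached), and internals.
#' @export
system_operator <- function(atlas, tissues, density, fwhm_mm = 0) {
  grid <- stopifnot_same_grid(atlas$grid, tissues$grid, density$grid)
  index <- param_index(atlas$n_regions, tissues$n_classes)
  B <- build_basis_matrix(atlas, tissues, density, index)
  sm <- make_smoother(grid$shape, grid$voxel_size_mm, fwhm_mm)
  op <- structure(list(grid = grid, index = index, fwhm_mm = fwhm_mm,
                       B = B, smoother = sm, sensitivity = NULL),
                  class = "system_operator")
  op$sensitivity <- op_adjoint(op, array(1, grid$shape))
  op
}

#' @export
print.system_operator <- function(x, ...) {
  cat("<system_operator> ", x$index$n_regions, " regions x ",
      x$index$n_classes, " classes = ", x$index$n_params,
      " parameters; H fwhm = ", x$fwhm_mm, " mm\n", sep = "")
  invisible(x)
}

#' Forward, adjoint and sensitivity of the system operator
#'
#' `op_forward` maps theta to the predicted template-resolution image
#' `H(sum_j theta_j basis_j)`; `op_adjoint` maps an image to parameter space
#' via `(HDTA)' y`; `op_sensitivity` returns the cached column sums
#' `s = (HDTA)' 1`, which are zero exactly for empty basis columns.
#'
#' @param op A [system_operator()].
#' @param theta Nonnegative parameter vector of length `op$index$n_params`.
#' @return `op_forward`: a 3-D array on `op$grid`; `op_adjoint` and
#'   `op_sensitivity`: numeric vectors of length `n_params`.
#' @export
op_forward <- function(op, theta) {
  if (length(theta) != op$index$n_params)
    stop("theta has length ", length(theta), ", expected ", op$index$n_params)
  if (any(theta < 0)) stop("theta must be nonnegative")
  acc <- array(as.numeric(op$B %*% theta), dim = op$grid$shape)
  smooth_apply(op$smoother, acc)
}

#' @rdname op_forward
#' @param y 3-D numeric array on the operator's grid.
#' @export
op_adjoint <- function(op, y) {
  if (!all(dim(y) == op$grid$shape)) stop("image is not on the operator grid")
  if (any(!is.finite(y))) stop("image must be finite")
  v <- smooth_adjoint_apply(op$smoother, y)
  as.numeric(Matrix::crossprod(op$B, as.vector(v)))
}

#' @rdname op_forward
#' @export
op_sensitivity <- function(op) op$sensitivity
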