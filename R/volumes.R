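#' Read a NIfTI volume with its grid
#'
#' Reads a NIfTI-1/-2 file and returns the voxel data together with its
#' [vox_grid()]. The function never resamples: if `expected_grid` is given and
#' the file's grid differs (shape, or affine beyond tolerance), an error is
#' raised so the caller can resample upstream.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param expected_grid Optional [vox_grid()] the file must match.
#' @param tol Relative tolerance on affine entries for the grid comparison.
#' @return A list with `values` (3-D array) and `grid` ([vox_grid()]).
#' @export
read_volume <- function(path, expected_grid = NULL, tol = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  d <- dim(vals)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " dimensions")
  vals <- array(as.numeric(vals), dim = d)   # strip NIfTI attributes
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  # voxel size from the affine's column norms (authoritative over pixdim)
  pix <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- vox_grid(d, pix, affine = aff)
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0)
    stop("volume contains ", n_bad, " non-finite voxel(s): ", path)
  if (!is.null(expected_grid) && !grids_equal(grid, expected_grid, tol = tol))
    stop("grid mismatch for ", path,
         ": input volumes must share one grid (resample upstream)")
  list(values = vals, grid = grid)
}

#' Write a volume as NIfTI (float32)
#'
#' @param values 3-D numeric array.
#' @param grid [vox_grid()] supplying the affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path) {
  stopifnot(all(dim(values) == grid$shape))
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$shape),
                         datatype = "float")
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Probabilistic parcellation atlas
#'
#' One probability map per region (the columns of the atlas matrix A): each
#' voxel's value is the probability it belongs to that region. Per-voxel sums
#' over regions may be below 1 (background); sums exceeding `1 + 1e-3` are
#' scaled down to 1, never up (background is preserved).
#'
#' @param grid [vox_grid()].
#' @param prob 4-D array `(nx, ny, nz, n_regions)` of probabilities in
#'   `[0, 1]`.
#' @param region_names Optional character vector of region labels.
#' @return A `prob_atlas` object with fields `grid`, `prob`, `n_regions`,
#'   `region_names`, and `empty_regions` (logical: zero total mass).
#' @export
prob_atlas <- function(grid, prob, region_names = NULL) {
  stopifnot(length(dim(prob)) == 4L, all(dim(prob)[1:3] == grid$shape))
  if (any(!is.finite(prob))) stop("atlas probabilities must be finite")
  if (any(prob < 0) || any(prob > 1 + 1e-6))
    stop("atlas probabilities must lie in [0, 1]")
  prob[prob > 1] <- 1
  nr <- dim(prob)[4]
  psum <- apply(prob, 1:3, sum)
  over <- psum > 1 + 1e-3
  if (any(over)) {
    # scale down offending voxels only; never up-normalize
    scl <- ifelse(over, 1 / psum, 1)
    prob <- prob * as.vector(scl)
  }
  if (is.null(region_names)) region_names <- paste0("region_", seq_len(nr))
  stopifnot(length(region_names) == nr)
  mass <- apply(prob, 4, sum)
  structure(list(grid = grid, prob = prob, n_regions = nr,
                 region_names = region_names, empty_regions = mass == 0),
            class = "prob_atlas")
}

#' One-hot probabilistic atlas from a hard label volume
#'
#' Convenience converter: label `r` becomes a binary probability map for
#' region `r`; label 0 is background.
#'
#' @param grid [vox_grid()].
#' @param labels Integer 3-D array of region labels in `{0..n_regions}`.
#' @param n_regions Number of regions (defaults to `max(labels)`).
#' @inheritParams prob_atlas
#' @return A `prob_atlas`.
#' @export
atlas_from_labels <- function(grid, labels, n_regions = max(labels),
                              region_names = NULL) {
  stopifnot(all(dim(labels) == grid$shape), all(labels >= 0),
            all(labels <= n_regions))
  prob <- array(0, c(grid$shape, n_regions))
  for (r in seq_len(n_regions))
    prob[, , , r] <- as.numeric(labels == r)
  prob_atlas(grid, prob, region_names)
}

#' Hard tissue-class volume
#'
#' Each voxel carries one integer tissue class in `{0..n_classes}`, 0 being
#' background (mirroring a classified histology volume with, e.g., 8 classes).
#'
#' @param grid [vox_grid()].
#' @param labels Integer 3-D array of class labels.
#' @param n_classes Number of tissue classes.
#' @param class_names Optional labels.
#' @return A `tissue_map` object; `empty_classes` flags classes with no
#'   voxels.
#' @export
tissue_map <- function(grid, labels, n_classes = max(labels),
                       class_names = NULL) {
  stopifnot(all(dim(labels) == grid$shape))
  labels <- array(as.integer(labels), dim = grid$shape)
  if (any(labels < 0L) || any(labels > n_classes))
    stop("tissue labels out of range 0..", n_classes)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes))
  stopifnot(length(class_names) == n_classes)
  counts <- tabulate(labels, nbins = n_classes)
  structure(list(grid = grid, labels = labels, n_classes = as.integer(n_classes),
                 class_names = class_names, empty_classes = counts == 0),
            class = "tissue_map")
}

#' Cell-body-density volume
#'
#' Per-voxel nonnegative scalar density (arbitrary units); the diagonal D of
#' the forward model, providing sub-regional heterogeneity.
#'
#' @param grid [vox_grid()].
#' @param density Nonnegative finite 3-D array.
#' @return A `density_map` object.
#' @export
density_map <- function(grid, density) {
  stopifnot(all(dim(density) == grid$shape))
  if (any(!is.finite(density))) stop("density must be finite")
  if (any(density < 0)) stop("density must be nonnegative")
  structure(list(grid = grid, density = density), class = "density_map")
}

#' Low-resolution tracer template image
#'
#' The reference scan m whose regional pattern the phantom parameters are
#' fitted to match. Negative voxels (possible in reconstructed scans) are
#' clipped to zero; the clip count is recorded and reported.
#'
#' @param grid [vox_grid()].
#' @param values 3-D array of intensities.
#' @param assumed_fwhm_mm Stated effective resolution (FWHM, mm) of the scan.
#' @return A `template_image` with fields `values`, `assumed_fwhm_mm`,
#'   `n_clipped`.
#' @export
template_image <- function(grid, values, assumed_fwhm_mm) {
  stopifnot(all(dim(values) == grid$shape), assumed_fwhm_mm >= 0)
  if (any(!is.finite(values))) stop("template contains non-finite voxels")
  n_clip <- sum(values < 0)
  if (n_clip > 0) {
    message("template: clipped ", n_clip, " negative voxel(s) to 0")
    values[values < 0] <- 0
  }
  structure(list(grid = grid, values = values,
                 assumed_fwhm_mm = assumed_fwhm_mm, n_clipped = n_clip),
            class = "template_image")
}
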