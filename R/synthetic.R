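#' Specification of a synthetic test scene
#'
#' Describes a complete toy input set — probabilistic atlas, tissue classes,
#' density texture, ground-truth uptake, template — emulating the real
#' inputs (a parcellation atlas, a classified histology volume, a cell-body
#' density volume and a low-resolution tracer scan) on a desk-scale grid.
#' The brain is an ellipsoid; tissue classes are nested shells (outer shell
#' behaves like cortical gray matter, inner like white matter); regions are
#' a Voronoi parcellation over seeds inside the brain, softened into
#' overlapping probability maps by Gaussian blurring; the density is a
#' strictly positive log-Gaussian random field.
#'
#' @param shape Grid shape (default `c(48, 48, 48)`).
#' @param voxel_size_mm Voxel size in mm (default 2: estimation-scale; a
#'   0.4 mm showcase grid is possible but not used in routine testing).
#' @param n_regions Number of atlas regions (default 8).
#' @param n_classes Number of tissue classes / shells (default 3).
#' @param softness_vox Gaussian sigma (voxels) blurring the hard region
#'   labels into probability maps (default 1).
#' @param density_sigma Log-scale SD of the density field (default 0.3).
#' @param density_corr_fwhm_mm Correlation length (FWHM, mm) of the density
#'   texture (default 6).
#' @param class_base_uptake Per-class base uptake values; default a
#'   geometric ramp from 4 (outer, GM-like) down to 1 (innermost), the
#'   conventional gray:white contrast for an FDG-like tracer.
#' @param region_sd Log-scale SD of the per-region uptake multiplier
#'   (default 0.25) — the large-scale heterogeneity the phantom must carry.
#' @param template_fwhm_mm Effective resolution of the template scan
#'   (default 6 mm, a typical reconstructed clinical PET resolution).
#' @param noise_factor Mean template counts per in-brain voxel for the
#'   Poisson draw; 0 disables noise (default 100, a clinical-count level).
#' @param seed RNG seed (default 1).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shape = c(48, 48, 48), voxel_size_mm = 2,
                       n_regions = 8, n_classes = 3, softness_vox = 1,
                       density_sigma = 0.3, density_corr_fwhm_mm = 6,
                       class_base_uptake = NULL, region_sd = 0.25,
                       template_fwhm_mm = 6, noise_factor = 100, seed = 1) {
  if (is.null(class_base_uptake)) {
    class_base_uptake <- if (n_classes == 1) 1 else
      4 * (1 / 4)^((seq_len(n_classes) - 1) / (n_classes - 1))
  }
  stopifnot(length(class_base_uptake) == n_classes,
            all(class_base_uptake > 0), n_regions >= 1, n_classes >= 1,
            softness_vox >= 0, noise_factor >= 0)
  if (n_regions * n_classes > prod(shape))
    stop("infeasible spec: more parameters than voxels")
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 n_regions = n_regions, n_classes = n_classes,
                 softness_vox = softness_vox, density_sigma = density_sigma,
                 density_corr_fwhm_mm = density_corr_fwhm_mm,
                 class_base_uptake = class_base_uptake,
                 region_sd = region_sd,
                 template_fwhm_mm = template_fwhm_mm,
                 noise_factor = noise_factor, seed = seed),
            class = "scene_spec")
}

# normalized radius (0 centre .. 1 brain edge) and ellipsoid brain mask
scene_geometry <- function(shape) {
  cx <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (0.42 * n))
  r2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, "+"), cx[[3]]^2, "+")
  dim(r2) <- shape
  list(r = sqrt(r2), mask = r2 <= 1)
}

#' Generate a complete synthetic scene with known ground truth
#'
#' Builds all four model inputs plus the template from the package's own
#' forward chain: `template = Poisson(scale * smooth(render(theta_true),
#' fwhm))`, with `theta_true` recorded. Also returns a two-level mu-map
#' (soft tissue 0.096/cm, background 0) and a guide image (tissue-contrast
#' anatomy plus an independent smooth bias field and noise). Deterministic
#' given the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @return A `synthetic_scene` list: `atlas`, `tissues`, `density`,
#'   `theta_true`, `template` ([template_image()]), `mu_map`, `guide`,
#'   `region_labels`, `brain_mask`, `grid`, `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  grid <- vox_grid(spec$shape, spec$voxel_size_mm)
  geo <- scene_geometry(spec$shape)
  mask <- geo$mask
  nv <- prod(spec$shape)

  # tissue classes: nested shells, class 1 outermost (cortex-like)
  shell <- ceiling(pmin(pmax(1 - geo$r, 0), 1) * spec$n_classes)
  labels <- array(0L, spec$shape)
  labels[mask] <- pmax(shell[mask], 1L)
  tissues <- tissue_map(grid, labels, spec$n_classes)

  # Voronoi region parcellation over in-brain seeds
  coords <- grid_world_coords(grid)
  in_brain <- which(as.vector(mask))
  seeds <- coords[sample(in_brain, spec$n_regions), , drop = FALSE]
  d2 <- matrix(0, nv, spec$n_regions)
  for (r in seq_len(spec$n_regions))
    d2[, r] <- colSums((t(coords) - seeds[r, ])^2)
  region_labels <- array(0L, spec$shape)
  region_labels[mask] <- max.col(-d2[in_brain, , drop = FALSE],
                                 ties.method = "first")

  # soften hard labels into overlapping probability maps
  prob <- array(0, c(spec$shape, spec$n_regions))
  for (r in seq_len(spec$n_regions)) {
    pr <- array(as.numeric(region_labels == r), spec$shape)
    if (spec$softness_vox > 0)
      pr <- smooth_volume(pr, 2 * sqrt(2 * log(2)) * spec$softness_vox *
                            spec$voxel_size_mm, spec$voxel_size_mm)
    prob[, , , r] <- pr
  }
  atlas <- prob_atlas(grid, prob)

  # strictly positive textured density: exp of a smoothed white-noise field
  wn <- array(stats::rnorm(nv), spec$shape)
  f <- smooth_volume(wn, spec$density_corr_fwhm_mm, spec$voxel_size_mm)
  f <- f / stats::sd(f)
  density <- density_map(grid, exp(spec$density_sigma * f))

  # ground-truth uptake: per-class base x per-region lognormal multiplier
  index <- param_index(spec$n_regions, spec$n_classes)
  mult <- exp(stats::rnorm(index$n_params, sd = spec$region_sd))
  rc <- param_unflat(index, seq_len(index$n_params))
  theta_true <- spec$class_base_uptake[rc[, "class"]] * mult

  # template from the scene's own forward chain
  x_hr <- render_phantom(theta_true, atlas, tissues, density)
  x_sm <- smooth_volume(x_hr$activity, spec$template_fwhm_mm,
                        spec$voxel_size_mm)
  if (spec$noise_factor > 0) {
    # Poisson noise at noise_factor mean counts per in-brain voxel; the draw
    # is rescaled back to activity units so theta keeps the true scale
    count_scale <- spec$noise_factor / mean(x_sm[mask])
    m <- array(stats::rpois(nv, as.vector(x_sm * count_scale)),
               spec$shape) / count_scale
  } else {
    count_scale <- 1
    m <- x_sm
  }
  template <- template_image(grid, m, spec$template_fwhm_mm)

  mu_map <- array(0.096, spec$shape) * mask   # soft tissue at 511 keV, 1/cm

  # anatomy-contrast guide: per-class T1-like levels + smooth bias + noise
  t1_level <- c(0, seq(1, 0.4, length.out = spec$n_classes))
  anat <- array(t1_level[labels + 1L], spec$shape)
  bias <- smooth_volume(array(stats::rnorm(nv), spec$shape),
                        4 * spec$density_corr_fwhm_mm, spec$voxel_size_mm)
  bias <- bias / max(abs(bias))
  guide <- anat * (1 + 0.1 * bias) + 0.01 * stats::rnorm(nv)

  structure(list(atlas = atlas, tissues = tissues, density = density,
                 theta_true = theta_true, template = template,
                 count_scale = count_scale,
                 mu_map = mu_map, guide = array(guide, spec$shape),
                 region_labels = region_labels, brain_mask = mask,
                 grid = grid, spec = spec),
            class = "synthetic_scene")
}

#' Piecewise-constant comparison phantom
#'
#' The classical control: a piecewise-constant brain phantom with a fixed
#' gray:white contrast (default 4:1) and zero background, built from the
#' same shell geometry as [generate_scene()] — GM is the outer shell, WM
#' everything inside, no sub-regional texture. Used to contrast guided
#' reconstruction behaviour against the heterogeneous phantom.
#'
#' @param gm_wm_contrast GM:WM mean-activity ratio (> 0, default 4).
#' @param spec A [scene_spec()] supplying grid and geometry (classes beyond
#'   the first are merged into WM).
#' @return List: `phantom` (a `phantom_volume`), `labels` (0 background,
#'   1 GM, 2 WM), `grid`.
#' @export
generate_piecewise_phantom <- function(gm_wm_contrast = 4.0,
                                       spec = scene_spec()) {
  stopifnot(gm_wm_contrast > 0)
  grid <- vox_grid(spec$shape, spec$voxel_size_mm)
  geo <- scene_geometry(spec$shape)
  shell <- ceiling(pmin(pmax(1 - geo$r, 0), 1) * spec$n_classes)
  cls <- array(0L, spec$shape)
  cls[geo$mask] <- pmax(shell[geo$mask], 1L)
  labels <- array(0L, spec$shape)
  labels[cls == 1L] <- 1L            # GM: outer shell
  labels[cls > 1L] <- 2L             # WM: everything interior
  activity <- array(0, spec$shape)
  activity[labels == 1L] <- gm_wm_contrast
  activity[labels == 2L] <- 1
  phantom <- structure(list(grid = grid, activity = activity,
                            provenance = list(theta_digest = NA_character_,
                                              smoothing_fwhm_mm = 0,
                                              gm_wm_contrast = gm_wm_contrast)),
                       class = "phantom_volume")
  list(phantom = phantom, labels = labels, grid = grid)
}

#' Guide image with controlled anatomical mismatch
#'
#' Produces a guide whose boundaries deliberately disagree with the PET
#' support: the anatomy is translated by `warp_mm`, an optional spherical
#' lesion absent from the PET phantom is added, and a smooth intensity bias
#' is applied. The mismatch is quantified by the Dice coefficient between
#' the warped and original brain supports (1 = perfect agreement).
#'
#' @param scene A `synthetic_scene`.
#' @param warp_mm Translation of the anatomy along x, in mm (default 0).
#' @param lesion_radius_mm Radius of an added guide-only lesion (0 = none).
#' @param bias_amplitude Relative amplitude of the smooth bias (default 0).
#' @param seed Seed for the bias/noise (default the scene's seed + 1).
#' @return List: `guide` (3-D array), `dice` (support overlap), `lesion_mask`.
#' @export
generate_mismatch_guide <- function(scene, warp_mm = 0, lesion_radius_mm = 0,
                                    bias_amplitude = 0, seed = NULL) {
  spec <- scene$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  shift <- round(warp_mm / spec$voxel_size_mm)
  shift_x <- function(a, s) {
    if (s == 0) return(a)
    out <- array(0, dim = dim(a))
    n <- dim(a)[1]
    if (s > 0) out[(s + 1):n, , ] <- a[1:(n - s), , ]
    else out[1:(n + s), , ] <- a[(1 - s):n, , ]
    out
  }
  labels <- shift_x(scene$tissues$labels, shift)
  support <- labels > 0
  orig <- scene$brain_mask
  dice <- 2 * sum(support & orig) / (sum(support) + sum(orig))
  t1_level <- c(0, seq(1, 0.4, length.out = spec$n_classes))
  guide <- array(t1_level[labels + 1L], spec$shape)
  lesion_mask <- array(FALSE, spec$shape)
  if (lesion_radius_mm > 0) {
    w <- grid_world_coords(scene$grid)
    ctr <- spec$voxel_size_mm * spec$shape / 5   # off-centre, inside brain
    lesion_mask <- array(sqrt(colSums((t(w) - ctr)^2)) <= lesion_radius_mm,
                         spec$shape) & orig
    guide[lesion_mask] <- max(guide) * 1.5
    dice <- 2 * sum(support & orig & !lesion_mask) /
      (sum(support & !lesion_mask) + sum(orig))
  }
  if (bias_amplitude > 0) {
    nv <- prod(spec$shape)
    bias <- with_seed(seed, smooth_volume(array(stats::rnorm(nv), spec$shape),
                                          4 * spec$density_corr_fwhm_mm,
                                          spec$voxel_size_mm))
    bias <- bias / max(abs(bias))
    guide <- guide * (1 + bias_amplitude * bias)
  }
  list(guide = guide, dice = dice, lesion_mask = lesion_mask)
}
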