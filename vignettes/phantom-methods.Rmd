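---
title: "Estimating heterogeneous digital PET brain phantoms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heterogeneous digital PET brain phantoms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petphantom)
```

## The problem

Digital PET phantoms are ground-truth activity volumes used to generate
simulated scanner data for evaluating reconstruction methods. A useful brain
phantom must be (a) high resolution, so partial-volume effects act on it the
way they act on real anatomy, (b) heterogeneous within tissue classes, because
real tracer uptake varies across anatomical regions, and (c) radiotracer
specific. Phantoms segmented directly from an MRI volume fail on (b) and —
more subtly — make anatomically *guided* reconstruction look unrealistically
good, because the phantom's activity boundaries then agree perfectly with the
guide image.

`petphantom` builds phantoms the other way around: the activity is
*parameterized anatomically* and *fitted to a measured tracer scan*.

## The forward model

The phantom activity is a nonnegative linear combination of
region-by-tissue-class basis functions,

$$\bar x \;=\; H\,D\,T\,A\,\theta,$$

where

* $A$ — per-region probability maps of a parcellation atlas (one column per
  region, repeated for every tissue class), giving each voxel's probability
  of belonging to the region;
* $T$ — the binary tissue-class masks from a hard-labelled classified volume;
* $D$ — a diagonal matrix of per-voxel cell-body density, which supplies
  sub-regional texture at the native resolution;
* $H$ — an isotropic Gaussian kernel modelling the *template's* effective
  resolution (FWHM in mm);
* $\theta$ — one relative-uptake value per (region, class) pair. With a
  95-region atlas and 8 tissue classes this is 760 parameters.

Basis column $j = (r, c)$ is the elementwise product
$\mathrm{prob}_r \odot \mathbf{1}[\mathrm{class} = c] \odot \mathrm{density}$
(`build_basis_column()`); the package stores the full stack as one sparse
matrix and applies $H$ once per forward evaluation, which is mathematically
identical by linearity and avoids one smoothing pass per basis function.

The *deliverable* phantom excludes $H$: `render_phantom()` returns
$DTA\theta$ at native resolution, because $H$ belongs to the template the
parameters were fitted against, not to the phantom itself. A smoothed
companion volume is available separately (`render_smoothed()`).

## Estimation

Given a template scan $m$ (any reconstructed image of the target tracer,
resampled onto the phantom grid), $\theta$ maximizes the penalized Poisson
log-likelihood

$$\hat\theta = \arg\max_\theta \; L(\theta \mid m) - \beta\, U(\theta),
\qquad L = \sum_i m_i \ln \bar x_i - \bar x_i ,$$

which is equivalent to minimizing the Kullback–Leibler distance between $m$
and $\bar x$ plus the penalty (the two objectives differ by a $\theta$-free
constant; `kl_distance()` checks this identity numerically). Optimization is
one-step-late (OSL) MAP-EM:

$$\theta_j \leftarrow \theta_j \cdot
  \frac{\left[(HDTA)^{\mathsf T}\, (m / \bar x)\right]_j}
       {s_j + \beta\, \partial U / \partial \theta_j},$$

with sensitivity $s = (HDTA)^{\mathsf T}\mathbf 1$ and the penalty gradient
evaluated at the previous iterate.

Why regularize at all? The problem is ill-posed: many high-resolution
distributions blur down to the same low-resolution template. Without the
penalty, the estimates for very small regions are driven by local noise and
can drift without bound over iterations — the package's test suite
reproduces this on a deliberately tiny (4-voxel) region and shows that a
modest $\beta$ pins it to its neighbourhood.

### The penalty

$U(\theta) = \sum_j \sum_{k \in N_j} \xi_{jk}\,(\theta_j - \theta_k)^2$,
where $N_j$ contains every other *same-tissue-class* parameter with a valid
centroid and $\xi_{jk}$ is the inverse Euclidean distance between the two
basis columns' mass-weighted centroids, normalized by the row sum of inverse
distances. Nearby regions therefore dominate each row. Notes on choices the
formulation leaves open:

* **Row normalization, then symmetrization.** Per-row normalization makes
  the raw weight matrix $W$ asymmetric; the package uses
  $\xi = (W + W^{\mathsf T})/2$, for which the simple symmetric-form
  gradient $4\sum_k \xi_{jk}(\theta_j - \theta_k)$ is *exactly* the gradient
  of the as-written objective. A global normalization reading is possible
  but not implemented.
* **Centroid weighting.** Centroids are density-weighted by default
  (`weighting = "mass"` in `compute_centroids()`); a `"binary"` switch uses
  the support indicator instead. The density weighting follows from the
  basis definition — the centroid of what the parameter actually controls.
* **Distances in world mm**, so the weights are resolution independent.
* Parameters with empty basis columns get empty neighbourhoods, zero
  penalty, and are frozen at exactly zero by the estimator.

### Numerical safeguards

* The EM ratio uses $0/0 := 0$, with an `epsilon_floor` (default $10^{-12}$)
  inside logs and quotients.
* **OSL denominator guard.** The OSL denominator $s_j + \beta\,\nabla_j U$
  can become nonpositive when $\beta\,|\nabla_j U| > s_j$. A clamp at a tiny
  absolute epsilon turns a single clamped step into an enormous
  multiplicative jump and the iteration explodes; the package instead clamps
  at $0.05\,s_j$, which bounds each step and degrades gracefully. Clamped
  steps are counted and reported in the fit object (`n_clamped`). The same
  guard is used in the reconstruction OSL loop. A nonzero clamp count is a
  sign that $\beta$ is beyond the reliable OSL regime for the data at hand.
* Initialization is uniform, scaled so the predicted total matches the
  template total; convergence is declared at a maximum relative change of
  $10^{-6}$ or 1000 iterations, both configurable. No subsets or
  acceleration: the parameter space is at most a few hundred values and
  iterations are cheap.
* Negative template voxels (possible in reconstructed scans) are clipped to
  zero with a reported count, since the Poisson likelihood requires
  $m \ge 0$.
* There is no canonical $\beta$ or iteration count for phantom estimation;
  both are configuration with the defaults above, and the $\beta = 0$ path
  is exactly MLEM on $\theta$ (verified per-iteration against an
  independently coded dense-matrix MLEM in the tests).
* The template's effective FWHM for $H$ is a required input with no asserted
  default — it is a property of the scan used as template.

### Gaussian smoothing and its adjoint

$H$ is separable Gaussian convolution with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ converted to voxels per axis,
with a *renormalized* boundary: $S(x) = C(x)/C(\mathbf 1)$, where $C$ is
zero-padded convolution with a sum-normalized kernel. This preserves
constants everywhere and preserves total mass exactly for images supported
away from the edges — which keeps EM count-consistent, since brains sit in
the grid interior. $S$ is not symmetric near edges, so the package applies
the exact adjoint $S^{\mathsf T}(y) = C(y / C(\mathbf 1))$; the
forward/adjoint pair passes a 20-draw inner-product test at $10^{-6}$
relative tolerance, and a $6^3$ instance is checked against an explicitly
materialized dense operator.

## The simulation and reconstruction harness

To exercise a phantom end to end, the package includes a deliberately small
acquisition model (`scanner_model()`): independent 2-D parallel-beam slices,
an image-space shift-invariant Gaussian PSF (default FWHM 4.3 mm, the
centre-of-FOV resolution of a clinical PET-MRI system), attenuation factors
$a = e^{-\int \mu\,dl}$ from a 511 keV $\mu$-map (soft tissue 0.096 cm$^{-1}$
in the synthetic scenes; bone is out of scope), randoms and scatter folded
into a flat additive expectation (default 30% of the mean true expectation),
and Poisson counts at a target total. The projector is a sparse pixel-driven
matrix, so projector and backprojector are exact transposes. Full 3-D ring
geometries, time-of-flight, scatter physics and vendor normalization are out
of scope.

Reconstruction is MLEM, or guided MAP with a Bowsher-selected smoothed-Lange
prior: for each voxel the $k = 40$ neighbours most similar in the guide
image within a $5^3$ window get binary weight 1 (ties broken by spatial
distance, then a fixed offset order, so the selection is deterministic), and
the prior potential is the Fair/Lange function
$\phi(t) = \delta^2(|t/\delta| - \ln(1 + |t/\delta|))$ — quadratic below
$\delta$, linear above. The $\delta^2$ scaling is chosen so the gradient is
$t/(1+|t|/\delta)$ with the clean quadratic limit $\phi \to t^2/2$ as
$\delta \to \infty$ (checked in the tests against a directly coded
quadratic-prior run). The named presets `beta_preset("mild")` = 4e2 and
`"strong"` = 2e3 label two conventional regularization levels; in this
simplified desk-scale geometry the stable range is orders of magnitude
smaller (the sensitivity image is small while Bowsher row sums are ~80), so
the presets are labels, not calibrated equivalences — tests use
$\beta \approx 0.03$ for reconstruction.

## The synthetic scene generator

`generate_scene()` emulates all four inputs on a desk-scale grid with known
ground truth, so every stage is testable without downloads:

* **Geometry**: an ellipsoidal brain; tissue classes are nested shells
  (outer shell cortex-like, inner white-matter-like).
* **Atlas**: a Voronoi parcellation over in-brain seeds, blurred with
  $\sigma$ = 1 voxel into overlapping probability maps and kept $\le 1$ per
  voxel, like real probabilistic atlases.
* **Density**: $\exp$ of a smoothed white-noise field (correlation FWHM
  6 mm, log-SD 0.3) — strictly positive, textured.
* **Ground truth**: per-class base uptake on a geometric ramp from 4 down to
  1 (the conventional gray:white contrast of an FDG-like tracer) times a
  per-region lognormal multiplier (log-SD 0.25) — the large-scale
  heterogeneity the phantom must carry.
* **Template**: the generator's own forward chain,
  $\mathrm{Poisson}\{s \cdot \mathrm{smooth}(DTA\,\theta_{\mathrm{true}},
  6\,\mathrm{mm})\}/s$, at 100 expected counts per in-brain voxel by
  default (a clinical count level); the draw is rescaled back to activity
  units so $\theta$ keeps its true scale, and `noise_factor = 0` gives the
  exact noiseless chain.
* **Guide**: a tissue-contrast anatomy image with an independent smooth bias
  field and noise; `generate_mismatch_guide()` adds controlled boundary
  disagreement (translation, guide-only lesions, bias), quantified by a Dice
  score — so guided reconstruction can be tested both in the flattering
  matched regime and the realistic mismatched one.
  `generate_piecewise_phantom()` provides the classical piecewise-constant
  control with an exact 4:1 gray:white ratio.

**What the toy scenes do not emulate**: anatomical realism (gyri, sulci,
asymmetric structures), real histology statistics, MRI contrast physics, and
grid sizes beyond a few dozen voxels per axis. Passing tests therefore
demonstrate the *estimator's* correctness and the *qualitative* behaviour of
guided reconstruction, not quantitative performance on real data.

## Problem sizes used in the validation suite

The routine test and acceptance runs use $6^3$–$32^3$ grids at 2–3 mm,
3–8 regions and 1–2 classes for estimation checks, and a
$48 \times 48 \times 8$ stack with 72 angles for the reconstruction ordering
study — sizes chosen so the whole suite completes in about a minute while
every contract (adjointness, oracle equivalence, recovery, monotonicity) is
exercised at full precision. A 0.4 mm "showcase" configuration exists in
`scene_spec()` but is not part of routine validation.

## Known limitations

* OSL MAP-EM is only locally stable: for $\beta$ large relative to the
  sensitivity the iteration saturates its guard and oscillates rather than
  converging; the clamp count exposes this.
* The inter-region penalty couples *all* same-class regions (locality comes
  from the inverse-distance decay, not truncation); an optional neighbour
  cap exists for speed only.
* Probabilistic tissue maps are not supported (the tissue volume is
  hard-labelled), registration and resampling between grids are the caller's
  responsibility, and the pseudo-CT/µ-map synthesis used for real phantom
  datasets is outside the package — the synthetic µ-map is a two-level
  stand-in.
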