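# petphantom

Heterogeneous, radiotracer-specific digital PET brain phantoms in R.

## What it does, and for whom

Researchers evaluating PET reconstruction methods need digital phantoms that
are high resolution, heterogeneous within tissue classes, and specific to a
radiotracer — and whose activity boundaries do *not* coincide perfectly with
the anatomical image used to guide reconstruction, which is the flaw of
phantoms segmented from MRI. `petphantom` builds phantoms by fitting an
anatomically parameterized activity model to a measured tracer scan.

The activity model is

```
x̄ = H D T A θ
```

where `A` holds per-region probability maps of a parcellation atlas, `T` the
binary tissue-class masks of a classified volume, `D` the per-voxel cell-body
density, `H` a Gaussian kernel at the template's effective resolution, and
`θ` one uptake value per (region, tissue class) — 760 parameters for a
95-region atlas with 8 classes. `θ` maximizes the penalized Poisson
log-likelihood of a template scan `m`,

```
θ̂ = argmax  L(θ | m) − β U(θ),      U(θ) = Σ_j Σ_{k∈N_j} ξ_jk (θ_j − θ_k)²
```

(equivalently: minimizes Kullback–Leibler distance plus penalty), by
one-step-late MAP-EM. The penalty couples same-tissue-class regions with
inverse-centroid-distance weights and suppresses the unbounded drift of
small-region estimates that plain MLEM exhibits on this ill-posed problem.

The package also ships the surrounding workflow: phantom rendering at native
resolution plus a smoothed companion, a desk-scale PET acquisition simulator
(parallel-beam, 4.3 mm PSF, attenuation, flat randoms+scatter background,
Poisson counts), MLEM and Bowsher-guided smoothed-Lange MAP reconstruction,
and a synthetic scene generator with known ground truth so everything is
testable offline. See the methods vignette
(`vignettes/phantom-methods.Rmd`) for the model details and design choices.

## Worked example

Generate a synthetic scene (atlas, tissue classes, density, noisy template
with known ground-truth uptake), estimate `θ`, and render the phantom:

```r
library(petphantom)

spec  <- scene_spec(shape = c(24, 24, 24), n_regions = 3, n_classes = 2,
                    seed = 2)
scene <- generate_scene(spec)

op  <- system_operator(scene$atlas, scene$tissues, scene$density, fwhm_mm = 6)
fit <- osl_mapem(scene$template, op,
                 config = estimation_config(beta = 0, n_iter = 300))
glance(fit)
#> # A tibble: 1 × 9
#>   n_params  beta n_iter converged loglik    kl penalty objective n_clamped
#> 1        6     0    113 TRUE       2735.  193.      NA     2735.         0

tab <- tidy(fit); tab$theta_true <- scene$theta_true
tab[, c("region", "class", "uptake", "theta_true")]
#>   region   class   uptake theta_true
#> 1 region_1 class_1  6.61       6.60
#> 2 region_1 class_2  0.887      0.884
#> 3 region_2 class_1  3.05       3.03
#> 4 region_2 class_2  0.838      0.873
#> 5 region_3 class_1  5.04       5.05
#> 6 region_3 class_2  1.00       0.955
```

The fit converged in 113 iterations and the recovered uptake values match
the generator's ground truth to a few percent at the default clinical count
level (exactly, on a noiseless scene). Rendering and per-region QC:

```r
phantom <- render_phantom(fit, scene$atlas, scene$tissues, scene$density)
phantom
#> <phantom_volume> 24 x 24 x 24 voxels; total activity 17881.9
region_report(phantom, scene$atlas, scene$tissues, scene$density)
#>   region   class    mean    sd volume_ml
#> 1 region_1 class_1 6.46  2.07      23.5
#> 2 region_1 class_2 0.999 0.256      4.41
#> 3 region_2 class_1 3.44  1.18      24.2
#> ...
```

The per-region SDs are nonzero because the cell-body-density factor `D`
textures the activity inside each region — the heterogeneity a piecewise-
constant phantom lacks. `render_smoothed(phantom, fwhm)` produces the
companion volume, `write_volume()` saves NIfTI, and
`simulate_acquisition()` / `mlem()` / `map_lange()` take the phantom through
a simulated PET acquisition and (guided) reconstruction.

A command-line wrapper mirroring the workflow
(`make-scene → estimate → render → simulate → recon`) is installed at
`inst/cli/petphantom`; every run writes a provenance JSON with config, input
and output hashes, and seeds.

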