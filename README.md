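# synmorph

Phantom-validated 3D morphometry of the B-cell immune synapse.

When a B lymphocyte engages immobilised antigen (an antigen-coated bead or
a coated coverslip), it builds an immune synapse: the microtubule-organising
centre (MTOC) and lysosomes polarise toward the contact site and the lobed
nucleus rotates so that its principal groove faces the synapse. `synmorph`
implements the full set of 3D image-quantification procedures used to
measure that reorganisation from multi-channel confocal z-stacks, together
with a synthetic confocal scene generator that provides exact ground truth
so every measure is validated by parameter recovery.

**Measures** (one row per cell, exported as CSV + JSON profiles):

* groove orientation vs. the bead axis `θ = ∠(a−b, c−b)` with `a, b, c`
  the bead, cell and groove centres of mass, classed Polarized `[0°,45°]` /
  Central `(45°,135°]` / Antipolarized `(135°,180°]`; dish-geometry
  orientation and lobe-baseline rotation
* normalised groove depth `h / D` (farthest groove point from the apex
  baseline, over the cell Feret diameter) and groove cross-section area
* polarity indexes `PI = (‖Cellmc→Pj‖ signed) / ‖Cellmc→Beadmc‖ ∈ [−1, 1]`
  for the MTOC and for the LAMP1 intensity centre of mass
* LAMP1 ring fraction within 3.5 µm of the bead; lysosome-cluster
  inside/outside call vs. the perinuclear region
* normalised z-profiles (10 × 0.2 µm slabs from the synapse, summing to
  100) and Exo70 radial profiles (0–2 µm around the MTOC)
* lamin–actin overlap with 1-px erosion and 2-px dilation tolerance
* antigen-extraction percentage over bead time courses; surface-BCR MFI
* nuclear/actin volumes by 3D voxel counting

**Phantom**: a spherical cell with a 3–4-lobed nucleus (union of spheres
minus a groove-carving wedge with analytic apices and depth), bead, MTOC,
lysosomes, cortical actin and surface BCR, rendered with a Gaussian PSF,
Poisson shot noise and Gaussian read noise — deterministic per seed, with
every ground-truth quantity exact or quadrature-grade.

## Worked example

```r
library(synmorph)

cfg <- scene_config(groove_orientation = 30, mtoc_offset = 0.6,
                    voxel_size = c(z = 0.2, y = 0.15, x = 0.15),
                    stack_shape = c(z = 60, y = 88, x = 108), rng_seed = 7)
scene <- make_scene(cfg)         # analytic ground truth
stack <- render_stack(scene, cfg)
rec <- analyze_cell(stack, mode = "bead")
```

This prints, against a ground truth of 30° orientation, 0.25 normalised
depth, 0.6 MTOC offset and 185.7 µm³ nuclear volume:

```
groove_angle_deg      30.04
orientation_category  Polarized
groove_depth_norm     0.242
mtoc_polarity_index   0.595
nucleus_volume_um3    185.8
```

i.e. the pipeline recovers the configured scene to within its stated
tolerances (±2° orientation, ±0.03 depth, ±0.05 polarity). The full
simulate→analyze→recover grid is one call:

```r
validate(seed = 7, n_per_condition = 20)   # bias/RMSE per measure
```

Batch analysis of real stacks goes through a manifest:

```r
run_experiment(data.frame(stack_path = files, condition = "control",
                          mode = "bead"), analysis_config(),
               out_dir = "results/")
```

A thin command-line front end (`inst/cli/synmorph.R`) wraps the same
functions: `simulate`, `analyze`, `run`, `validate`.

## Package layout

* `R/phantom.R` — scene configuration, analytic ground truth, rendering
* `R/imgio.R` — TIFF/OME-TIFF stacks, measurement tables, YAML configs
* `R/segmentation.R` — masks, 3D components, morphology, overlaps
* `R/groove.R`, `R/morphometry.R` — the measures
* `R/pipeline.R` — per-cell orchestration, experiments, `validate()`
* `vignettes/synapse-morphometry.Rmd` — models, conventions, limitations
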