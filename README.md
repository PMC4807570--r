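# kescan

Dual-energy **K-edge subtraction (KES) micro-CT** analysis in R:
localize and quantify yttria (Y₂O₃) nanoparticle accumulation in plant
tissue from pairs of reconstructed tomograms acquired just below
(16.5 keV) and just above (17.2 keV) the yttrium K-edge (17.038 keV).

Across the K-edge, yttrium's attenuation jumps by a factor of ~5 while
everything else dims slightly, so the registered voxelwise difference

    Δµ(x,y,z) = µ₁₇.₂(x,y,z) − µ₁₆.₅(x,y,z)

lights up only the target element, and the simplified KES equation

    C [mg/cc] = 1000 · Δµ / (µ/ρ(17.2) − µ/ρ(16.5))

turns it into a voxelwise concentration map. The package is aimed at
beamline users and image-analysis people who want the full published
protocol — registration, signed subtraction, the five-threshold
morphological segmentation (26-connectivity dilation + mask
arithmetic), and concentration mapping — as tested, scriptable code,
validated end-to-end on synthetic dual-energy root phantoms with known
ground truth.

## What's inside

| Area | Functions |
|------|-----------|
| Attenuation physics | `mass_attenuation()`, `linear_attenuation()`, `transmission()`, `kedge_delta_mu_rho()` (embedded 10–25 keV tables for H, C, N, O, Ca, Fe, Zn, Y; mixture rule; log-log interpolation that never bridges an edge) |
| Synthetic phantoms | `phantom_spec()`, `build_root_phantom()`, `sample_particles()`, `apply_shrinkage()`, `add_noise()`, `fbp_roundtrip()` |
| Registration | `estimate_transform()` (phase correlation, sub-voxel), `resample_volume()` |
| Subtraction | `kes_subtract()`, `pixel_histogram()`, `crossing_threshold()` |
| Segmentation | `segmentation_params()`, `threshold_mask()`, `dilate26()`, `shift_artifact_mask()`, `segment_yttria()`, `label_regions()` |
| Quantification | `concentration_map()`, `region_stats()`, `dice_coefficient()` |
| I/O + pipeline | `read_stack()`/`write_stack()` (TIFF), `pipeline_config()`, `run_pipeline()`, `kescan_cli()` |

## Worked example

Simulate a small dual-energy root phantom and run the whole pipeline:

```r
library(kescan)
spec <- phantom_spec(shape = c(16, 64, 64), n_yttria_blobs = 3,
                     n_mineral_blobs = 2, seed = 5)
cfg  <- pipeline_config(output_dir = "demo_run", simulate = TRUE,
                        phantom = spec, seed = 5)
rep  <- run_pipeline(cfg)
```

which logs (real output):

```
[kescan] simulate     shape=16x64x64 yttria_voxels=2050
[kescan] register     t=0.05947,0.4592,-0.1034
[kescan] subtract     min=-6.8728 max=9.4802
[kescan] segment      final_voxels=2012
[kescan] quantify     regions=2
[kescan] score        dice=0.9906
```

Reading it: the phantom placed 2050 true yttria voxels and moved its
second scan by a known sub-voxel shift; registration recovered that
shift, the five-threshold protocol kept 2012 voxels in the final mask
(Dice 0.991 against ground truth), grouped into 2 connected
aggregates. `rep$concentration` reports min 47.7 / max 139 / mean
111 mg/cc over the mask — consistent with the simulated 44.12–132.35
mg/cc aggregate concentrations — and `demo_run/` holds every
intermediate (stage masks `mask_A.tif` … `mask_i.tif`, the signed
subtraction, the concentration map, histograms and region stats as
CSV, and `report.json`).

The worked numbers of the underlying study reproduce directly:

```r
kedge_delta_mu_rho()                                  # 68 cm^2/g
as.vector(concentration_map(array(3, c(1,1,1)), array(1L, c(1,1,1))))
# 44.11765  -> the published minimum, 44.12 mg/cc
as.vector(concentration_map(array(9, c(1,1,1)), array(1L, c(1,1,1))))
# 132.3529  -> the published display maximum, 132.35 mg/cc
mu <- linear_attenuation(yttria_compound(), c(16.5, 17.2))
mu[2] / mu[1]                                         # 5.612 K-edge jump
```

A command-line entry point covers the same stages
(`simulate`, `register`, `subtract`, `segment`, `quantify`, `run`):

```sh
Rscript -e 'kescan::kescan_cli()' run --simulate --out run_dir --seed 7
```

## See also

The methods vignette (`vignettes/kes-pipeline.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the phantom generator does and does not emulate, the
ambiguities in the published protocol and how they are resolved, and
the package's numerical conventions.
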