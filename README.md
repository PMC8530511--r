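# rpemorph

3D morphometry of epithelial flattening in the folding vertebrate eye.

During optic-cup formation the outer layer of the optic vesicle converts
into the retinal pigment epithelium (RPE): within a few hours its cells
flatten from columnar to squamous, the tissue thins several-fold while its
surface expands, and proliferation drops away. `rpemorph` turns 3D
fluorescence time-lapse stacks of a tissue reporter into the numbers that
describe this process, for developmental biologists quantifying epithelial
remodelling from confocal recordings.

The core measurements, all in physical units on anisotropic voxel grids:

- **Tissue volume** `V` — positive-voxel count × voxel size (µm³).
- **Tissue surface** `S` — the graph area of a second-order fit
  `x = f(y, z)` through the segmented tissue, integrated over its
  footprint (µm²).
- **Mean thickness** `t = V / S` (µm), valid while `t ≪ R` for tissue
  curvature radius `R`.
- **Growth kinetics** — OLS slopes of volume vs. time over stated windows
  (µm³/hr), endpoint fold changes, slope ratios.
- **Block decomposition** — 7 equal-width anterior–posterior blocks with
  exclusion of ciliary-marginal-zone-contaminated blocks from 20 hpf.
- **Whole-eye volume** — 3D convex hull of the eye channel, lens included.
- **Cell metrics** — shoelace apical areas, apico-basal lengths,
  contralateral normalization, invagination angle.
- **Proliferation index** — labelled / total nuclei per region, by centre
  lists or by connected-component segmentation of the channels.

Segmentation follows the reference processing chain: median filter →
white top-hat background neutralization → median-intensity cutoff. A
synthetic phantom generator (`generate_shell_stack`,
`generate_cup_sequence`, `generate_nuclei_stack`) renders shells, folding
cups and nuclei fields with exact analytic ground truth, so every stage is
testable without microscopy data.

## Worked example

Generate a clean shell phantom whose true thickness falls 24 → 8 µm
between 17 and 21 hpf, run the full pipeline, and compare with truth:

```r
library(rpemorph)

sp <- phantom_spec(shell_thickness_by_frame = c(24, 16, 8),
                   frame_times = c(17, 19, 21),
                   noise_sd = 0, background_ramp_amplitude = 0)
run <- run_pipeline(run_config(phantom = sp))
run
#> <rpe_run> 3 frames, 17-21 hpf
#>   thickness 23.93 -> 7.91 µm (truth 24 -> 8)
#>   full: slope -2.173e+04 µm³/hr

whole <- subset(run$metrics, block == 0)
whole[, c("time_hpf", "volume_um3", "surface_um2", "thickness_um",
          "true_thickness_um")]
#>    time_hpf volume_um3 surface_um2 thickness_um true_thickness_um
#> 1        17     129869        5428       23.927                24
#> 9        19      86362        5426       15.917                16
#> 17       21      42948        5427        7.914                 8

1 / fold_change(whole$thickness_um)   # flattening fold
#> [1] 3.023418
```

The measured thickness tracks the prescribed trajectory within 0.1 µm at
every frame, and the flattening fold exceeds 3 — the tissue-level
signature the pipeline exists to detect. The negative volume slope is the
phantom's construction (volume ∝ thickness at constant radius); per-block
metrics sit in the remaining `run$metrics` rows, and growth fits over
custom windows come from the `windows` argument of `run_config()`.

A thin CLI wrapping the same functions lives at `inst/cli/rpemorph.R`
(subcommands `phantom`, `segment`, `morpho`, `kinetics`, `cells`,
`prolif`, `run`).

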