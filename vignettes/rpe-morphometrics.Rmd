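---
title: "Quantifying epithelial flattening in the folding optic vesicle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial flattening in the folding optic vesicle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpemorph)
```

## The measurement problem

During vertebrate eye development the optic vesicle (OV), a bilayered
epithelial pouch, folds into the optic cup (OC). While the inner layer
bends to become the neural retina (NR), the outer layer converts into the
retinal pigment epithelium (RPE): its cells stop cycling, stretch in the
medio-lateral plane and collapse their apico-basal axis, turning a
pseudostratified sheet into a squamous monolayer within a few hours. The
question this package addresses is quantitative: given 3D fluorescence
time-lapse stacks of a tissue reporter, how thick is the tissue at each
time point, how fast do its surface and volume change, how deep is the
fold, and what fraction of its cells still proliferate?

The central operational definition is

> thickness = volume / surface,

with volume the count of positive voxels times the physical voxel size and
surface the area of a smooth sheet fitted through the tissue. For a curved
shell of mid-radius $R$ and thickness $t$ this estimator is exact to
second order: $V/S = t\,(1 + O((t/2R)^2))$, so it is trustworthy only
while $t \ll R$ — a limitation inherited by everything downstream and the
reason the validation phantoms keep $t/R \le 0.2$.

## Processing chain

A raw stack travels through four stages, each preserving grid geometry:

1. **Median filter** (`median_filter`): rank median, default 3×3×1
   voxels in-plane, honouring z anisotropy. The pipeline driver defaults
   to 5×5×3, which suppresses background speckle far more strongly at
   negligible cost to 10–40-voxel-thick tissue.
2. **Background neutralization** (`subtract_background`): white top-hat —
   the image minus its own grey-scale opening. The opening is the
   background estimate, so the structuring element (SE) must be *larger*
   than the widest bright structure that should survive: an SE smaller
   than the tissue deletes the tissue interior along with the ramp. The
   function default is a 15 px in-plane ellipsoid (adequate for nuclei
   and thin sheets); `run_pipeline` uses a 35 µm box SE, above the
   thickest (24 µm) tissue it measures, with the separable box shape
   chosen for speed at that size.
3. **Median-intensity threshold** (`median_threshold`): the median of the
   pooled intensities (whole series by default, per frame on request)
   becomes the cutoff; voxels strictly below it are background. Two
   refinements matter in practice. Exact-zero voxels are never signal,
   because tissue volume is defined over strictly positive intensities —
   without this rule a mostly-zero stack (median 0) would classify every
   voxel as tissue. And the statistic is computed inside an optional
   region-of-interest mask: the original workflow isolated the tissue
   semi-manually before measuring, and a pooled median is only a
   meaningful cutoff when foreground and background occupy comparable
   volumes. For phantom runs the ROI is the true mask dilated by 3 µm.
4. **Nuclear channels** additionally get a grey-scale closing
   (`close_nuclei`) to bridge gaps between nuclei, and the whole-eye
   channel a maximum → Gaussian blur → minimum chain (`hull_prefilter`)
   before convex-hull volume estimation.

All rank morphology runs in compiled code over explicit voxel-offset SEs
(ellipsoids or boxes defined in physical micrometres and converted per
axis), with reflective borders so flat regions stay flat at the edges.

## Tissue metrics

- **Volume** (`voxel_volume`): foreground count × $s_x s_y s_z$.
- **Surface** (`fit_surface`): $x$ is regressed on the full quadratic
  basis $\{1, y, z, y^2, yz, z^2\}$ over foreground voxel centres — a
  second-order fit in the hinge plane — and the area is the graph area of
  the fitted sheet over the mask's $(y,z)$ footprint,
  $\sum \sqrt{1 + f_y^2 + f_z^2}\; s_y s_z$. A flat slab returns its
  footprint area exactly; a plane tilted at 45° returns $\sqrt2$ times
  it; a shallow spherical cap (half-angle 20°) is recovered within 5%,
  and a triangulated-mesh quadrature of the same fit agrees within 1%.
  Collinear footprints raise a rank-deficiency error rather than a
  garbage area.
- **Thickness** (`tissue_thickness`): the guarded quotient.
- **Blocks** (`discretize_blocks`): the anterior–posterior extent of the
  z-projected foreground is split into 7 equal-width intervals and every
  voxel assigned by its x coordinate, so block volumes sum to the total
  exactly. "Equivalent" is read geometrically (equal width, not equal
  volume) because the point of the decomposition is to compare volumes
  between blocks. Once the ciliary-marginal-zone reporter turns on
  (default 20 hpf), the most anterior block is dropped, and from the
  following frame the two most anterior (`exclude_cmz_blocks`); the
  anterior direction is a mandatory setting for real data and fixed to
  +x by the phantoms.
- **Whole-eye volume** (`convex_hull_volume`): the 3D convex hull of
  foreground voxel centres, lens cavity included. No qhull binding is
  assumed: the hull is built incrementally after reducing the cloud to
  per-column extremes and per-slice 2D hull vertices, and the
  implementation is validated against analytic boxes, tetrahedra and a
  frozen reference volume computed independently for a fixed point set.

Growth kinetics are ordinary least squares of volume against time over
closed windows (`fit_growth_slope`, returning a classed fit with
`coef`/`predict`/`plot` methods), endpoint fold changes (`fold_change`)
and slope ratios (`slope_ratio`). No robust or weighted variants: the
trends being summarized are plain lines.

Cell-scale measurements are deliberately small and exact: shoelace polygon
areas with a simplicity check, Euclidean apico-basal lengths,
contralateral normalization, and the invagination angle via
`atan2(|u×v|, u·v)` — the numerically stable form of the normalized dot
product. `measure_cup_angle` operationalizes the manual angle tool on a
voxel cup: vertex at the deepest basal point of the central section, edge
vectors to the rim; its accuracy is limited by voxel size, so angles
within ~10–15° of 180° (indentations shallower than a voxel) are not
resolvable.

Proliferation scoring counts nuclei either from centre lists
(`count_positive_fraction`) or by segmenting the channels
(`segment_and_count`: threshold at the intensity midpoint, 26-connected
components, positivity when ≥ 50% of a component overlaps the thresholded
label channel). The 50% overlap default replaces a human judgement the
original counting made by eye; for non-overlapping nuclei any threshold
between 0 and 1 gives the same answer.

## The phantom generator

Every stage is validated against synthetic stacks with closed-form truth
(`phantom_spec`, `generate_shell_stack`, `generate_cup_sequence`,
`generate_nuclei_stack`). Defaults emulate the acquisition this pipeline
targets: voxel spacing (0.62, 0.62, 1.37) µm, frames every 0.5 hr from 17
to 21 hpf, tissue amplitude 100 over Gaussian noise (sd 5) and a linear
background ramp (amplitude 10) along x, intensities quantized to integers
as integer-valued formats do. The acquisition interval and intensity
calibration of the original recordings are not published; these values
are declared defaults, not inferences.

**Shell geometry.** The epithelium is a spherical-cap shell, opening
toward +x. For coverage ≤ 0.5 the cap is cut by the coaxial cylinder of
radius $R\sin\theta$ rather than by a cone: the mid-surface is then
exactly a graph over $(y,z)$ — the geometry the surface estimator assumes
— and, crucially, the mask footprint does not widen with shell thickness
(a cone cut inflates the fitted-surface area by roughly $t/R$, which
would corrupt the thickness estimator with an artefact of the phantom
rather than of the method). Truth volume uses the exact sphere–cylinder
closed form, truth surface the cap area $2\pi R^2(1-\cos\theta)$; both
agree with the solid-angle-fraction formulas within the $(t/2R)^2$
curvature factor, and the full-sphere case is exact.

**Cup geometry.** The whole eye is a solid sphere indented by a second
sphere (radius ratio 0.8) from +x. The indentation depth is solved so the
basal invagination angle matches the prescribed value, and the eye radius
is solved so the analytic eye volume lies *exactly* on the prescribed
linear trajectory — the default slope, 5.54×10⁴ µm³/hr from 17 hpf,
reproduces the whole-eye growth regime this pipeline is meant to
recover. A 180° frame renders the unfolded stage as a plain sphere with
collinear hinge points.

**Nuclei.** Spheres of radius 3 µm (sections show packed nuclei but no
sizes; 6 µm diameter is typical for these embryos) placed by rejection
sampling with a hard-core separation of one diameter plus a guard gap of
two voxels, so digitized nuclei can never touch under 26-connectivity.
Exactly `round(labelled_fraction × n)` of them — a seeded random subset —
appear in the labelled channel.

What the phantoms deliberately omit: optical point-spread, photobleaching,
intensity texture within the tissue, cell-resolved membranes, and the rim
involution cell flow. Passing tests therefore demonstrate that the
measurement chain recovers known geometry under realistic sampling and
noise — not that segmentation would survive the full optics of a real
microscope.

## Validation conditions and numerical choices

The headline recovery checks in the test suite run the *full* pipeline on
phantoms built to the reported trajectories: thickness 24 → 8 µm must
come back with a flattening fold above 3, a doubling true surface as a
fold of ≈ 2, prescribed growth slopes within 10%, and labelled fractions
of 49% and 70% exactly. The fold phantoms run without noise: their truth
fold is exactly 3, so the check is a pure geometry-recovery statement,
and any background-noise volume inflation — which hits thin frames
relatively harder — would turn it into a test of the noise level rather
than of the method. Noise robustness is covered separately (a noisy
shell must be recalled at ≥ 99%, slopes are fitted on noisy series, and
the slope estimator is shown unbiased over 1000 seeded replicates).

Problem sizes are chosen to keep the whole suite within a few minutes on
one CPU: recovery phantoms use grids of roughly 0.5–1 million voxels at
the native 0.62/1.37 µm spacing, unit-test fixtures far less; the
mid-radius default of 120 µm keeps $t/R \le 0.2$ over the whole 24–8 µm
trajectory so the thickness definition itself contributes < 1% error.

Other numerical choices, fixed once: ties at the threshold cutoff are
kept as foreground (only values strictly below the cutoff are zeroed);
block boundaries are half-open with the maximum closed; the quadratic
surface fit uses voxel centres in physical micrometres; structuring
elements include their origin; Gaussian kernels truncate at 3σ and
renormalize; all generators restore the caller's RNG state.

## Limitations

- The volume/surface thickness is a tissue average; it says nothing about
  per-cell shape, and it degrades for steep caps (coverage > 0.5) where
  the sheet is no longer a graph over the hinge plane.
- The median-intensity cutoff presumes a roughly balanced
  foreground/background mixture inside the analysis region; on sparse
  fields it must be combined with an ROI, exactly as the semi-manual
  original did.
- Hull volumes use voxel centres, so they underestimate by up to half a
  voxel per face — negligible at these grid sizes.
- The cup angle is measured in a single section, matching the manual
  protocol; no 3D solid-angle generalization is attempted.
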