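---
title: "Quantifying peripheral bone microstructure from CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripheral bone microstructure from CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Osteoporotic fracture risk depends not only on how much mineral a bone
contains but on how that mineral is arranged: whether the trabecular
(spongy) compartment is built from connected plates or from eroded,
disconnected rods, how thick and how far apart the trabeculae are, how
much of the network is oriented transversely to the loading axis, and how
thick and porous the cortical shell is. Modern whole-body CT scanners
reach an in-plane resolution of roughly 200 µm at the distal tibia, which
is *coarser than a single trabecula* (100–400 µm). Individual trabeculae
therefore appear as fuzzy, partial-volume structures, and any method that
binarizes the image before analysis throws information away. This package
implements a quantification pipeline built around that constraint: fuzzy
(membership-weighted) representations are kept as far into the analysis
as possible.

The pipeline starts from a calibrated density image and ends with ten
scalar measures per scan: eight trabecular measures — volumetric BMD
(Tb.vBMD, mg/cc), transverse-trabecular BMD (Tb.tBMD, mg/cc), network
area density (Tb.NA, mm²/mm³), mean plate width (Tb.PW, µm), thickness
(Tb.Th, µm), separation (Tb.Sp, µm), erosion index (EI), and structure
model index (SMI) — evaluated over an inner (60% peel) and an outer
(30–60% peel annulus) region at the 4–6% distal tibial site, plus
cortical thickness (Cb.Th, mm) and porosity (Cb.Poro) at the 14–16% site.

## Pipeline stages and the reasoning behind them

**Calibration.** CT intensities (HU) are mapped to bone mineral density
(mg/cc) by scanning a characterization phantom with rod inserts of known
density. `fit_density_calibration()` summarizes each rod by its mean HU
over a one-voxel-eroded rod region (the erosion discards partial-volume
rims) and fits ordinary least squares of known density on mean HU.
Out-of-range densities after calibration are kept; the membership ramp
downstream clamps instead, so no information is destroyed early.

**Isotropic resampling.** Scanners reconstruct anisotropic voxels
(e.g. 150 µm in-plane, 200 µm between slices). `resample_isotropic()`
interpolates onto an isotropic grid with a separable Lanczos windowed
sinc (window radius 4 voxels, rows renormalized so constants are exact).
Windowed sinc is the standard high-fidelity choice: for band-limited
content it is nearly lossless, which also matters for the rigid
realignment below.

**Anatomy frame.** All regions of interest are defined relative to two
subject-specific references so that the same anatomical tissue is
compared across subjects of different size and positioning: the distal
tibial *end plateau* and the *tibial axis*. The filled-in bone
(`fill_bone_volume()`: threshold, multiscale closing, largest connected
component, cavity fill) is traced slice by slice from proximal to distal;
the first slice whose cross-section contains a 2D hole (an enclosed
background region — the distal cup of the joint surface seen in cross
section) marks the transition, and the plateau is the slice just proximal
to it. The axial faces of the scan are treated as cut planes during the
cavity fill — a marrow cavity opened only through the top of the scan is
still interior. The axis is the mean-squared-error-optimal line through
the 60%-peeled filled bone proximal to the 8% site; it is fit through the
per-slice centroids of the peeled cross-sections (weighted by slice
size), because centroids of axial cross-sections lie on the shaft axis
even where the flat axial cuts truncate a tilted shaft obliquely —
fitting the raw voxel cloud instead picks up an end-cut bias of about a
degree at 10° tilt. When the fitted axis deviates from the grid axis the
volume is rigidly realigned with Lanczos interpolation, and the filled
mask is rotated alongside it rather than recomputed (re-filling after
rotation would let the now-oblique proximal cut break the cavity fill).

**Percent sites and peels.** Axial position is expressed as percent of
tibial length measured proximally from the plateau. The scan covers only
the distal ~10% of the bone, so the full tibial length cannot be measured
from the image; it is a configuration input (`tibial_length_mm`), with a
fallback estimate of 22% of stature. Radial position is expressed as
percent *peel*: on each realigned slice, voxels survive a p% peel when
their 2D distance to the cross-section boundary is at least p% of that
slice's maximum inscribed distance. The inner region is the 60% peel; the
outer region is the annulus between the 30% and 60% peels. Peeling by a
distance fraction (rather than an area fraction) makes the peel track the
cross-section's shape.

**Fuzzy membership and skeletonization.** Density maps to a bone
membership in [0, 1] by a clamped linear ramp between `marrow_ref`
(default 0 mg/cc) and `bone_ref` (default 800 mg/cc); with partial-volume
voxels the membership approximates the local bone occupancy fraction.
The trabecular network's medial representation is obtained by fuzzy
skeletonization: the fuzzy distance transform (FDT; shortest-path cost
weighted by the mean membership of each step) is computed over the
support, and the support is eroded in increasing FDT order, deleting only
simple voxels (the (26,6) topology-preserving test) and retaining
fuzzy-medial anchors. Ties in FDT are resolved deterministically by
linear voxel index, and an exact two-layer medial plane (both layers
tying in FDT with background on both far sides) is thinned to a single
deterministic layer. The result is a thin union of medial surfaces and
curves whose voxel count per volume gives Tb.NA.

**Tensor scale.** At each skeleton voxel, rays are cast to the fuzzy
boundary (membership 0.5 crossing, subvoxel interpolated) in 45
near-uniform hemisphere directions and their antipodes; each direction's
radius is the mean of the two one-sided distances (robust to the
half-voxel off-centering of a digital medial surface), and the
largest-fitting ellipsoid is recovered by least squares on its quadratic
form. Rays that graze the fuzzy boundary at shallow angles exit early and
would shrink the fit, so the fit is repeated after dropping the 40% most
negative signed residuals. Semi-axes are sorted `a1 ≥ a2 ≥ a3`; plate
width is `2·a2`, capped at twice `max_scale_mm` (default 3 mm) for open
plates. A voxel is plate-like when `a2/a3 ≥ 2`, rod-like otherwise. A rod
is longitudinal when its long axis lies within 45° of the tibial axis; a
plate is transverse when its *normal* lies within 45° of the axis (the
plate then spans the axial plane). The angular cutoff is configurable;
45° is the natural two-class boundary. Tb.tBMD divides the BMD mass in
transverse-classified structure by the full ROI volume, so the transverse
and longitudinal parts sum to the structural BMD and Tb.tBMD ≤ Tb.vBMD by
construction.

**Star lines.** Tb.Th casts 49 deterministic hemisphere directions
through every bone-phase voxel in the ROI, measures the bone-intercept
chord through the voxel in each direction, takes the minimum over
directions (the local plate thickness), and averages over voxels. Tb.Sp
is the same statistic on the marrow phase. The marching step is 50 µm
(≤ half a voxel), chords are capped at the ROI bounding-box diagonal and
a hit cap is reported. Inside the pipeline the marrow phase is restricted
to the trabecular compartment, so separation chords terminate at the
compartment boundary instead of escaping through the masked-out cortex.

**Digital topology.** Each skeleton voxel is classified from its local
topological numbers: the number of 26-connected object components among
its neighbors and the number of 6-connected background components in its
18-neighborhood. For classification the background count imposes no
face-adjacency requirement, because an oblique digital surface often
exposes its second side only through edge voxels of the neighborhood;
the stricter face-adjacent count is reserved for the simple-point test
during thinning, where the topological guarantee is what matters.
Residual border voxels are resolved by an iterated second pass that
absorbs staircase chains adjacent to surfaces into the surface-edge
class. The erosion index is the ratio of curve-like classes
(curve interior/edge, curve–curve junctions, profiles, isolated voxels)
to surface-like classes (surface interior/edge, surface junctions); the
composition is exposed as an argument because the classical literature
admits variants.

**Structure model index.** SMI = 6·V·S′/S², where S′ is the derivative of
surface area under simulated thickening. The offset surfaces are realized
through a subvoxel-accurate signed distance field: voxels straddling the
membership level set are seeded with their interpolated distance to the
crossing (per-axis crossings combined in Eikonal-consistent form) and the
distance is propagated by chamfer Dijkstra. The offset-body volume V(r)
is evaluated with a one-voxel linear smoothing kernel (turning the voxel
count staircase into a piecewise-linear estimate), a quadratic is fitted
to V(r) over ±3 voxels of offset, and V, S = V′(0) and S′ = V″(0) are
read off the fit. This is the same simulated-thickening derivative as the
classical triangulated-surface construction — parallel offset surfaces
along outward normals — realized through the distance field instead of an
explicit mesh, and it is exact in the analytic limits (4 for spheres, 3
for cylinders, 0 for plates). The wide fit range is needed because the
level-set wiggle of a voxelized surface (±0.1 voxel) otherwise
destabilizes the curvature term.

**Cortex.** At the 14–16% band the cortical shell is segmented by
thresholding (default 600 mg/cc), keeping the largest connected
candidate, and closing slice-wise across pores; enclosed low-density
components of at least 2 voxels form the pore mask. Cb.Th is the mean of
twice the slice-wise distance-transform value over the medial ridge of
the wall (cortex plus pores), which equals the local wall thickness for
tubes and averages correctly over wedge-shaped walls. Cb.Poro is the pore
volume fraction of the wall.

## The synthetic phantoms

All validation inputs are generated, never stored. Two aspects of the
generators matter for interpreting test results.

*Partial volume and band-limiting.* Geometry is evaluated in continuous
coordinates and voxelized with 3×3×3 subvoxel supersampling, so boundary
voxels carry occupancy-weighted densities; the distal-tibia phantom
additionally applies a Gaussian point-spread blur (σ = 0.1 mm,
comparable to the true resolution of the emulated scanner class). A
piecewise-constant phantom is not band-limited, and no interpolation can
make a rotation of it lossless; with the blur, rigid reorientation plus
windowed-sinc resampling is nearly information-preserving, which is the
regime real scans live in.

*Generic orientation.* The trabecular lattice of the tibia phantom —
longitudinal plates (0.45 mm thick, 1.5 mm pitch) crossed by transverse
rods (0.45 mm diameter, 0.9 mm axial pitch) — lives in a deliberately
oblique frame (18° about the axis, 12° off vertical) anchored to the
plateau. Real trabeculae are never aligned with the reconstruction grid;
an axis-aligned lattice would make the untilted phantom an idealized
special case that no reoriented scan of the same bone could reproduce,
and rotation-invariance comparisons against it would measure the
idealization, not the method. The axial rod pitch is kept well below the
2 mm height of the percent-site band so the lattice is homogeneous at
band scale. Densities are synthetic magnitudes on the calibrated scale
(trabecular bone 800, marrow 100, cortex 1200 mg/cc), not physiologic
claims. Default problem sizes (a 12 mm diameter, 26 mm long phantom at
150 µm voxels; structure phantoms of 6–10 mm extent) are chosen so the
full validation suite exercises every stage at realistic feature-to-voxel
ratios.

What the phantoms do *not* emulate: scanner noise power spectra, beam
hardening, motion artifacts, marrow heterogeneity, or the disordered
connectivity of real trabecular networks. Passing tests demonstrate
correct geometry, calibrated statistics and internal consistency — not
clinical accuracy on patient scans.

## Statistics layer

The validation statistics mirror a standard imaging-biomarker workup.
Accuracy against a reference modality is summarized by Pearson r and the
least-squares calibration line of reference on CT (`accuracy_calibration()`,
which therefore passes through the centroid of the pairs).
Reproducibility across repeat scans uses the one-way random-effects
single-rater ICC, `(MSB − MSW)/(MSB + (k−1)·MSW)`, with classical
F-distribution confidence bounds; repeat scans are exchangeable
replicates, so the one-way model is the appropriate variant. Group
comparisons use pooled-variance t-tests with Cohen's d defined as mean
difference over pooled SD — the pooled convention is forced by that
effect-size definition. Covariate-adjusted comparisons fit
`value ~ group + covariates` and compare least-squares means at equally
weighted covariate levels (the classical LSMEANS convention), with the
adjusted effect size as the LS-mean difference over the root MSE. Power
for the unbalanced two-sample design is exact noncentral-t with
noncentrality `d·sqrt(n1·n2/(n1+n2))`. No multiple-testing adjustment is
applied, matching the unadjusted reporting convention of pilot studies;
p-values are two-sided throughout.

## Known limitations

* **EI is fragile.** The erosion index is a ratio of minority topological
  classes. On ~10³-voxel skeletons its value moves by ±20% under rigid
  reorientation of the same structure, driven by staircase
  reclassification at plate rims and junctions, while the other seven
  trabecular measures stay within a few percent. This mirrors the
  measure's behavior in repeat-scan reproducibility studies, where EI is
  consistently the weakest of the panel. Treat small EI differences with
  caution.
* **Sphere-limit SMI carries a small curvature bias** (~0.05–0.1 at 12
  voxels radius) from the interaction of the quadratic fit with voxelized
  level sets; the cylinder and plate limits are much tighter. Scale
  stability is excellent for cylinders and plates; for spheres it is
  ~0.1.
* **Tensor-scale widths** are resolved to roughly half a voxel; rods at
  3 voxels diameter read ~10% narrow because grazing rays exit the fuzzy
  boundary early.
* **Skeleton tie-breaking** is deterministic by voxel index, so the
  skeleton of a rotated grid can select the adjacent tied medial layer;
  skeletons agree in size and to within one voxel of position, not voxel
  for voxel.
* The pipeline assumes one bone per volume (largest component); fibula
  separation beyond that, wrist anatomy, DICOM ingestion and scanner
  artifact correction are out of scope.
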