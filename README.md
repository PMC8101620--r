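# bonemicro

Quantitative assessment of peripheral cortical and trabecular bone
microstructure from volumetric CT, for researchers studying osteoporosis
and fracture risk at clinical scan resolutions.

At the distal tibia, whole-body CT resolves roughly 200 µm — coarser than
a single trabecula — so trabeculae appear as fuzzy partial-volume
structures. `bonemicro` implements an analysis chain built around that
constraint:

* **Calibration & resampling** — rod-phantom HU→BMD calibration
  (ordinary least squares of known density on mean rod HU) and isotropic
  windowed-sinc (Lanczos) resampling.
* **Anatomy-standardized ROIs** — filled-bone segmentation, detection of
  the distal end plateau (the slice just proximal to the first
  cross-section containing a 2D hole), mean-squared-error tibial-axis
  fitting with rigid realignment, percent-of-tibial-length site bands and
  percent-peel regions (inner 60% peel; outer 30–60% annulus), and
  randomly sampled spherical ROIs (7.05 mm ≙ 47 voxels at 150 µm).
* **Trabecular measures** — fuzzy skeletonization ordered by the fuzzy
  distance transform with topology-preserving (26,6) erosion;
  tensor-scale local ellipsoids for plate width `Tb.PW = 2·a2` and
  plate/rod and transverse/longitudinal classification; star-line
  thickness `Tb.Th` and separation `Tb.Sp` (minimum intercept chord over
  49 directions); network area density `Tb.NA`; digital topological
  classification with the erosion index `EI` (curve-like over
  surface-like class counts); and the structure model index
  `SMI = 6·V·S′/S²` from simulated thickening of the structure surface.
* **Cortical measures** — shell segmentation at the 14–16% site,
  medial-ridge wall thickness `Cb.Th` and pore volume fraction `Cb.Poro`.
* **Validation statistics** — accuracy calibration against a reference
  modality (Pearson r + least-squares line), one-way random-effects ICC
  with F-based confidence bounds, pooled-t group comparisons with
  Cohen's d, covariate-adjusted least-squares means with d = ΔLS/√MSE,
  exact noncentral-t power for unbalanced designs, and Spearman
  associations. Results are tibbles; fitted objects support `tidy()`,
  `glance()` and `autoplot()`.
* **Synthetic phantoms** — antialiased, band-limited generators for plate
  stacks, rod lattices, mixed lattices, spheres, hollow shafts with
  pores, and a distal-tibia-like phantom (cortical shaft, end-plateau
  cap, annular distal cup, oblique trabecular lattice, tiltable axis),
  each with analytic ground truth, plus simulated long-format measure
  tables with known effects.

## Worked example

Generate a distal-tibia-like phantom and run the full pipeline:

```r
library(bonemicro)

tp  <- make_tibia_phantom(seed = 2)
cfg <- pipeline_config(tibial_length_mm = tp$truth$tibial_length_mm,
                       marrow_ref = 100)
res <- run_pipeline(tp$volume, cfg)
res
#> <pipeline_result>
#> # A tibble: 3 x 11
#>   roi      tb_vbmd tb_tbmd  tb_na tb_pw tb_th tb_sp     ei   smi cb_poro cb_th
#>   <chr>      <dbl>   <dbl>  <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl>   <dbl> <dbl>
#> 1 inner       370.    80.4  0.762 1880.  424.  669.  0.135  2.78      NA NA
#> 2 outer       365.    77.2  0.855 1639.  402.  605.  0.116  2.78      NA NA
#> 3 cortical     NA     NA   NA       NA    NA    NA  NA     NA          0  1.22
```

Reading the inner-region row: mean density 370 mg/cc over the 60%-peel
core at the 4–6% site; 80 mg/cc of that is carried by transverse
trabeculae; the medial network presents 0.76 mm² of surface per mm³; the
mean tensor-scale plate width is about 1.9 mm (vertical plates are wide;
open plates saturate at twice the 3 mm scale cap); star-line thickness
424 µm matches the phantom's 450 µm plates to within a voxel, and the
669 µm separation sits between the lattice gaps; the low erosion index
(0.14) and an SMI near 2.8 describe a mixed plate/rod network. The
cortical row recovers the phantom's 1.2 mm wall with zero porosity (the
default phantom has no wall pores).

The statistics layer works on plain tibbles:

```r
tab <- simulate_measure_table(n_per_group = 200, k_replicates = 3,
                              sigma_between = sqrt(0.8),
                              sigma_within = sqrt(0.2), seed = 7)
icc_oneway(tab, unit_id, value)
#> <icc_result> ICC = 0.823 (95% CI 0.783, 0.858), n = 200 x 3

ttest_power(1.0, n1 = 9, n2 = 21)
#> [1] 0.6784
```

A thin command-line wrapper (`inst/exec/bonemicro`) exposes `run`,
`calibrate`, `resample` and `power` over the same functions.

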