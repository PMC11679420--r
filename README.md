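# olivescan

Canopy structure phenotyping for olive rows surveyed with a side-mounted 2D
line-scan LiDAR and a proximal multispectral crop sensor on a ground
vehicle. The package targets the question a grower's agronomist actually
asks after pruning: *how much canopy came off each tree, and can a cheap
mobile scanner measure it?*

It provides, end to end:

- a **synthetic orchard generator**: a parametric row of olive trees
  (trunks, primary branches carrying ellipsoidal foliage envelopes with
  known wood mass, mid-row reference markers), a **pruning operator** that
  removes whole branch units with known removed mass per canopy side, a
  seeded **ray-casting scan simulator** (270° sector, 0.33° resolution,
  0.05–10 m working range, one frame per 0.2 m of travel) in which foliage
  boundaries return with probability 1 − porosity, and a multispectral
  emulator with a saturating band response;
- **reconstruction**: polar → Cartesian conversion
  (x = r cos θ, y = h + r sin θ), pass assembly along the travel axis,
  reference-marker detection, least-squares pairing of the east and west
  passes into a common row frame, percentile ground removal, marker-based
  plant splitting, and layer-spread trunk/canopy separation;
- the four **apparent-volume estimators** used in mobile laser scanning
  studies, for a canopy point cloud of plant *i*:
  - slice-wise convex hull: `VCH_i = Σ_s Δw · A_c,s` with Δw = 0.1 m slices
    along the thickness axis and `A_c,s` the 2D hull area of slice *s*;
  - voxel occupancy: `VV_i = N_i · v` with `v = 1e-5 m³` voxels anchored at
    the cloud's minimum corner;
  - cylinder `VCY = π (DCL/2)² · HCL` and sphere
    `VSP = (4/3) π r³, r = mean(DCL, HCL)/2` simplifications;
- canopy **biometrics** HPL (max plant height), HCL (canopy height),
  HTL = HPL − HCL (trunk height), DCL (maximum horizontal caliper);
- **point-density profiles** (impacts · m⁻³): 0.4 m cubic bins along canopy
  height, and seven thickness sections of width
  `Wb = ((max_x − min_x)/2) / a`, `a = 3.5`, labelled E1 E2 E3 C W3 W2 W1
  across the row, with per-section density percentages;
- **vegetation indices** NDVI = (NIR−RED)/(NIR+RED) and
  NDRE = (NIR−RE)/(NIR+RE), sentinel-aware cleaning, per-side sampling
  (100 points per exposition), Pearson correlations with the |r| > 0.6 and
  p < 0.05 significance rule, and pre/post-pruning ANOVA + Tukey HSD
  comparisons with Bonferroni-corrected α and letter codes.

Everything is tidyverse-native: functions take a data frame of points
(`x`, `y`, `z`, `label`) first and return tibbles, result objects have
`tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

Simulate a ten-plant row, scan it from both sides before and after pruning,
and ask whether the change in apparent volume predicts the wood mass
removed:

```r
library(olivescan)

cfg <- pipeline_config(seed = 42)     # protocol defaults, varied pruning
bundle <- run_experiment(cfg)

bundle$volume_weight_correlations
#>          pair     r        p  n significant
#> 1 dVCH~weight 0.922 0.000148 10        TRUE
#> 2  dVV~weight 0.778 0.008079 10        TRUE
#> 3 dVCY~weight 0.846 0.002017 10        TRUE
#> 4 dVSP~weight 0.829 0.003030 10        TRUE

glance(bundle)$mean_weight_removed
#> [1] 12.27
```

Each row correlates the per-plant decrease of one volume estimator (NP − P)
with the true removed wood mass (kg) recorded by the pruning operator. All
four estimators track the removed mass (r ≈ 0.78–0.92 here), the regime
reported for field campaigns of this design; ~12 kg of wood came off the
average tree at the simulated pruning intensities.

The unpruned spectral summary lands in the expected proximal-sensing
regime — NDVI 0.628 ± 0.094 over the cleaned, per-side-sampled points —
and pruning shifts the indices slightly downward:

```r
bundle$spectral_summary[, c("variable", "mean_np", "sd_np", "mean_p", "letter_np", "letter_p")]
#>   variable mean_np  sd_np mean_p letter_np letter_p
#> 1      red  0.0706 0.0140 0.0779         a        b
#> 2 red_edge  0.2042 0.0288 0.2158         a        b
#> 3      nir  0.3161 0.0503 0.2932         a        b
#> 4     ndvi  0.6279 0.0938 0.5750         a        b
#> 5     ndre  0.2107 0.1164 0.1488         a        b
```

Per-plant biometrics, volumes and density profiles live in
`bundle$biometrics`, `bundle$density_height` and
`bundle$density_thickness`; `autoplot(bundle)` draws the volume
distributions by state, and `autoplot()` on a single profile reproduces the
height-density and thickness-percentage curves.

A thin command line mirrors the pipeline
(`inst/cli/olivescan.R <simulate|reconstruct|analyze|run> --config cfg.yaml
--out dir`), composing to the same outputs.

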