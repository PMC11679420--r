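---
title: "Canopy phenotyping from mobile LiDAR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy phenotyping from mobile LiDAR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivescan)
```

olivescan quantifies the structural change pruning causes in an olive row,
from the viewpoint of two vehicle-mounted proximal sensors: a 2D line-scan
LiDAR that sweeps a 270° fan perpendicular to travel, and an active
multispectral crop sensor. Because field campaigns of this kind rarely
deposit their raw scans, the package pairs every analysis step with a
synthetic-data generator that produces the same kind of data *with known
ground truth*, so each estimator can be validated against the quantity it
claims to measure. This vignette records the models, the parameters that
matter, and the choices made where the design was genuinely open.

## The scene model

A scene is one row of `n` olive trees at fixed spacing (defaults: 10 plants,
5 m apart, 6 m between rows). Each plant has

- a cylindrical trunk (radius 0.12 m) whose height is the crown base,
  drawn from N(0.7 m, 0.08 m) and clamped to [0.4, 1.0] m;
- a total height drawn from N(3.5 m × vigor, 0.3 m), with cultivar presets
  (`san_francesco` 1.08, `piangente` 0.96, `scarlinese` 0.96) whose vigor
  multipliers average to 1 so the row's expected height equals the
  configured mean;
- three primary branches, each carrying three *branch units*. A unit is a
  straight wooden axis plus an ellipsoidal foliage envelope centered 80% of
  the way along it, with semi-axes (0.50, crown-depth, 0.42) × branch
  length. The leader unit of each primary is sized so its envelope top
  reaches the plant height; secondary units are 60–95% as long. Units fan
  out across their primary's azimuthal sector so the envelopes tile the
  crown rather than piling up at its center — this matters for the
  correlation design discussed below. Envelope centers are clamped so
  canopies neither close over the inter-plant gap (where the reference
  markers stand) nor reach the sensor path ~3 m from the row axis, which is
  how such rows are actually managed.

Each unit has a wood mass from a deliberately simple allometry,
`mass = ρ · L · π (0.019 L)²` with ρ = 800 kg m⁻³, i.e. mass ∝ L³. Since an
envelope's volume is also ∝ L³, removed mass and removed foliage volume are
proportional *per unit*; with envelopes that overlap little, the same holds
approximately for whole pruning removals. That proportionality is the point
of the generator: the experimental design correlates volume change against removed
mass, and a generator in which the two were decoupled could not validate
the analysis. Defaults give ≈37 kg of primary-branch wood per tree, so the
default removal fraction of 0.25 takes off ≈9 kg — the magnitude reported
for mature trees pruned after a skipped year.

Pruning removes whole units, preferring the most thickness-protruding and
lowest-attached ones (what a pruner cuts when crowns push into the
inter-row), stopping at the prefix of the removal order whose cumulative
mass is closest to the target fraction. The tie-break jitter is drawn
before any early exit so the removal order is identical across intensities
under one seed; removals are therefore nested, which gives the documented
monotonicity (weight never decreases, post-pruning true volume never
increases, with intensity). True crown volumes before and after use the
*same* Monte-Carlo point sample per plant (20 000 points, per-plant derived
seed), so the after ≤ before inequality holds by construction rather than
within sampling error.

## The scan model

At each record station (every 0.2 m of travel) the simulator casts one ray
per angular step (0.33°) across the 270° sector, oriented so the blind 90°
faces away from the row; angle 0 is horizontal toward the row, +90 straight
up. Ground, trunks and marker targets are opaque. Foliage interacts only at
envelope boundaries: each boundary crossing is accepted with probability
1 − porosity, independently. Because acceptances are independent, "first
accepted surface along the ray" is exactly "minimum-range accepted event",
which the implementation exploits to stay fully vectorized per station. A
porosity of 0.25–0.5 (cultivar presets) produces both surface returns and
interior returns behind the first boundary, the behaviour that makes
voxel-based volumes differ from hull-based ones on real crowns.

Ranges get truncated Gaussian noise (σ = 0.01 m) and are clipped to the
working range [0.05, 10] m; beams with no accepted in-range hit record the
sentinel −1, keeping every frame rectangular. Scan frequency (15 Hz) and
speed (1.38 m s⁻¹) are carried as metadata only: the 0.2 m record spacing
already encodes the kinematics, and modeling them separately would add
parameters without changing any measurable geometry.

The reference markers — a 1 m pole topped by a 0.2 × 0.2 m square — are
modeled with the square as a thin vertical panel facing the scanner,
spanning 0.2 m along the row. At the default record spacing at least one
station intersects each panel, which is what makes the markers reliably
detectable; a horizontal board seen edge-on from the side would not be.

## Reconstruction

Polar frames convert by `(r cos θ, h + r sin θ, z)` in the pass-local
frame. Marker detection looks for point clusters whose top lies in
[0.8, 1.3] m, with horizontal extent ≤ 0.35 m, isolated from crown points
by ≥ 0.5 m along the row. Pairing maps the west pass so its markers sit at
x = 0, mirrors the east pass onto negative x, and shifts it along the row
by the least-squares marker correspondence; the achieved residual is
recorded and warned about above 0.1 m. No iterative registration is used:
the pole method is the point of the protocol, and on simulated data it
aligns to machine precision.

Ground removal fits the ground level as the 5th percentile of height in
1 m windows along the row and drops points within 0.15 m of it; points at
or above 0.5 m are never touched, so crown bases (≈0.7 m) are safe even in
windows where the crown dominates. Plant splitting cuts at marker
positions (half-open on the left, so a boundary point joins the lower-z
plant), with a 0.2 m count-histogram fallback when no markers exist.
Trunk separation walks 0.1 m layers upward from the cloud bottom and keeps
layers whose RMS horizontal spread about the trunk axis stays below
0.3 m — a deterministic, trainable-free stand-in for interactive
multi-scale classifiers, adequate for simulated and typical field rows. A
crown-only cloud has a wide bottom layer and yields an empty trunk.

## Volume estimators and their numerics

The slice-hull estimator slices along the thickness axis (x). The
projection plane is therefore (y, z); "slices following the plant's width"
could also be read as slicing along the row, so the axis is a parameter —
on near-axisymmetric crowns the difference is small. Slices are half-open,
anchored at the cloud minimum, with the closing boundary folded into the
last slice; degenerate slices (< 3 affinely independent projected points)
contribute zero area rather than erroring, because thin crown edges are
expected, not exceptional. Hulls come from `grDevices::chull` with a
shoelace area.

The voxel estimator anchors its cubic grid at the cloud's minimum corner:
deterministic and translation-covariant per plant. Points exactly on the
far faces fold into the last voxel, so a cube sampled on a corner-aligned
grid occupies exactly (side/voxel-side)³ voxels. Both estimators accept an
optional fixed `origin`. That matters for one property: with the default
data-dependent anchor, deleting points moves the anchor, and a shifted
grid or re-anchored slices can *increase* the count or summed hull area on
adversarial configurations. Monotonicity under point deletion — the
property the tests assert — is well-posed under a common grid, so the
monotonicity tests fix the origin at the original cloud's minimum corner.

Heights use true minima/maxima of the points, as "maximum height" means;
no percentile trimming is applied by default. The sphere radius averages
canopy diameter and canopy height; whether plant height also belonged in
that average is not decidable from the protocol wording, so the measurement
set is exposed as a parameter.

## Density profiles

Height profiles use 0.4 m cubic bins anchored at the canopy's minimum
corner; density is count / 0.064 m³. Per height layer the package reports
the mean over *occupied* bins only (a flag restores all-bin averaging):
crowns are horizontally asymmetric, and averaging over the full bounding
slab would dilute layer densities by however much empty box the bounding
geometry happens to include. Thickness profiles split the x range into
2a equal sections (7 at the default a = 3.5, labelled E1–E3, C, W3–W1 from
east to west, +x being west). Each section's volume uses its own points'
y and z extents, floored at 0.01 m so single-point sections stay finite;
empty sections report zero density. Percentages normalize by the total
density, and the tests hold their sum to 100 ± 1e-6.

## Spectral emulation and statistics

The emulator traces one horizontal view ray per station at sensor height
and accumulates `D = Σ chord × (1 − porosity)` through the envelopes. Bands
follow a saturating response in `u = exp(−kD)`: NIR = 0.1 + 0.35(1 − u),
RED = 0.03 + 0.1u, and an intermediate red edge 0.13 + 0.19u, each with
multiplicative log-normal noise (σ = 0.12); stations seeing no crown emit
the negative sentinel that the cleaning rule later drops. The rate k is the
one deliberately calibrated constant: k = 0.20 m⁻¹ places the default
scene's cleaned samples at NDVI ≈ 0.63 ± 0.09 (and NDRE ≈ 0.23,
NIR ≈ 0.32, RED ≈ 0.07), the regime reported by the field instrument this
emulates. It was set once against the unpruned default scene and is not a
fitting knob. One caveat the synthetic data makes visible: at kD ≈ 0.9 the
response is *not* deeply saturated, so simulated pruning shifts the indices
detectably — field NDVI over dense mature crowns saturates more strongly
and showed almost no pruning response. Passing tests on the emulator
therefore validate the index arithmetic, cleaning, sampling and test
machinery, not the claim that real NDVI is pruning-insensitive.

Cleaning drops samples with any negative band, then samples with an index
outside [0, 1]; it is order-preserving and idempotent. Sampling retains
100 points per canopy side (all of them, with a warning, when fewer exist).
Pearson correlations report the exact-t p-value and the field significance
rule (|r| > 0.6 *and* p < 0.05). Pre/post comparisons pool points per
treatment (a per-plant-blocking design would also be defensible; pooling
matches the reported tables and is the default), run one-way ANOVA plus
Tukey HSD at a Bonferroni-corrected α, and assign letter codes. The
normalizing pre-transform is an explicit hook (identity default, log and
rank provided) rather than a silently applied ladder of powers whose
parameters would otherwise have to be invented. With two groups Tukey's
HSD reduces to the two-sample ANOVA comparison, which the tests verify
against brute-force oracles.

## Problem sizes and determinism

Defaults reproduce the survey conditions: 10 plants over 50 m, 251 stations
per pass, 819 beams per station (~205 000 rays per pass), two passes per
state and two states. A full `run_experiment()` takes a few seconds; test
and acceptance runs use the same defaults, with smaller rows (2–4 plants)
where only mechanics are under test. Every stochastic stage takes a seed;
per-stage seeds derive from the master seed, and re-running any operation
with the same inputs and seed is bit-for-bit identical. The Monte-Carlo
truth volumes use 20 000 points per plant, enough for the ~1% relative
error that the before/after comparisons need.

## Known limitations

- Foliage is a union of ellipsoids with boundary-only interaction: no
  leaf-level geometry, no beam divergence, no multiple returns.
- Radiometry is minimal: no BRDF, sun angle or mixed pixels; the spectral
  emulator supports method validation, not instrument simulation.
- The trunk separator assumes a single near-vertical trunk per plant.
- Crown diameters in the default scenes run slightly below the widest
  field-grown crowns because envelopes are clamped away from the sensor
  path; all estimator comparisons are unaffected, but absolute VCY/VSP
  magnitudes sit below the widest field tables.
- GNSS error, vehicle dynamics and multi-row mosaics are out of scope; the
  along-track coordinate is taken as exact.
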