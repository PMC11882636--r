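---
title: "Methods: quantifying punctate aggregates and double-positive neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying punctate aggregates and double-positive neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaquant)
```

## What the package measures

punctaquant implements two image-quantification pipelines used in
neuropathology of misfolded-protein disease models, plus the scalar
statistics usually reported alongside them.

The **3D aggregate pipeline** measures the burden of punctate protein
aggregates (such as misfolded SOD1 visualized with conformation-specific
antibodies) in confocal stacks of brain tissue. Aggregates appear as
bright blobs 0.3–3 µm in equivalent diameter; the quantities of interest
are the total aggregate volume as a percentage of the analyzed tissue
volume, the per-aggregate volume distribution, and the split of aggregate
volume inside versus outside neuron cell bodies (for example
tyrosine-hydroxylase-positive dopamine neuron soma). Cell bodies are
segmented manually by tracing a region of interest on a subset of slices;
the package interpolates the remaining slices.

The **2D counting pipeline** automates double-positive motor-neuron
counting in two-channel projected images of spinal cord: nuclei are
segmented in a nuclear-marker channel (ISL-1), each nucleus is expanded
into a perinuclear zone proportional to its own Feret diameter, and a
neuron is counted when the mean intensity of a cytoplasmic marker (ChAT)
in that zone exceeds the background level. Counts are normalized per mm
of cord from the section-series geometry (50 sections of 30 µm span
1.5 mm).

The **derived statistics** are small, exactly specified computations:
replicate-averaged Cu:Zn metallation ratios with a 3×LOD retention rule,
dopamine turnover (HVA/dopamine), the percentage of α-synuclein
phosphorylated at S129, enzymatic activity per unit protein, neuron
density and percent-of-reference, Cronbach's α for interrater
reliability, and extreme-value exclusion by 3×IQR fences.

Because raw microscopy from such studies is rarely deposited, the package
ships a **synthetic-image generator** that produces stacks and image
pairs with exactly known ground truth, so every stage has a recovery test.

## Coordinate and calibration conventions

All indices are 0-based in file formats and documentation; arrays follow
(z, y, x) / (y, x) axis order with z the slice axis. Voxel `i` covers the
half-open interval `[i, i+1)` times the spacing, with its center at
`(i + 0.5) · spacing`. Physical spacing `(dz, dy, dx)` in µm is mandatory
for volumes — it travels in a JSON sidecar next to each TIFF rather than
in TIFF tags, which keeps the convention independent of TIFF dialects.
Non-integer imagery is stored as 32-bit float scaled into [0, 1] with the
scale recorded in the sidecar; integer imagery round-trips exactly.

## The 3D aggregate pipeline

1. **Threshold** — a voxel is foreground iff intensity ≥ t. Thresholds
   are per image, mirroring practice with variable staining and
   illumination: the operator (or a config map) assigns one threshold per
   captured region. For unattended runs on synthetic data the midpoint of
   background and object intensity is the natural choice; `yen_threshold()`
   offers an automatic alternative.
2. **Label** — 3D connected components. Default connectivity is 26
   (faces, edges, corners), the more inclusive and most common choice for
   bright blob detection; 6 and 18 are available. Labels are assigned in
   raster-scan order of each component's first voxel, so labeling is
   deterministic and relabeling cannot change summaries.
3. **Measure** — volume is `voxel_count × dz·dy·dx`; no resampling to an
   isotropic grid is ever done (interpolation would distort volume
   totals). The equivalent spherical diameter is `(6V/π)^(1/3)`.
   Components straddling the soma boundary are split voxelwise between
   inside and outside, so `inside + outside = volume` holds exactly for
   every record; a whole-object assignment could not produce a
   "proportion inside and outside" for straddlers.
4. **Summarize** — `percent_volume = 100 × total / analyzed_volume`,
   where the analyzed volume is the full extracted subvolume extent times
   the voxel volume (no exclusion of unstained voids — whether voids
   should count is not decidable from the imagery itself). With zero
   components the mean component volume is reported as `NA`, not 0.

An optional equivalent-diameter window (default off) restricts reporting
to a size range, e.g. the 0.3–3 µm range in which such aggregates are
observed; on noisy stacks it also removes single-voxel noise components,
whose equivalent diameter (~0.18 µm at 0.1×0.1×0.3 µm voxels) falls below
any real aggregate. For noisy unattended runs `quantify_stack()` can
additionally apply a light Gaussian pre-smoothing (about half a voxel per
axis); this is standard confocal practice and stabilizes the threshold
crossing without measurably biasing totals.

## Trace interpolation

Manual traces on every second slice are turned into a dense mask by
shape-based interpolation: each untraced slice between traced slices
`z0 < z1` is the zero-superlevel set of the linear blend
`(1−w)·D0 + w·D1` of the signed Euclidean distance transforms of the
bounding traces, `w = (z−z0)/(z1−z0)`. This is the standard deterministic
choice that handles topology changes gracefully; the commercial package
used in the original workflow does not document its algorithm, so only
this contract — not bit-equivalence with any particular tool — is claimed.

Numerical details that matter:

* Signed distance is positive inside, measured in pixel units, with the
  zero level placed at the **half-pixel boundary** between foreground and
  background pixel centers (`d − 0.5`). Without this offset every
  interpolated slice inflates by roughly 0.4 px, which is visible as a
  systematic Jaccard loss at soma scales.
* Ties at the zero level count as inside.
* A slice that is empty (or full) in a trace gets a constant
  pseudo-distance of ∓(image diagonal), so shapes shrink or grow
  progressively toward it rather than failing.
* Traced slices pass through unchanged; slices outside the traced range
  are empty. Correcting a badly interpolated slice is expressed by adding
  that slice as an extra trace and re-interpolating.

On z-linear shape families at soma scale (disk radii 10–22 px), sparsify
at step 2 then interpolate recovers every slice with Jaccard ≥ 0.95 (a
z-constant cylinder round trips exactly). At radii of ~5 px lattice
quantization alone costs ~10% IoU; traced structures that small would be
traced on every slice in practice.

## The 2D counting pipeline

The chain reproduces the published operator sequence with each step an
exported, separately tested function:

* `enhance_contrast()` clips at the `f/2` and `1−f/2` order statistics
  (default f = 0.2%) and rescales to [0, 1].
* `rolling_ball()` subtracts the grayscale opening by a non-flat
  hemispherical structuring element (radius 100 px by default). Radii
  above 32 px use block-minimum shrinking with bilinear restoration, the
  standard acceleration for this filter; `shrink = 1` forces the exact
  computation, which the tests compare against a brute-force opening.
  A radius exceeding both image dimensions degenerates to a flat
  background at the global minimum.
* `yen_threshold()` maximizes the entropic correlation criterion
  `TC(t) = −ln[(Σ_{i≤t} p_i²)(Σ_{i>t} p_i²)/(P(t)²(1−P(t))²)]` over a
  256-bin histogram and returns a bin edge, ties toward the lower
  threshold.
* `binary_cleanup()` fills background components not connected to the
  border (4-connected) and erodes once with a 3×3 square — the minimal
  reading of "fill holes and erode".
* `analyze_particles()` keeps 8-connected components with area ≥ 0.5
  (µm² when a pixel size is supplied, px² otherwise — the ambiguity of
  the original tool's convention, so the unit used is recorded) and
  circularity in [0.1, 1].
* `expand_by_feret()` dilates each nucleus by a Euclidean disk of radius
  `round(0.25 × Feret)` px. The proportionality constant is not published;
  0.25 creates a perinuclear annulus on the order of a soma's extent
  without merging neighbors, and is config-exposed.
* `call_positives()` averages the second channel over the full expanded
  zone (not the annulus only — also config-reachable by measuring on a
  zone minus the particle) and calls a neuron positive iff that mean is
  **strictly greater** than `background + k·sd` (default k = 0, the
  literal "above background"). Under noise a halo-free nucleus has a zone
  mean exactly at background, so k = 0 becomes a coin flip; the noisy-data
  configuration uses k = 2 with the background sd measured in the
  background box.
* `estimate_background()` automates the by-eye choice of a background
  area: on a seeded subset of images (default 30%) a 500×500 px box
  (shrunk to fit small images, with a warning) slides on a half-box grid
  and the minimal-mean box is taken; the mean of the per-image means is
  the level, and the pixel sd within the chosen box supplies the sd for
  the k-margin.
* `normalize_per_mm()` divides by `n_sections × thickness / 1000` mm.

**Perimeter and circularity.** The circularity gate is the one place
where the perimeter estimator decides the outcome: pure pixel-edge
counting overestimates a digitized disk's perimeter by ~27% (circularity
0.62, failing the 0.8–1 expectation for round nuclei), while
boundary-step and Crofton-type estimators under- or over-shoot thin
1-px structures enough to let them pass the 0.1 gate. The package
estimates perimeter as the length of the convex hull of the component's
pixel-corner points (equivalently Cauchy's mean caliper width). For a
digital disk of radius 10 this gives circularity ≈ 0.92, and for a
1×30 px line 0.098 — both on the intended side of the gates. The
estimator is exact for convex particles and a lower bound for concave
ones, a benign bias when gating round nuclei. The Feret diameter uses the
same corner convention (max pairwise corner distance, computed on the
hull), so a single pixel has Feret √2 px.

The display-range rescale sometimes applied to the cytoplasmic channel
(e.g. clip to 50–700 and rescale) is implemented but off by default: its
computational role in the original workflow is unclear, and applying a
monotone rescale before a mean–background comparison changes calls only
through the background estimate, which is measured on the same rescaled
image.

## The synthetic generator: what it emulates and what it does not

`generate_aggregate_stack()` rasterizes an ellipsoidal soma (default
semi-axes 4×7×7 µm, the scale of a dopamine neuron cell body) and
spherical aggregates with diameters drawn uniformly from 0.3–3 µm — the
observed size range — on an anisotropic grid with 0.3 µm z-step. The
z-step matches the published imaging protocol; the lateral pixel size of
the original 60× images is not published, so the default of 0.1 µm is a
typical value for such optics and is configurable, not a claim about the
study. Objects are rasterized by center-of-voxel inclusion so the truth
volume is exactly countable; placement enforces a >1-voxel gap so truth
objects are never 26-adjacent. Aggregates are placed wholly inside or
wholly outside the soma according to `inside_fraction`; the per-object
inside volume is nevertheless computed voxelwise from the noise-free soma
mask, so straddling configurations would be measured correctly too.

Optional degradations: separable Gaussian blur (a cheap PSF stand-in),
Poisson shot noise, and additive Gaussian noise, all off by default so
exact tests stay exact. The default stack is 32×192×192 voxels
(9.6×19.2×19.2 µm) with 20 aggregates — large enough for stable
percent-volume statistics, small enough that the full suite runs in under
a minute per stack.

The blurred test condition uses an isotropic PSF of σ = 0.1 µm (one
lateral voxel). On the anisotropic grid "one voxel" per axis would mean
an axial σ of 0.3 µm, which renders 0.3 µm objects sub-resolution — no
threshold recovers them, and recovery errors reach −40% on
small-object-heavy draws. That regime is a physical resolution limit,
not a software property, so it is not part of the recovery contract.

`generate_spinal_image()` draws non-overlapping nucleus disks (radius
6 px) and, for exactly `round(fraction × n)` of them, a surrounding halo
annulus in the second channel above a flat background. Noise is additive
Gaussian on both channels. The noisy test condition sets σ to 10% of the
halo contrast.

Neither generator simulates optical sectioning physics, spectral
bleed-through, chromatic shift, tissue autofluorescence, or uneven
illumination. Passing recovery tests therefore demonstrates that the
measurement chain is correct and stable under blur and sensor-like noise
— not that it is robust to every artifact of real tissue imaging; the
per-image manual threshold exists precisely because real illumination
varies.

## Derived statistics: conventions

* **3×LOD retention** is strict: a value at exactly 3×LOD is dropped
  ("above" is read literally).
* **Cu:Zn** averages per-replicate ratios (mean-of-ratios) because a
  reported sd of ratios requires per-replicate ratios; ratio-of-means is
  available via `method`. Replicates with zero zinc are excluded with a
  warning. A fully metallated dimer (two Cu, two Zn) gives exactly 1.
* **Cronbach's α** treats raters as items:
  `α = k/(k−1) · (1 − Σ s²ᵢ / s²_T)` with sample variances over rated
  images. α ≤ 1 always, with equality iff raters agree up to additive
  constants; zero total variance is an error, not a value.
* **Extreme values** use fences `Q1 − 3·IQR` / `Q3 + 3·IQR` with
  linear-interpolation quartiles (`stats::quantile` type 7) — the
  documented convention that makes the fences reproducible. Values at a
  fence are excluded (the rule is ≥), except in the degenerate IQR = 0
  case where the fences collapse onto the data and equality is retained,
  so constant samples lose nothing. The alternative ±2 sd rule is
  available via `rule = "sd"`. Fewer than four values pass through with a
  warning.

## Problem sizes and determinism

All randomness flows from a single integer seed per generator call
(Mersenne-Twister with fixed normal/sample kinds), so identical
(config, seed) pairs are bit-identical. The test suite uses 10×10×10
volumes against brute-force labeling oracles (100 replicates), 64×64
images against a brute-force grayscale opening, 8–256-bin histograms
against an exhaustive Yen scan (100 replicates), default-size synthetic
stacks for recovery, and 20 seeded replicates for the noisy counting
condition; these sizes give stable statistics while keeping the default
suite under a minute of compute. `scripts/acceptance.R` recomputes the
same quantities from scratch at the same sizes.

## Known limitations

* The interpolation contract is the stated signed-distance blend;
  equivalence with any specific commercial implementation is not claimed.
* The hull-based perimeter underestimates for strongly concave particles;
  circularity is accordingly optimistic for such shapes.
* Volume percent recovery under blur assumes objects at or above the
  lateral resolution; sub-resolution objects are systematically lost by
  any threshold-based measurement.
* The background box search assumes the image contains at least one
  box-sized region free of signal; images saturated with staining would
  bias the background upward.
* `analyze_particles()` measures plane geometry only; overlapping nuclei
  merged by projection are counted once, as in the original procedure.
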