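---
title: "Quantifying intracytoplasmic membrane localization from BChl autofluorescence"
author: "icmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracytoplasmic membrane localization from BChl autofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmap)
```

## The measurement problem

Purple nonsulfur bacteria harvest light with an intracytoplasmic membrane
(ICM) whose photosystems contain bacteriochlorophyll a (BChl). BChl is
autofluorescent, so ICMs can be imaged in live, genetically untouched
cells. Two qualitatively different localization phenotypes occur among
these organisms:

* **longitudinally restricted**: BChl fluorescence concentrates in one or
  two discrete sites at conserved distances from the cell poles. In
  asymmetrically dividing rods the single site sits near the *old* pole
  (the pole carrying the unipolar polysaccharide adhesin, UPP); a second,
  initially weaker site appears near the new pole once the cell passes a
  length threshold, so the distance between the two sites grows linearly
  with cell length;
* **nonrestricted**: fluorescence spans essentially the whole cell,
  whatever its size.

`icmap` turns multi-channel micrographs (phase contrast, BChl
fluorescence, optional lectin-stained adhesin channel) into per-cell and
population-level measurements of this phenotype, and maps the resulting
discrete trait onto a species tree by minimum-change (Fitch) ancestral
reconstruction. Because no public single-cell dataset accompanies the
phenomenon, the package also contains a first-class synthetic scene
generator with exact ground truth; every downstream stage is validated
against it.

## Synthetic scenes

`generate_scene(scene_config(), localization_model())` draws cells as
spherocylinders (straight or slightly curved axes; a mild width taper of
the mid-cell "tube" in cells longer than `L_star` approximates budding
morphology), places them without overlap by rejection sampling (at most
100 attempts per cell, then an error naming the count placed), and
renders three channels:

* *phase*: dark cells on a bright background (background 200, cell
  contrast 0.7);
* *fluorescence*: for the restricted pattern, axial Gaussians of extent
  `sigma_focus` centered at the true focus positions, masked to the cell;
  the new-pole focus is scaled by `rho`. For the nonrestricted pattern,
  uniform in-cell intensity `amp`. The signal is convolved with a
  Gaussian PSF and the uniform background is added;
* *adhesin*: a 2-D Gaussian spot at the old-pole coordinate for a random
  `adhesin_fraction` subset of cells.

Noise is Poisson (pixel values are treated as expected photon counts)
followed by additive Gaussian read noise. Scenes are bitwise
deterministic given `seed`.

Default conditions, chosen once: field 512 x 512 px at 0.065 µm/px
(100x camera sampling); cell lengths normal 2.2 ± 0.6 µm truncated to
[1.4, 4.5] µm; width 0.8 µm; PSF sigma 0.08 µm (≈ 0.21 λ/NA for a
1.4-NA objective near 520 nm); background 100, read noise sd 3, peak
amplitude 150 (peak SNR ≈ 9). The localization model defaults are
`d_old = 0.6` µm, `d_new = 0.5` µm, `L_star = 2.5` µm, `rho = 0.6`,
`sigma_focus = 0.25` µm. The lower length bound of 1.4 µm keeps the
generator self-consistent: with newborn cells shorter than `2 * d_old`
the "old-pole-proximal" focus would sit at or beyond mid-cell, which
contradicts the model the generator is supposed to embody.

What the generator does *not* emulate: 3-D optics and defocus, uneven
illumination, spectral bleed-through, cell crowding/touching (cells are
placed with a small gap; the watershed splitter is exercised with
separately constructed fused rods), motility blur, and real budding
shapes. Passing tests on synthetic scenes therefore demonstrates the
correctness of the measurement chain under the stated imaging model, not
performance on arbitrary real micrographs.

## Registration

The two optical paths of a real microscope can be offset by a consistent
spatial distortion. `estimate_distortion()` least-squares fits an affine
(or quadratic polynomial) map from fluorescence to phase coordinates
from landmark pairs, reporting the per-coordinate residual RMS in
pixels; `apply_correction()` resamples a channel onto the phase grid by
bilinear interpolation of the inversely mapped positions, filling
out-of-field pixels with the channel median and flagging them. A
low-order polynomial was chosen over free-form elastic registration: the
documented distortion is a fixed property of the optics and is
low-order in practice, and the correction must be estimated once from a
single crowded reference field and then applied unchanged to all other
fields. Segmentation refuses a `field_image` whose provenance does not
show correction, unless explicitly waived; synthetic scenes are
co-registered by construction and carry the flag.

## Segmentation and cell geometry

Cells are detected by thresholding the inverted, Gaussian-smoothed phase
channel (Otsu by default; a fixed threshold is available for clean
synthetic masks). A guard rejects thresholdings whose
foreground/background class separation is below two standard deviations
of the smoothed image — this is what makes a blank, noise-only image
return zero cells rather than noise specks. Touching cells are probed by
watershed on the distance transform: a component is split only when the
watershed finds fragments whose distance-transform maxima are at least
`split_min_distance` apart and all fragments exceed half the minimum
cell area. Components are then filtered by area (0.5–8 µm²) and aspect
ratio (length/width ≥ 1.3).

The medial axis is built by a projection-and-recenter construction
rather than skeleton thinning: mask pixels are projected onto the
principal axis; unit-length axial bins yield transverse midpoints and
chords (pixel count per bin, an area-exact width estimate that is
rotation invariant for straight rods); cap-region bins (within half a
width of either end) are dropped because end-face pixels bias the
midpoint; the resulting polyline is refined by recentering each point
between the two boundary crossings along its local normal (two passes),
then extended to the boundary along its end tangents to define the
poles. This construction needs no branch-pruning heuristics, behaves
identically under translation and rotation (verified to 3% for a 37°
rotation, exactly for 90°), and tracks a quarter-annulus bent rod's
analytic midline length within 5%. Cells whose skeleton degenerates to
a point are flagged and excluded from axial analyses.

Coordinates follow the raster convention: 0-based, origin top-left,
pixel centers on integers; all lengths are in µm via the pixel size.

## Fluorescence quantification

The field background is the median intensity outside all cell masks
after a 2-pixel dilation — robust, parameter-free, and testable, in
contrast to rolling-ball approaches whose radius would be another free
parameter. Per-cell mean intensity is the mask mean minus background.
The medial profile samples, at a uniform axial step (default: one
pixel), the mean of bilinear interpolations over a transverse segment
spanning the central 75% of the local width (the outermost positions
straddle the rasterized boundary and would dilute the mean with
background).

Foci are detected on the Gaussian-smoothed profile (`smooth_sigma`
0.1 µm) as local maxima with topographic prominence at least
`min_prominence` (0.25) of the smoothed maximum, retained greedily in
order of prominence subject to a pairwise separation of
`min_separation` (0.5 µm), at most `max_foci` (3). The greedy rule makes
the focus count monotone non-increasing in both thresholds, which the
test suite asserts as a property. Focus position is refined as the
intensity-weighted centroid over ±0.3 µm and mapped back to 2-D through
the axis (fluorescence-weighted over the window when the image is
available). These thresholds are this package's own defaults; 1- and
2-focus cells are the analyzed classes, so `max_foci` must allow at
least 2.

## Polarity

The adhesin spot is the brightest pixel within the cell's dilated mask;
it must reach `min_snr` (5) over the channel noise (median/MAD
estimates) and lie within `pole_capture_radius` (0.5 µm) of a pole. A
bright spot at mid-cell marks the cell `adhesin_present` but leaves it
unassigned. Profiles of assigned cells are flipped so s = 0 is the old
pole; unassigned cells are left alone (default) or oriented by the
brighter half (`fallback = "bright_end_left"`), with the decision source
recorded per cell. Orientation is a pure reflection, so applying it
twice with the same calls restores the input. Unassigned cells remain in
non-polar analyses and are excluded from pole-referenced statistics.

## Population statistics

* **Demograph**: per-cell profiles resampled to a common bin step,
  rows sorted by length ascending, left-aligned at the old pole or
  centered; per-cell max-normalization is optional and off by default
  (raw background-corrected intensity).
* **Focus position map**: each focus at (s/L, transverse offset / local
  half-width) in a pole-aligned unit-cell frame, plus the population
  mean outline (average normalized half-width profile).
* **Length by focus count**: classes 0/1/2/3+, medians and interpolated
  (type-7) quartiles, Tukey outliers at 1.5 IQR.
* **Spacing regression**: OLS of inter-focus spacing on cell length in
  two-focus cells. In a restricted population spacing equals
  `L - d_old - d_new` by construction, so the recovered slope is a
  direct check of the whole chain (observed ≈ 0.99 on the reference
  simulation). Constant spacing is reported as slope 0 with a
  zero-variance flag rather than an undefined correlation.
* **Pole distances**: medians, IQRs and coefficients of variation of
  the old-pole (smaller s) and new-pole (L − larger s) distances.
* **Old/new intensity**: paired per-cell new/old ratio with a Wilcoxon
  signed-rank statistic.
* **Content correlation**: Pearson correlation (rank-based by flag)
  between per-culture BChl content (A770/OD660) and population mean
  cellular fluorescence.
* **Classification**: per-cell occupancy is the fraction of profile
  bins at or above half that cell's maximum; a cell is focal when
  occupancy ≤ 0.5, and a population is restricted when ≥ 80% of cells
  are focal, nonrestricted when ≤ 20%, else indeterminate; fewer than
  30 analyzable cells yields indeterminate with an insufficient-data
  flag. For a single Gaussian focus of sd 0.25 µm in a 3 µm cell the
  occupancy is the FWHM fraction ≈ 0.196, comfortably focal; a whole-
  cell boxcar has occupancy 1.

All of these are invariant to a global intensity gain, asserted in the
tests by scaling the fluorescence channel threefold.

## Ancestral-state reconstruction

`fitch_parsimony()` computes the minimum number of state changes over
all full labelings with a unit-cost dynamic program (subtree and
complement cost tables), which generalizes Fitch's intersection/union
pass to multifurcating nodes; on binary trees the score equals the
classical Fitch length, and the suite verifies equality with exhaustive
enumeration on 100 random trees of up to 8 leaves and 3 states, plus
invariance under rerooting. Node state sets contain exactly the states
attained by some maximum-parsimony labeling. `map_changes()` lists
change-bearing branches for an ACCTRAN-like or DELTRAN-like labeling
(tie-breaks prefer or avoid the parent state, respectively; the root may
be pinned to any state in its MP set) or, for `all_mp`, the exact union
and intersection over all MP labelings computed from the same tables.

The packaged species tree is a package-curated encoding, not a published
file: the three orders form clades (Rhodospirillales; Rhodobacterales
sister to Rhizobiales), the within-Rhizobiales branching order is left
as a polytomy because it cannot be recovered from descriptive text, and
the outgroup carries no ICM state and is pruned. On this fixture the
reconstruction needs 3 changes, the root set is {nonrestricted}, and the
DELTRAN labeling places one gain of restriction on the Rhizobiales stem
with two subsequent losses — the restricted state arises entirely within
that order.

## Problem sizes and tolerances

The validation suite uses one reference restricted population of 300
cells on a 1024² field (focus-geometry recovery: old-pole distance
median within 10% of 0.6 µm, spacing slope in [0.9, 1.1], intercept in
[−1.3, −0.9], intensity ratio in [0.5, 0.7]); 2 × 10 populations of 200
cells for classification (≥ 19/20 correct); a 120-cell field for
segmentation (recall and precision ≥ 0.95, 90% of lengths within 10%);
five 60-cell scenes for the content correlation (r ≥ 0.9); and noise-free
scenes for pixel-level focus position checks (errors bounded by one
pixel or one sampling step). Registration checks demand residual and
post-correction misalignment RMS below 0.5 px. These sizes give stable
statistics while keeping a full run of suite plus acceptance script in
a few minutes on one core.

## Known limitations

* The medial-axis construction assumes rod-like cells bent by at most
  ~90°; strongly curled or branched cells are out of scope, as are
  crossing/overlapping cells.
* Axial focus detection cannot separate two foci at the same axial
  position on opposite sides of the axis; the phenotype of interest is
  longitudinal, so foci are 1-D detections with 2-D back-mapping.
* The occupancy classifier assumes the profile maximum is signal; in
  cells with essentially no fluorescence the occupancy is undefined and
  the cell is dropped from classification.
* Fluorescence patterns say nothing about ICM architecture (lamellar
  vs vesicular); the architecture column in the trait fixture is
  carried as an independent annotation.
* TIFF pages are stored as 32-bit unsigned samples with a recorded
  quantum: integer-valued data round-trip exactly; real-valued data are
  quantized at ~5e-10 of their range.
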