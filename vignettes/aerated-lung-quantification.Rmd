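---
title: "Automated aerated-lung quantification in mouse micro-CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated aerated-lung quantification in mouse micro-CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungct)
```

## The measurement problem

In mouse models of pulmonary fibrosis and emphysema, disease severity
shows up as a change in how much of the lung is filled with air:
fibrotic consolidation replaces aerated parenchyma (volume loss),
elastase-induced emphysema enlarges airspaces (volume gain). In vivo
micro-CT can measure this longitudinally in the same animal, but only
if the analysis is automated — manual seeding or visual histogram
reading reintroduces observer bias and makes weekly scanning of whole
cohorts impractical. This package implements a fully automated chain
from reconstructed tomograms to aerated volumes, and the statistical
layer needed to treat that volume as a validated quantitative
endpoint.

## Data model

A `CTVolume` is a 3D array stored `[z, y, x]` (slice file order, image
row, image column; 1-based in R) with an isotropic voxel size,
defaulting to 35 µm. Fixing the axis convention matters: connected
component labeling and its tie-breaking are only reproducible with a
defined voxel order. Slice stacks are read in *natural sort* order
(`s2` before `s10`) so scanner exports stack correctly, and stored
integer grayscale values are used as-is, because HU calibration is
defined on stored indices; 8- and 16-bit TIFF/PNG are treated alike.

## Calibration

Two-point calibration from a water/air phantom: the measured water
mean maps to 0 HU and the air mean to −1000 HU,

$$\mathrm{HU}(g) = 1000\,\frac{g - g_\mathrm{water}}{g_\mathrm{water} - g_\mathrm{air}}.$$

The anchors are *inputs*, not constants: the reference water grayscale
of 81.32 belongs to one scanner's reconstruction settings and bit
depth, so `CalibrationModel(waterGray, airGray)` takes whatever the
user measured on their own phantom. The implementation computes the
ratio before scaling by 1000 so that both anchors map exactly in
floating point. Full-stack histograms use 1-HU half-open bins
$[h, h+1)$ over −1000..+1000 HU with the last bin closed; voxels
outside the range are tallied in underflow/overflow counters so the
ROI voxel count is always conserved. The bin width is a package
choice; the plotted range is the protocol's.

## Respiratory gating

The breathing signal is a 1-D displacement trace extracted upstream
from a video of the thorax. Cycle onsets are placed at displacement
*troughs*: end-expiration is the initiation of inspiration, so bin 0
is earliest-inspiration (EIV) and bin 3 end-expiration (EEV),
consistent with how the two endpoints are defined. The marker's sign
convention is hardware-dependent, so `invert = TRUE` flips it, and a
consistency flag is raised whenever a computed EIV falls below EEV.

Design choices, since the upstream signal is only described as
pseudo-sinusoidal: smoothing is a centered moving average with a
default window of 25 % of the dominant (FFT-peak) period; candidate
troughs closer than half that period are merged, keeping the deepest;
partial cycles at the ends of the trace are discarded because phase
fraction is undefined there. Bins are equal phase-fraction quarters,
`bin = floor(4 * phi)`; a binning is valid only when every bin holds
at least 2 projections, and projections outside all cycles are listed
in the QC output rather than dropped. EEV is the endpoint recommended
for group comparisons: it measures air trapping and is insensitive to
anesthesia-induced gasping.

## Segmentation

The algorithm's logic is that air is unmistakable on CT but occurs in
two places — inside the animal and around it — and the two can be
separated morphologically:

1. **Threshold**: voxels with HU ≤ −580 (euthanized mode) are air.
   For free-breathing animals, residual gated motion blur mixes air
   and tissue at organ borders, so the in-vivo mode raises the
   threshold to −383 HU; the two modes differ in nothing else. We use
   HU ≤ *t* uniformly for both modes: the originating protocol states
   one bound inclusively and the other strictly, a one-HU discrepancy
   that is immaterial at this noise level, and a single rule is
   testable.
2. **Despeckle (external air)**: per axial slice, air components
   (8-connectivity) touching the slice border are external; every
   enclosed 2D air pore — lungs included, since the thorax encloses
   them on every axial slice — is removed from the air mask.
3. **Body ROI**: the complement of external air; its border is
   sharpened by a per-slice erosion with a square (Chebyshev)
   structuring element of radius 10 px, removing the partial-volume
   skin rim. Erosion is 2D because the ROI operations are slice-wise
   in the originating workflow and "10 pixels at the border" then has
   an exact meaning.
4. **Sweep**: thresholding inside the eroded ROI yields all internal
   air; the largest 26-connected 3D component is the lung (left and
   right lungs connect through the trachea and main bronchi), and
   everything else — subcutaneous-fat voxels, gut gas, speckle — is
   discarded. Size ties are broken toward the component containing
   the lexicographically smallest (z, y, x) voxel, for bit-exact
   reproducibility.

Degenerate inputs fail loudly at the stage that detects them: a field
of view that is entirely external air ("no subject"), an ROI that
vanishes under erosion, a body with no internal air ("empty
segmentation").

## Volumes, PV curves, statistics

Volumes are reported in voxels and mm³ (`count × voxelSize³`),
exactly conserved between units. Post-sacrifice pressure–volume
curves accept the descending acquisition order (30 → 3 cmH₂O) and are
integrated by the trapezoidal rule *over the measured range only* —
no extrapolation to zero pressure, since neither the integration rule
nor any schedule outside 30–3 cmH₂O is part of the protocol.

Repeatability follows Bland and Altman: within-subject SD is the
square root of the residual mean square of a one-way ANOVA with
subject as factor (unbalanced designs supported; subjects with a
single scan are dropped with a warning — scan attrition is routine —
rather than failing the analysis), the 95 % repeatability coefficient
is 1.96·√2·s~w~, and heteroscedasticity is checked by the Spearman
correlation of per-subject mean against SD. Agreement with reference
measurements (histology score, collagen content) is ordinary least
squares with 95 % prediction bands. Group comparisons use the Welch
t-test unconditionally: the correction is uniformly valid and removes
an unstated "if necessary" branch.

Power calculations use the exact noncentral distributions: two-sided
two-sample t with δ = d·√(n₁n₂/(n₁+n₂)) on n₁+n₂−2 df, and one-way
fixed-effects ANOVA F with λ = f²·N on (k−1, N−k) df. A-priori sample
sizes search balanced designs upward from n = 2 per group, because
the published designs are balanced; unbalanced post-hoc queries take
explicit group sizes. Raw power is kept unrounded; rounding to whole
percent happens only at presentation. The two-way repeated-measures
ANOVA power rows of the original design table are not implemented:
they require inter-measurement correlation and nonsphericity inputs
that were never published.

## The phantom: what it emulates and what it does not

`makeThoraxPhantom()` builds the study conditions the rest of the
package is tested under: a soft-tissue body (+40 HU, elliptical
cylinder filling ~80 % of the in-plane field of view) surrounded by
external air (−1000 HU) above a bed slab (+100 HU); two lung
ellipsoids of pure air joined by a bronchial bridge; four phases
deflating monotonically with an EIV/EEV volume ratio of 1.45 (mouse
tidal excursion at this scale is tens of percent of FRV; the exact
ratio is a generator convention); Gaussian HU noise of σ = 20 HU,
consistent with in vivo micro-CT at this dose; and isotropic 35 µm
voxels. Fibrosis replaces a requested fraction of lung-air voxels
with tissue-density patches (a seeded stream of spherical patches,
trimmed voxel-wise so the removed fraction is exact to one voxel;
lower severities consume a prefix of the same stream, making severity
strictly monotone on matched seeds). Emphysema scales the lung
compartment's volume. Optional −600 HU "speckle" pockets in the
tissue exercise the sweep: they threshold as air but must not survive
to the final mask. Ground truth is recorded on the noiseless
geometry, which keeps the oracle exact and moves all noise handling
into explicit test tolerances.

What the phantom does *not* emulate: partial-volume boundaries (its
edges are sharp), beam hardening and ring artifacts (reconstruction
corrections are upstream of this package), anatomical lobe structure,
the diaphragm and mediastinum, and intra-scan motion. Passing the
phantom tests therefore demonstrates that the algorithm and its
bookkeeping are correct under controlled noise — not that the
thresholds generalize to every scanner; the calibration anchors and
thresholds remain scanner-protocol quantities.

Problem sizes: the end-to-end recovery and severity-monotonicity
checks run on 200³ grids (10 seeds); unit tests use 40–120³ grids,
chosen so the default 10 px erosion leaves the lung untouched —
on grids much below ~70³ the eroded body ROI begins to clip the
phantom lung, which is a property of the geometry, not of the
algorithm. The full 1000×1000×N reconstruction size of a real scan is
reachable by passing larger `dims`.

## Known limitations

* The despeckle step assumes the subject never touches the image
  border in any slice; a cropped reconstruction violates this.
* One threshold pair is provided per scanning mode; density-based
  sub-classification of fibrotic texture is out of scope.
* Gating starts from the extracted 1-D trace; video processing and
  projection re-sorting for reconstruction are upstream.
* The −580/−383 HU thresholds and the 81.32 water anchor belong to
  one scanner and reconstruction configuration; both are exposed as
  parameters and should be re-derived (phantom scan, inspiration/
  expiration comparison) when porting to other instruments.
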