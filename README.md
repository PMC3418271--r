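# lungct

Fully automated quantification of **aerated lung volume** in mouse
micro-computed tomography (µCT), for preclinical researchers studying
pulmonary fibrosis (bleomycin-type restrictive disease, where aerated
volume falls) and emphysema (elastase-type airspace enlargement, where
it rises). The package covers the whole analysis chain downstream of
tomographic reconstruction — no step requires operator interaction —
plus the repeatability, agreement, and power statistics used to
validate such an imaging endpoint.

## What it computes

**Hounsfield calibration.** From a water/air phantom scan, stored
grayscale indices *g* are mapped linearly to Hounsfield units with the
water mean anchored at 0 HU and the air mean at −1000 HU:

    HU(g) = 1000 · (g − g_water) / (g_water − g_air)

**Retrospective respiratory gating.** A pseudo-sinusoidal breathing
trace (thorax-marker displacement) is smoothed and its troughs mark the
initiation of inspiration. Each cycle is divided into 4 phases of
identical length; a projection at phase fraction φ lands in bin
⌊4φ⌋. Bin 0 yields end-inspiratory volume (EIV), bin 3 end-expiratory
volume (EEV, the functional residual volume); a binning is valid when
every bin holds ≥ 2 projections.

**Aerated-lung segmentation.** On a calibrated volume: (1) threshold
air at HU ≤ −580 (euthanized) or ≤ −383 (in vivo, where gated motion
blur contaminates boundary voxels); (2) *despeckle* per axial slice —
keep only air 8-connected to the slice border, removing all enclosed
2D pores, which isolates the air outside the animal; (3) the
complement is a body region of interest, whose border is sharpened by
a 10-pixel per-slice square erosion; (4) re-threshold air inside the
eroded ROI; (5) *sweep* — keep only the largest 26-connected 3D
component, discarding stray low-density voxels (e.g. subcutaneous
fat). The result is reported in voxels and mm³ (isotropic 35 µm
voxels by default) with a full-stack HU histogram of the body ROI.

**Quantification and statistics.** Pressure–volume curves from
post-sacrifice deflation series (30 → 3 cmH₂O) with trapezoidal AUC;
Bland–Altman repeatability (within-subject SD *s_w* from the one-way
ANOVA residual mean square, 95 % repeatability coefficient
1.96·√2·*s_w*, Spearman mean-vs-SD heteroscedasticity check);
agreement by linear regression with 95 % prediction bands; Welch
t-tests; and exact noncentral-t / noncentral-F power and sample-size
calculations (two-sample t: δ = d·√(n₁n₂/(n₁+n₂)); one-way ANOVA:
λ = f²·N).

A seeded **digital thorax phantom** (4 respiratory phases, optional
fibrotic consolidation and emphysematous volume gain, exact ground
truth) and a water/air calibration phantom make every stage testable
without scanner data.

## Worked example

```r
library(lungct)

ph <- makeThoraxPhantom(dims = c(120L, 120L, 120L), seed = 7)  # 4 phases
segmentAeratedLung(ph$volumes$bin3)
#> SegmentationResult: 77553 lung-air voxels = 3.325 mm^3 (mode euthanized, threshold -580 HU)
ph$groundTruth$volMm3[["bin3"]]
#> [1] 3.325085

respiratoryVolumes(lapply(ph$volumes, segmentAeratedLung))
#> RespiratoryVolumes: EIV 4.822 mm^3, EEV 3.325 mm^3

round(100 * ttestPower(1.861, 5, 6))   # post-hoc power, bleomycin vs control
#> [1] 78
ttestSampleSize(1.861, 0.95)$nPerGroup # mice per group for 95% power
#> [1] 9
```

The segmentation recovers the phantom's known aerated volume to within
a fraction of a percent (77 553 voxels ≙ 3.325 mm³ at 35 µm), EIV
exceeds EEV as the lungs deflate across bins, and the noncentral-t
machinery answers the design questions a study of this kind poses.

A thin command-line front end is installed with the package
(`inst/scripts/lungct`), exposing `run`, `segment`, `pv`, `power` and
`simulate` subcommands over the same functions.

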