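---
title: "Measuring diaphragm motion and shape from dynamic lung segmentations"
author: "diaphragmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diaphragm motion and shape from dynamic lung segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaphragmotion)
```

## The problem

Respiratory weakness in neuromuscular disease is usually monitored by
spirometry, but forced vital capacity mixes the contributions of the
diaphragm and the thoracic wall. Dynamic sagittal MRI of a forced
inspiration — a ~15-frame series running from an end-expiration
breath-hold to an end-inspiration breath-hold — separates the two: the
caudal excursion of the diaphragm dome drives cranio-caudal (CC) lung
expansion, while rib-cage motion drives the anterior-posterior (AP)
expansion. A weak diaphragm moves less (CC ratio approaches 1) and,
unable to resist the fall in intrathoracic pressure, becomes *more*
curved during inspiration (DA and DH ratios rise above 1), even when
spirometry is still normal. This package implements the measurement
chain for such series, taking binary lung segmentation masks as input;
segmentation itself is an upstream (manual or automatic) step.

## Coordinate conventions

Masks are converted to physical coordinates with x increasing anterior to
posterior and y increasing caudal to cranial; image row 1 is the cranial
edge, and an orientation flag flips x for images stored facing the other
way. All downstream rules ("anterior corner has smaller x", "highest
point along the major axis") are stated in this frame. Contours are
stored counter-clockwise; extraction from masks traces the 0.5 iso-level
of the binary image (marching squares with linear interpolation), which
places straight boundaries exactly half-way between foreground and
background pixel centres and avoids the staircase bias of pixel-edge
tracing. Only the largest connected component is kept (ties broken by
raster-scan order) and holes are discarded.

## The landmark chain

Per frame:

1. **Orientation.** A direct algebraic least-squares ellipse fit (solving
   the reduced 3×3 eigenproblem on centred, scaled coordinates) gives the
   lung's general orientation. The major-axis angle is reported from the
   +y axis in (−π/2, π/2], and the axis direction used downstream is the
   representative with positive cranial component, so "highest point" is
   well defined for any fitted angle. Near-collinear vertex sets make the
   algebraic fit degenerate; the principal axes of the vertex scatter are
   then used and flagged (`method = "principal"`).
2. **Lung apex.** The vertex maximizing the scalar projection on the
   cranially-directed major axis; ties resolve to the smaller x.
3. **Centroid.** The polygon *area* centroid, not the vertex mean; for
   densely sampled contours the difference is negligible, but the area
   centroid is invariant to uneven vertex spacing.
4. **Costophrenic angles.** Among vertices whose major-axis projection is
   caudal to the centroid's ("the lower part of the lung" made
   orientation-corrected and parameter-free), the vertex furthest from
   the centroid on each side of the major-axis line through the centroid.
   The smaller-x side is anterior. Ties resolve caudal-most, then
   smaller x. Both rules are deterministic so results are reproducible
   bit for bit.
5. **Diaphragm contour and apex.** Of the two corner-to-corner paths
   along the closed contour, the one not containing the lung apex,
   oriented anterior to posterior. The raw apex is the point furthest
   from the inter-corner chord (ties toward the smaller arc-length
   fraction). Because the raw apex is variable between consecutive
   frames when the dome is flat, the *derived* apex is placed at the
   series-median of the per-frame raw arc-length fractions (even frame
   counts: mean of the two middle values), linearly interpolated along
   each frame's diaphragm polyline. CC and DH use the derived apex; the
   raw apex is kept in exports for diagnostics.

A completely flat diaphragm (all points collinear with the chord) has no
meaningful apex; the frame is flagged and the apex reported at fraction
0.5 with zero distance.

## Outcomes and their signs

Per frame: CC distance (lung apex to derived diaphragm apex), AP extent
(x range of the normalized frame, matching the horizontal arrows of the
outcome diagrams and stable when the per-frame ellipse rotates slightly),
lung area (shoelace), DA (signed area between the diaphragm polyline and
the chord) and DH (signed apex-chord distance). DA and DH are positive
toward the lung interior; a dome that inverts caudally gives negative
values, and a sign change between the two breath-hold frames (clinically
meaningful paradoxical motion) is flagged rather than hidden. Subject
ratios divide end-inspiration by end-expiration values; the CC-AP ratio
is CC ratio over AP ratio. When the expiratory |DH| falls below a
configurable 0.5 mm the DA and DH ratios are reported `NA` ("undefined")
instead of exploding. Corner displacements are net end-to-end Euclidean
distances between the breath-hold frames — the quantity depicted by
expiration-vs-inspiration overlays and robust to frame jitter — with the
summed frame-to-frame path length exported as a secondary diagnostic.

## The synthetic phantom

No public image data accompany this problem, so the package generates
its own. The lung is a half-ellipse cap over a rectangle of AP width,
with a caudal dome arch spanning the two basal corners — the simplest
family in which every outcome has a closed form. Two choices deserve
explanation:

* **Dome family.** A circular-segment arc fixes the ratio
  DA/(chord × height) once the chord is given, so the DA-ratio and
  DH-ratio targets could not be set independently. The dome is therefore
  the power arch y = h(1−u²)^m, whose fullness
  F(m) = √π Γ(m+1)/(2 Γ(m+3/2)) spans (0, 1); per frame, m is solved
  from the DA target. The expiratory fullness defaults to 0.5 (m ≈ 2.4),
  in the m > 1 regime where the arch meets the chord with a horizontal
  tangent: the costophrenic corners are then near right angles and
  survive binary rasterization (acute corner wedges are chamfered by
  marching squares by up to a pixel, which measurably biases DA and DH).
* **Cap fraction.** The published lung-area ratios (up to 2.57) exceed
  the product of the CC and AP ratios, so the shape change between
  expiration and inspiration is deliberately non-affine: the expiratory
  lung is cap-dominated (cap fraction 0.9 of the supra-chord height,
  dome-like), and the inspiratory cap fraction is *solved* from the
  lung-area target (elongated, wall-dominated). Geometrically
  inconsistent targets fail fast with a named error.

Baseline expiratory geometry is a realistic sagittal right lung — CC
120 mm, AP 100 mm, dome height 30 mm. The dome height was set at the
upper end of the realistic range so that half-pixel quantization of the
dome apex and chord levels stays near 1% of DH at the 1 mm default
raster spacing. Frames interpolate all extents and shape parameters
geometrically (constant per-frame factor), so intermediate frames are
valid lungs; only the end frames enter the ratios. The diaphragm chord
descends linearly by the drop implied by the posterior-displacement
target, with the anterior corner keeping its x position; as a
consequence the anterior displacement co-varies with the posterior one,
which is a simplification — real anterior corners move little and
independently of severity — and no package claim rests on anterior
displacement.

Phenotype presets pin the true ratios to the published group means
(healthy 1.72/2.54/1.38/0.91/0.82 and 70.7 mm; normal-spirometry
patients 1.60/2.57/1.22/1.34/1.08 and 70.6 mm; decreased-spirometry
patients 1.32/1.95/1.04/1.79/1.41 and 35.6 mm). The `severe` preset is
anchored only by "CC ratio ≈ 1"; its remaining values (AP 1.25, area
1.30, DA 1.90, DH 1.55, posterior displacement 32 mm) are package
choices consistent with that phenotype: thoracic-wall-dominated
inspiration and strongly increased dome curvature. The 32 mm is the
smallest round value compatible with the displacement model's lower
bound (the AP-extent change of 25 mm).

Cohort simulation draws per-subject true ratios around the preset means
with a latent severity term shared (with opposite signs) by the CC and
DH ratios plus independent noise; group-level sds are not published
(error bars only), so the defaults (≈0.11 on the CC ratio) are
documented choices. Pulmonary-function values are *linear* functions of
the true CC ratio plus noise, calibrated so the preset CC means map onto
the published group means of FVC supine (102/60), FVC upright (106/81)
and MIP (106/72); MEP is only weakly linked. This is an explicit
simulation assumption that makes the correlation structure recoverable
by construction — passing correlation tests demonstrates that the
statistics code recovers a known monotone link, not that real data
behave this way.

### What the phantom does not emulate

Real segmentations have observer-dependent boundary placement, partial
lung visibility, cardiac borders (left lung), through-plane motion and
non-elliptical apices. Passing phantom tests shows the geometry,
measurement and statistics chain is correct under the stated shape
family and noise model; it does not validate segmentation quality or
anatomical generality.

## Numerical behaviour and tolerances

On exact polygon input the pipeline reproduces analytic truth to better
than 0.5% (machine precision for most outcomes). On 1 mm binary masks,
extent-, area- and displacement-type outcomes are accurate to ≈2% per
series. DA and DH ratios are limited by an irreducible discretization
floor: the dome apex and the chord are locally flat, so their traced
levels quantize to the half-pixel grid phase (±0.5 mm on 25-40 mm
heights), giving worst-case per-series ratio errors near
(h_i ∓ 0.7)/(h_e ± 0.7) ≈ 7%; averaging over grid phases (different
subjects, or vertex jitter) brings the means below 1%. The test-suite
assertions mirror exactly these bounds, and the per-preset recovery
checks use means of 20 jittered phantoms at the 1 mm default. The same
floor applies to corner displacements (two positions, each quantized),
asserted at 1 mm. Simulation sizes throughout (20 phantoms per preset,
100 oracle contours, 100-200 seeds for the ICC/power checks, 53-subject
cohorts at 5-15 frames) were chosen so the whole suite runs in a few
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Statistics

* **ICC.** "Two-way mixed, absolute agreement" is implemented as the
  single-measurement variant — each rater contributes one measurement
  per subject in the validation design — from the two-way mean squares:
  (MSS − MSE)/(MSS + (k−1)MSE + (k/n)(MSR − MSE)). A constant matrix is
  reported undefined, not 1.
* **Group comparison.** Ordinary least squares of the outcome on group
  indicators plus caller-listed covariates (no automatic selection; age
  is the typical adjustment since it is the characteristic that differs
  between subgroups). The overall p is the joint F test on the group
  indicators — the natural choice where the test statistic is not
  otherwise specified — and pairwise contrasts are judged at the
  Bonferroni level 0.05/3 rounded to 0.017. With two groups and no
  covariates the pairwise p equals the pooled-variance t test to within
  10⁻¹⁰, which the suite asserts.
* **Spearman correlations** use average ranks for ties; constants are
  flagged undefined. The correlation table stars coefficients at
  p < 0.05/0.01/0.001 (asymptotic t approximation, appropriate at
  n ≈ 50 with ties present).
* **ΔFVC** is upright minus supine FVC (% predicted); the subgroup split
  is supine FVC ≥ 80% predicted *and* z ≥ −1.64.

## Known limitations

The pipeline is contour-generic: it trusts the provided masks, models no
heart inclusion, applies no temporal smoothing beyond the median-fraction
rule, and has no manual-override pathway for visually rejected
landmarks beyond exporting the raw apex. The displacement model ties
anterior to posterior corner motion (above). Statistics assume complete
cases and a single measurement per rater; mixed-effects extensions are
out of scope.
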