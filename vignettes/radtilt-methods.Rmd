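---
title: "Automatic volar tilt and radial inclination on 3D radius models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic volar tilt and radial inclination on 3D radius models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtilt)
```

## The measurement problem

Volar tilt (VT) and radial inclination (RI) are the two angles a hand surgeon
reads off plain radiographs to grade a distal radius fracture or malunion:
VT on the lateral view, between the articular-rim line and the perpendicular
to the radial long axis (negative when the surface is tilted dorsally), and
RI on the frontal view, between the line from the central reference point
(CRP) to the radial styloid and the same perpendicular. Measuring them on 3D
surface models removes projection error and rater variability — but only if
the 3D coordinate system and landmarks replicate the 2D definitions, which
is what this package's pipeline is built around. The CRP (midpoint between
the volar and dorsal ulnar corners of the articular surface) is the origin;
the longitudinal axis is taken from the shaft segment 28.8–53.3 mm proximal
to the CRP, the segment reported to best reproduce the 2D long axis; and VT
is measured between margin reference points at fixed fractions of the
dorsal and volar cortical-margin arcs (57% and 33% of the normalised
CRP-to-styloid length), the placement found to best match 2D readings.

## The detection chain and its assumptions

`measure_radius()` runs a fixed, deterministic sequence; every stage
consumes only plane–mesh cross-sections, inertia axes and extremal-point
searches, so the result is bit-identical across runs.

1. *Canonical pose.* The largest principal axis of the area-weighted
   triangle-centroid covariance goes to Z; the rounder of the 8%/92%
   cross-sections (shape factor `4πA/P²`) is the proximal head and is turned
   toward −Z; the most prominent convex inflection of the 35% section — the
   interosseous ridge — marks the ulnar (−X) direction. Assumptions: one
   connected, complete radius; a mesh in millimetres; a declared side (left
   models are mirrored to right-canonical form first).
2. *Distal refinement.* The origin moves to the section 8% from the distal
   end; the inertia axis of the distal triangles, an estimate of the
   articular-surface direction, is aligned with X; then five iterations of
   YZ-section recentring/Y-alignment with reselection of triangles above
   −1 mm leave the articular surface approximately in the XY-plane. This is
   the step that makes the later rim searches well-posed even for strongly
   tilted malunions.
3. *Styloid, corners, CRP.* Five XZ-section recentring/X-alignment
   iterations level the styloid-to-sigmoid-notch span; the styloid is the
   z-maximum on the radial side; the ulnar corners are z-maxima on the ulnar
   side under ±25° tilts about X combined with 25° about Y; the CRP is the
   z-maximum of the XZ-section of the distal selection under a 25° tilt
   about Y, and becomes the origin.
4. *Margins.* Twenty planes parallel to the YZ-plane at
   `x_i = (i − 0.5)/20 · x_styloid` (centre-of-bin spacing avoids degenerate
   cuts at the CRP and the styloid); on each section the highest point under
   a +5° (dorsal) or −5° (volar) tilt about X is the margin point. The ±5°
   budget is what disambiguates the two rims, so the refinement residual
   must stay within a few degrees — on meshes whose rim does not rise toward
   the styloid this margin can be consumed (see *Synthetic data* below).
5. *Final coordinate system.* Two band alignments (40–60 mm proximal of the
   styloid, then 28.8–53.3 mm proximal of the CRP) set Z; X is the
   CRP-to-styloid direction orthogonalised against Z; Y completes the
   right-handed frame. VT and RI follow from their `atan2` projection
   formulas on the margin reference points and the styloid.

### Shaft-band axis as a central line

The longitudinal axis of a band is estimated as the major principal axis of
**thin-slice area-weighted centroids** rather than of the raw triangle
covariance. The difference matters: the band is selected along the *working*
z-axis, which at that stage can still be tilted by 10–25° relative to the
shaft. Under such oblique selection the raw covariance of a ~20 mm band of a
~13 mm-wide tube is both nearly degenerate (axial and transverse second
moments are comparable) and sheared by the partial rings clipped at the band
boundaries — in experiments the estimated axis then deviated from the true
tube axis by more than the frame tilt itself, so the two-pass alignment
diverged. Thin oblique slices, by contrast, are complete elliptical bands
centred on the tube axis, so their centroid line is unbiased at any tilt and
the alignment converges. For the same reason the CRP-band pass is repeated
(up to four times, stopping when the incremental rotation falls below 0.2°):
a single pass from a tilted frame under-corrects because the selection moves
with the frame. This also matches the manual definition of the longitudinal
axis as the *central line* of the 3–5 cm segment.

A deformity apex inside the 28.8–53.3 mm band bends that central line. The
pipeline quantifies this as the angle between the centroid-line directions
of the proximal and distal halves of the band (`band_axis_split`); above 3°
the result carries a `shaft_band_deformity` flag. On straight shafts the
split is a fraction of a degree; a 18° wedge at 40 mm produces 8–9° and a
measurably deviated axis — the known failure mode for very proximal
malunions, reported rather than hidden.

### Numerical conventions

* All triangle selections (`z > 0, −1, −5, −10` mm) take whole triangles by
  centroid z, except the margin-extraction selection, which takes a triangle
  if *any* vertex clears the threshold: near the sigmoid-notch corners the
  rim is carried by tall triangles whose centroids dip below −5 mm, and
  dropping them punches holes into the near-CRP sections.
* Extremal-point ties break lexicographically (z, then x, then y).
* Eigenvector choices are always by maximal alignment with the current
  working axis, never by eigenvalue rank, to prevent 90° flips on stubby
  selections; near-isotropic selections fall back to the reference axis with
  a warning.
* "More circular" is the isoperimetric factor `4πA/P²`; "most prominent
  inflection" is the maximum of convex discrete curvature after a 2 mm
  arc-length smoothing, declared non-prominent when the maximum does not
  stand 1.5× above the 90th percentile of the smoothed curvature (a smooth
  ellipse varies gradually; a ridge is a localised peak).
* Cross-sections chain triangle–plane segments into loops; open chains with
  end gaps of at most 1 mm are closed; sections of selected (open) shells
  legitimately yield open polylines, which all centroid/inertia computations
  handle with segment-length weighting.
* Rotations are right-handed about the named axes; `+25°` about X tips the
  dorsal side distally. The 180° proximal–distal flip is about X, fixed for
  determinism.
* Vertex merge tolerance on STL import is 1e-6 mm; models whose longest
  extent is outside 100–400 mm trigger a unit-sanity warning.

### Tunable parameters

All algorithm constants sit in `radtilt_config()` and are echoed into every
report: the shaft band (−53.3 to −28.8 mm, default-locked to the published
segment), the first-pass styloid band (−60 to −40 mm), margin fractions
(0.33 volar / 0.57 dorsal), 20 margin sections, 25° corner and 5° margin
tilts, and 5 refinement iterations. Changing them is possible but moves the
measurement away from the validated 2D-equivalent definitions.

## Synthetic data: what it emulates and what it does not

Patient meshes cannot be shipped, so validation runs on a parametric
radius: a hemispherical-capped round head (high circularity), an elliptical
shaft with a compact convex interosseous ridge (35° half-width, 2.5 mm), a
flared elliptical metaphysis with a flat sigmoid-notch facet whose junctions
with the ellipse are the ulnar corners, a concave articular dish, and a
styloid expressed as a quasi-linear rise of the entire rim from the notch
toward the styloid topped by a sharp crown. Two constructions make the
ground truth exact rather than approximate:

* the rim rise depends on the radial coordinate only, so dorsal and volar
  rims share it at equal x and margin-side disambiguation is unaffected; the
  ground-truth margins are sampled exactly as the algorithm samples them
  (CRP, 20 centre-of-bin rim crossings, styloid), so the 33%/57% reference
  points of truth and detection correspond;
* the rim-plane tilt is solved numerically (and the styloid elevation in
  closed form) such that recomputing VT and RI from the annotated reference
  points, styloid, CRP and shaft axis reproduces the requested values to
  1e-6° — including for wedge malunions, where the bent fragment twists the
  anatomical frame about Z and a naive construction would be inconsistent.

The quasi-linear rim rise is not cosmetic: the styloid/CRP levelling steps
assume the articular rim climbs toward the styloid roughly with the
inclination. An early generator that concentrated the whole rise in a narrow
styloid spike left the mid-rim 5–6 mm below the working plane and broke the
−5 mm margin selection — real anatomy does not do this, and the generator now
does not either.

Default geometry: 240 mm length, 6 mm mean shaft radius, 11 mm head radius,
14 × 9 mm distal ellipse, ~15k triangles (`facet_density = 1.5`/mm², the
scale of clinical CT-derived STLs). The seed drives a ±5–10% jitter of these
shape parameters, never of the requested angles. Cohort sampling follows the
validation study's composition: healthy VT ~ N(11°, 3°), RI ~ N(23°, 3°);
dorsal malunions draw VT uniformly in [−35°, −5°] with a wedge sized against
a healthy baseline (capped at 25°, the remainder carried by the articular
tilt) 15–24 mm proximal to the CRP; mixed cohorts use the 13:3 dorsal:volar
ratio.

What passing tests on these meshes shows: the chain's geometric logic,
conventions and invariances (pose, mirroring, determinism, recovery to
≤1.5° mean absolute error across VT ∈ [−35°, 25°], RI ∈ [5°, 35°]). What it
does not show: robustness to segmentation noise, cortical irregularity,
osteophytes, intra-articular steps, or partial scans — none of which the
generator models. Combinations of strong dorsal tilt (≤ −20°) with very
high inclination (≥ 30°), rare in clinical series, remain difficult for the
margin disambiguation and are outside the validated envelope.

## Agreement statistics

`bland_altman()` uses the signed mean difference (bias) with the
*population* standard deviation (divisor n): this convention reproduces the
published limits of agreement from the packaged tables; the descriptive
"Mean (SD)" table rows use the sample SD (divisor n−1). Both are exposed.
The printed tables label the difference row as an absolute mean difference,
but the printed numbers match the signed bias — the signed convention is
implemented, and the discrepancy documented here. The limits-of-agreement
confidence half-width follows `1.96·√(3/n)·SD`, and outliers are differences
beyond the 5° clinically relevant threshold. Distributional normality is not
re-tested here; with no relationship between means and differences the
effect of non-normality on the limits is negligible, and `stats`
(e.g. `shapiro.test`) is available to users who want a check.

```{r agreement}
t1 <- measurement_table("malunited")
bland_altman(paired_measurements(t1$id, t1$vt_auto, t1$vt_2d))
```

## Problem sizes used in the shipped validation

The test suite and acceptance script use 10-model cohorts for the
test–retest check, a 20-case recovery sweep spanning the full stated angle
ranges (half healthy, half dorsally wedged), 20 random poses for
rigid-motion invariance, and single meshes of ~15k triangles throughout —
sizes chosen so the whole validation reruns in a few minutes on one core
while still exercising every code path at clinical mesh resolution.

## Known limitations

* The styloid-band / CRP-band sequence follows the published order; whether
  the first band is superseded by or averaged with the second is ambiguous
  in the source description — they are applied sequentially here.
* The distal refinement is a contraction, not an exact fixed point: its
  z-selections move with every rotation, so re-running it from its own
  output shifts the frame by a bounded, shrinking amount (single degrees).
  Downstream measurements are insensitive to this residual.
* Automatic side detection is intentionally not provided; declared side is
  required, mirroring the reliability finding that motivated it.
* Exact polyhedral mass properties, geodesics and curvature tensors are out
  of scope; all "inertia axes" are area-weighted surface-shell quantities,
  as appropriate for STL surfaces that may not be watertight.
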