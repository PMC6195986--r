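---
title: "Curved-surface quantification of secondary-palate clefts from CT"
author: "cleftmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curved-surface quantification of secondary-palate clefts from CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftmorph)
```

## The measurement problem

In neonates the bony hard palate — the palatine processes of the incisive
bones and maxillae plus the horizontal plates of the palatine bones — is a
thin, curved shell. A congenital cleft of the secondary palate is a
through-gap in that shell. Its clinically useful size measure is the
*surface area of the defect on the curved palate*, together with the
fraction of the whole hard palate it occupies: a flat, projected
measurement systematically under-reports both. `cleftmorph` computes these
quantities automatically from a CT volume, replacing an interactive
segment–trim–model workflow with a deterministic pipeline.

Two neonatal peculiarities shape the design. First, neonatal bone is less
mineralised than adult bone, so segmentation uses a low inclusive
threshold (`HU >= 140`). Second, the skull sutures are still unfused:
normal radiolucent lines (median palatine, palatomaxillary,
incisivomaxillary) look like narrow gaps in the bone and must not be
mistaken for clefts. The pipeline therefore *bridges* gaps narrower than a
configurable width (`min_gap_mm`, default 1 mm): reported true clefts are
about 2 mm wide and upward, while sutures are sub-millimetre.

## Pipeline model

### Segmentation and surface extraction

The bone mask is `HU >= threshold` (inclusive, so the boundary case is
deterministic), cleaned to its largest 26-connected component (thin
neonatal plates fragment under 6-connectivity). The surface is extracted
by marching tetrahedra: each voxel cell is split into six tetrahedra with
translation-consistent diagonals, giving a watertight, consistently
oriented triangulation; vertices are welded on cell edges and live in
world millimetres (`origin + index * spacing`).

Marching a *binary* segmentation produces a staircase surface whose raw
area is far too large (about +27% at 0.5 mm voxels for a sphere). Two
numerical choices restore accurate areas:

* the threshold indicator (0/1) is smoothed with a small Gaussian
  (`presmooth = 0.4` voxels) and the surface is extracted at the 0.5
  level. Crossings then sit midway between voxel centres, which is an
  unbiased estimate of the interface position. Extracting the raw HU
  field at 140 instead would place every crossing at a fixed 0.33 of the
  edge between bone (+700) and air (−1000) voxels and bias every
  interface by ~0.17 voxels into bone — enough to inflate a 2 mm cleft's
  area by ~8%. (`presmooth = 0` gives plain marching interpolation at the
  iso level, preferable for analytically smooth fields.)
* the mesh is then smoothed with 50 iterations of Taubin's
  shrink-compensated two-pass filter (λ = 0.63, μ = −0.65). With these
  defaults a voxelised 10 mm sphere and a 20 mm cube at 0.5 mm spacing
  both recover their analytic areas within 2%, the sphere within ~1.4%.

### The oral sheet and defect outlines

All areas are measured on the oral (ventral) sheet of the bone surface,
matching how a repaired palate would be viewed. Faces whose outward
normal lies within `max_tilt_deg` (default 60°) of the ventral direction
are kept and the largest connected sheet retained. A strict "negative
dot product with the dorsal axis" rule would keep half of every vertical
cleft wall; the 60° cap excludes walls while tolerating palatal curvature
up to slopes of ~1.7.

The sheet's boundary edges chain into closed loops: one outer border plus
one loop per through-gap. Because smoothing rounds the corner between the
oral surface and a cleft wall, the raw loop sits a fraction of a
millimetre outside the true bone margin. Each outline point is therefore
*snapped* onto the cleft wall: near-vertical faces (|cos to dorsal| <
0.5, preferring < 0.25) from a minimally smoothed companion surface are
collected near the point, filtered by agreement with the loop's local
inward normal, fitted with a line (or, where two wall orientations meet,
two lines intersected to rebuild the corner sharply), and the point is
projected onto it; its height is re-estimated from the adjacent oral
surface. A three-point circular median filter and a 2-opt uncrossing pass
clean up residual jitter. Wall localisation uses a companion mesh with
only 3 Taubin iterations because heavy smoothing bows the walls of narrow
slots inward by a few hundredths of a millimetre, and because staircase
"riser" faces on an unsmoothed curved sheet would masquerade as walls.

Loops are then classified by their transverse width profile (polygon
scanlines at stations along the principal axis, ends trimmed by 5%, the
10th percentile acting as a jitter-robust minimum): loops narrower than
`min_gap_mm` are bridged sutures, the rest are defects, reported largest
first.

### Virtual filling

Each defect is filled with a tensor-product cubic B-spline patch (8 × 8
control points by default; the rational NURBS form with unit weights is
kept so weighted nets evaluate correctly). The data are the oral-sheet
vertices within `support_band_mm` (3 mm) of the outline plus the outline
itself, parameterised by projection onto the band's principal plane and
mapped to the unit square. The objective is penalized least squares:

* the smoothness penalty takes third-order differences of the control
  net, built from windowed annihilators of the exact control vectors of
  polynomials up to degree 2. Planes and quadratic sheets are therefore
  reproduced *exactly at any penalty weight* (the parabolic palate shell
  is quadratic), while higher-frequency wiggle is damped strongly. This
  matters twice: the data-free hole interior is extrapolated as the
  penalty minimiser, and the closest-point re-parameterization loop
  (below) is unstable under a weak penalty — the fit can chase its own
  parameterization and wrinkle across the hole. The default weight
  (`lambda = 1`) is deliberately strong because it is unbiased for the
  surfaces of interest.
* the outline is up-weighted (10×, escalating ×10 up to three times)
  until it is interpolated to `rms_tol` (0.2 mm).
* after each solve, all data points are re-parameterised by damped
  Newton closest-point projection and the system is re-solved, until the
  RMS improves by less than 1% or `max_iter` (50) is reached; fits
  ending above `5 * rms_tol` raise a failure. The procedure contains no
  randomness, so identical inputs give bitwise-identical results.

The patch is tessellated on a regular parametric grid (64 samples per
direction; doubling changes phantom areas by < 0.5%) and trimmed to the
outline in parameter space: interior triangles are kept, straddling ones
subdivided 4-to-1 up to 3 levels with leaves kept by the centroid rule,
so the trimmed edge tracks the outline to a fraction of a tessellation
cell and trimming can only remove area.

### Morphometry and classification

Cleft area is the trimmed fill area; total hard-palate area is the
residual oral sheet plus all fills — the "virtually repaired" palate.
This definition keeps the percentage well defined for large defects and
makes conservation (intact area ≈ residual + fill) a testable property.
The percentage is rounded half away from zero to an integer, the
convention that reproduces all ten printed percentages of the bundled
case series from their raw areas (e.g. 79/142 → 55.6 → 56). Defect
length is the extent along the configured rostro-caudal axis; widths are
transverse extents of cross-sections sampled at the mesh resolution.
Severity grading is *not* automated: the four-region numerical code
(lip, primary palate, hard palate, soft palate; right/left pairs or a
single midline grade, 0–3) is user input, which the codec validates,
canonicalises to hyphens, and round-trips, accepting the en-dashes found
in print.

## The phantom generator

`phantom_spec()` / `generate_phantom()` build a parabolic-cylinder bone
shell `z = a x^2` (the simplest surface with non-trivial, analytically
integrable curvature) of thickness 1.6 mm, with polygonal through-clefts,
capsule-shaped suture slits, bone at +700 HU (clearly above the 140
threshold but below adult cortical values), soft tissue at +40, air at
−1000, optional seeded Gaussian noise, and a cell-centred voxel grid so
feature edges never coincide with voxel centres. Voxel membership is a
pure centre test — no partial-volume simulation — which keeps the
analytic oracle exact; resolution effects are probed by the spacing sweep
instead. `true_surface_area()` integrates the first fundamental form with
scanline-exact chords and refined Simpson quadrature, and is itself
checked against the closed-form antiderivative
`x sqrt(1+4a^2x^2)/2 + asinh(2ax)/(4a)`.

`standard_suite()` fixes the study conditions: a ~20 × 24 mm palate
(realistic for a day-old puppy), curvature 0.015/mm, cleft widths 2, 5
and 10 mm bracketing the reported 2.1–9.6 mm clinical range, midline,
unilateral and bilateral outlines, an intact control carrying only
0.5 mm suture slits, and voxel spacings 0.5 mm (the scanner slice
thickness) and 1.0 mm. The 1.0 mm member uses a 2.4 mm shell: a 1.6 mm
shell is under-resolved at that spacing and fragments, which is a
statement about imaging resolution, not about the algorithm under test.

What the phantoms do *not* emulate: real skull anatomy (vomer, teeth
buds, rugae), scanner physics (beam hardening, reconstruction kernels,
partial-volume ramps), soft-tissue clefts, and marginal defects that
reach the edge of the analysed region — defect detection currently
handles interior holes only. Passing the phantom suite therefore
demonstrates geometric correctness of the measurement chain, not
robustness to every clinical artifact.

## Verification summary

The test suite asserts, among others: exact reproduction of the ten
case-series percentages; cleft-area recovery within 3% of the quadrature
truth and percentages within 3 points on every 0.5 mm suite phantom
(measured errors are ≤ ~2%), within 5% under 30 HU noise; intact-area
conservation within 3% against cleft-free twin phantoms (measured ≤ ~1%);
oracle agreement to 1e-6; zero defects on the suture control and exactly
one for a 2.1 mm fissure; and bitwise determinism of the fill. Problem
sizes (phantom ~50–60 voxels per axis, tessellation 64²) were chosen so
the whole suite runs in minutes on a single core while keeping every
tolerance comfortably met at 0.5 mm spacing.

## Known limitations

* Marginal (edge-opening) clefts are not detected; outlines must close
  inside the analysed region.
* The coarse 1.0 mm phantom recovers its cleft area only to ~6–10%:
  at two voxels across the narrowest features, outline localisation is
  limited by sampling, as expected.
* Absolute areas from clinical scanners additionally depend on
  reconstruction kernels and any smoothing applied by the acquisition
  workstation, which the phantoms deliberately exclude.
* The total-palate-area definition (residual + fills) is one of several
  defensible conventions; percentages from other software may differ by
  a point for wide clefts.
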