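---
title: "Measuring murine lung tumors in micro-CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring murine lung tumors in micro-CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murinod)
library(ggplot2)
```

murinod measures lung tumors in mouse micro-CT scans and characterises
their growth.  This vignette explains the model behind each stage, the
parameters that matter, what the built-in phantom generator does and does
not emulate, and the design decisions taken where the method left room.

## The measurement problem

Mouse lung tumors appear in micro-CT as soft-tissue-density lesions
(tens to hundreds of HU) inside low-density aerated parenchyma (around
-400 HU at typical inflation).  At ~50 µm isotropic voxels, a 1-2 mm
adenoma spans 20-40 voxels across, but per-voxel noise is high (SD of
tens of HU) and the scanner's effective calibration drifts from session
to session, so a fixed global threshold is unreliable.  Vessels share the
nodule's density and frequently touch it; nodules seated on the pleura
(juxtapleural) merge with the chest wall entirely at any density
threshold.

## Segmentation pipeline

`segment_nodule()` runs the stages below; each is exported separately.

**Seed stroke.**  The only required interaction is a line drawn across
the nodule on one slice (`seed_stroke()`).  Its midpoint anchors the
region of interest; its length approximates the nodule diameter and
scales the vessel filter and the wall-separation neighbourhoods.
Manual editing of the output mask is deliberately not supported: the only
way to change a result is to re-run with different parameters, which
keeps runs reproducible from their provenance records.

**Region of interest.**  A cube of edge `roi_edge` (default 5 mm,
grown in 1 mm steps when the stroke does not fit) centred on the stroke
midpoint.  The voxel count per edge is the nearest odd integer to
`roi_edge / spacing`, so the midpoint sits on the centre voxel; at 0.05 mm
spacing the default ROI is 101 voxels per edge.  ROIs are clamped at the
scan border and the clamping recorded as a warning.

**Adaptive threshold.**  The ROI density histogram (10 HU bins, aligned
to multiples of the bin width so binning is data-order independent) is
assumed bimodal: a parenchyma mode and a soft-tissue mode.  The histogram
is computed before resampling, smoothed with a 5-bin moving average, and
the two peaks are taken as the two highest local maxima at least 100 HU
apart; the threshold is their midpoint.  The peak detector is our own
design choice — bimodality is the assumption, but no detector is implied
by it; a moving-average smoother plus a minimum mode separation of 100 HU
(well below the ~450 HU parenchyma/soft-tissue gap, well above the
10 HU bin) is the simplest detector that is stable under 30-90 HU noise.
Voxels at or below -800 HU are excluded from the histogram: a clamped ROI
can contain air outside the animal, whose -1000 HU mode must not be
mistaken for parenchyma.  A constant or unimodal ROI raises a classed
bimodality error; `threshold_override` bypasses estimation entirely.

**Resampling and thresholding.**  The ROI is resampled to an isotropic
grid at the minimum input spacing (trilinear; an already-isotropic ROI is
returned unchanged, bit for bit), and the threshold labels every voxel at
or above it as soft tissue.

**Vessel removal.**  The soft-tissue mask is opened with a ball whose
radius defaults to `max(1 voxel, 0.1 x stroke length)` — the method
derives the filter size from the user's stroke and lets it be adjusted;
no formula is prescribed, so this default is our choice, sized so that a
nodule-scale object survives while vessels an order of magnitude thinner
do not.  The opened component containing the stroke midpoint is kept and
re-dilated by the same ball, constrained to the original mask: the
opening's erosion of the true boundary is undone without regrowing the
severed vessels (at most one ball radius of vessel stub can return).  A
filter that erases the seed component raises a classed error instead of
guessing.

**Lung mask.**  `compute_lung_mask()` labels sub-threshold voxels,
discards components touching the lateral x/y faces (air outside the
animal; the z faces are exempt because axial scans crop the lungs in z),
and fills holes slice-wise — vessels and nodules are interior to the lung
for this purpose, which is also what a total-lung-volume measurement
wants.  Inside `segment_nodule()` the filling is applied along all three
axes so that vessels running parallel to any slice plane are absorbed.

**Juxtapleural classification and wall separation.**  An isolated
nodule is a filled hole in the lung mask; a juxtapleural nodule merges
with the wall and is not.  The candidate is classified juxtapleural when
at least `contact_min` (default 10) of its voxels lie outside the
hole-filled lung region.  This implements "does the candidate contact
wall soft tissue" directly on wall territory; a dilation-based contact
test against "non-candidate wall" cannot work at this stage because the
attached wall *is* part of the thresholded candidate component.

For juxtapleural nodules the pleural surface is reconstructed and the
mask cut along it.  Lung voxels adjacent to the candidate, in a flanking
band between one and two stroke lengths from the midpoint (widened if
sparse, restricted to the lung component whose boundary comes nearest the
midpoint so the far side of the wall cannot contribute a second, parallel
surface), are fitted with an orthogonal-least-squares plane; if the
residual RMS exceeds `plane_tol` (0.1 mm) a quadratic height field is
fitted instead (`quad_tol` 0.3 mm) — walls are locally flat to gently
curved at nodule scale.  Because the fitted surface interpolates lung
voxel *centres*, it sits half a voxel inside the lung; the cut therefore
keeps candidate voxels up to a quarter-voxel on the wall side, without
which the nodule's entire base layer is shaved off (a systematic ~9%
volume loss for a 0.75 mm hemisphere at 0.05 mm spacing).

The method assumes a single major wall attachment.  Two disjoint wall
patches of at least `contact_min` voxels within one nodule radius of the
midpoint — or a pleural boundary that neither a plane nor a quadratic can
describe — raise a multiple-attachment error.  Both routes are needed:
anatomically the two walls (e.g. lateral wall and diaphragm) are one
connected soft-tissue structure, so counting wall components can never
detect the case.

## Volumetry

Volumes are exact voxel counts times the voxel volume; the
volume-equivalent diameter is `(6V/pi)^(1/3)`.  Two manual comparators
are implemented: the cylindrical bi-dimensional approximation (on every
5th slice, the mean of the longest in-plane extent and its perpendicular
is the diameter of a cylinder five slices tall; volumes are summed) and
full planimetry (shoelace polygon areas times slice thickness).  Each
measured slice is taken to represent the slab `[slice, slice + step)`
starting at the first tumor slice; the anchoring is not dictated by the
procedure's description, so it is exposed as the `step` convention rather
than hidden.

## Growth kinetics

Tumor growth is modelled as `V(t) = V0 e^{rt}` with `t = 0` at each
tumor's first scan.  The rate is estimated two ways, and both are
reported: unweighted nonlinear least squares on the natural volume scale
(the convention of the commercial fitting software this mirrors),
initialised from the log-linear fit, and ordinary least squares of
`ln V` on `t`, which is the representation used for comparing slopes.
A fit requires at least three observations — the same criterion used to
admit a tumor into a longitudinal analysis.  Derived summaries:

* volume doubling time `VDT = ln 2 / r` (days), defined only for `r > 0`;
* growth index `GI = 100 (e^{30.44 r} - 1)` percent per month, with
  30.44 the mean number of days per month; equivalently
  `GI = 100 (2^{30.44/VDT} - 1)`, and the two are algebraically
  consistent to 1e-10 relative over the biologically relevant range.

Slopes from two measurement methods are compared with a pooled-variance
two-line Student's t test on `n1 + n2 - 4` degrees of freedom, which is
identical to testing the interaction term of a dummy-coded combined
regression (the package's tests verify this equivalence to 1e-8).
"R² with a 95% confidence interval" is ambiguous as a specification, so
the package reports R² and standard errors on the slope and rate, from
which a 95% CI on either is `estimate ± t(0.975, n-2) · se`.

```{r growth-example}
series <- readr::read_csv(system.file("extdata", "synthetic_growth_volumes.csv",
                                      package = "murinod"),
                          show_col_types = FALSE)
kinetics <- fit_growth_cohort(series)
kinetics[, c("tumor_id", "r_per_day", "vdt_days", "gi_pct", "r2")]
cohort_summary(kinetics)
plot_growth_series(series)
```

## The synthetic phantom

`build_thorax_phantom()` voxelises a declarative geometry
(`phantom_spec()`): a soft-tissue body cylinder with a chest wall of
configurable thickness, a parenchyma-density lung cavity, an optional
flat diaphragm slab, tubular vessels, spherical nodules (isolated,
juxtapleural against either wall, vessel-attached, or touching two
walls), spherical calibration inserts in the exterior air, and i.i.d.
Gaussian noise.  A voxel belongs to a solid iff its centre is inside the
analytic surface, so voxelisation is deterministic and
resolution-consistent, and each nodule carries two ground truths: the
voxelised mask volume and a grid-free geometric volume (slice-wise
circle-intersection areas integrated over z, truncated at the diaphragm),
which agree within 2% for radii of 8 voxels and up and converge as the
grid is refined.

Default densities are parenchyma -400 HU, soft tissue +50 HU, air
-1000 HU, bone +2600 HU with 60 HU noise.  Air and water are fixed by the
definition of the HU scale; the tissue values are chosen so that the
mode-midpoint threshold lands in the -155 to -190 HU band observed on
repeat scans of live animals, which the default phantoms reproduce
(typically -170 to -175 HU).  The default nodule is a 0.75 mm radius
(15-voxel) sphere — the scale of an early adenoma.

What the phantom does *not* emulate: partial-volume blur at tissue
interfaces (densities are binary plus noise), beam hardening, streaks,
scatter, respiratory motion, and anatomy beyond a cylindrical thorax.
Consequences worth keeping in mind when reading the test results: with
binary densities the thresholded boundary is essentially exact, so
phantom recovery errors (well under 1%) flatter the algorithm relative to
real scans, and the expected growth of relative error towards small
nodule radii is absent — tests therefore bound the error at several radii
rather than asserting a monotone trend that the generator cannot produce.
Threshold placement, vessel filtering, wall separation, attachment
counting and all volumetric and kinetic arithmetic are exercised
faithfully.

```{r phantom-example}
ph <- build_thorax_phantom(phantom_spec(seed = 1))
tidy(ph)
seg <- segment_nodule(ph$image, seed_stroke(c(3.25, 4, 3.2), c(4.75, 4, 3.2)))
tidy(seg)
autoplot(seg$threshold)
```

## Numerical choices and degenerate inputs

* Coordinates are 0-based voxel indices with `world = origin +
  index * spacing`; mask index ranges are half-open.  Sample (n-1)
  standard deviations throughout, matching how scan-to-scan phantom QC is
  conventionally reported.
* Histogram bins cover `[floor(min), ceil(max)]` aligned to bin-width
  multiples: results cannot depend on data order or on a particular
  voxel's value.
* Ties in peak height resolve by scan order of the smoothed histogram
  (lowest bin first); the threshold is the exact midpoint of the two peak
  centres, so it is always strictly between them.
* Trilinear resampling targets the minimum input spacing, never
  upsampling beyond the best acquired resolution; sampling positions are
  clamped to the source grid so no extrapolation occurs.
* Degenerate inputs raise classed conditions rather than returning empty
  results: empty masks/regions, unimodal histograms, strokes outside the
  image, vessel filters that erase the seed, solid volumes without an
  enclosed lung, series with fewer than three scans, non-positive
  volumes, and multiple wall attachments each have their own condition
  class, and pipeline errors carry the identity of the failing stage.

## Problem sizes used in the shipped tests

The test-suite phantoms are 160 x 160 x 128 voxels at 0.05 mm (an
8 x 8 x 6.4 mm thorax section) with one 0.75 mm nodule, which keeps a
full pipeline run around half a second while leaving the nodule 15 voxels
in radius; fit-recovery simulations use 200 series of 4 scans.  These
sizes are stated so results can be reproduced exactly; nothing in the
implementation depends on them.

## Known limitations

* One major wall attachment per nodule; violations error out by design.
* No partial-volume modelling in the phantom (see above), hence no
  sub-voxel boundary accuracy claims.
* The DICOM reader handles explicit-VR little-endian single-frame CT
  series — the form produced by common research converters — and is
  read-only; NIfTI is the canonical round-trip format.
* Growth models beyond the single exponential (Gompertz, logistic,
  mixed-effects) are out of scope.
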