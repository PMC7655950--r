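---
title: "Mapping cold-water coral habitats and the currents that feed them"
author: "reefscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cold-water coral habitats and the currents that feed them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefscape)
```

## The scientific problem

Reef-framework cold-water corals (for example *Desmophyllum pertusum*) live
below the photic zone and feed on particles delivered by near-bed currents.
Field observations place these habitats in energetic settings, yet flume
experiments show the polyps capture food most efficiently at low flow speeds
(around 2.5 cm s^-1^ for zooplankton and 5 cm s^-1^ for phytoplankton).
Resolving that tension requires joining two very different data streams at
one site:

* **spatial**: centimetre-scale photogrammetric products (a digital
  elevation model and an orthomosaic) classified into benthic facies —
  live coral framework (LCF), dead coral framework (DCF), soft coral (SC),
  coral rubble (CR) and sediment (S) — plus terrain aspect over the
  live-coral patches; and
* **temporal**: months of current-meter records (speed, direction,
  temperature, instrument attitude) at a fixed cadence, typically 10
  minutes.

The joining statistic is the **coral-facing mean current speed**: the mean
speed restricted to records whose flow-toward direction travels *into* the
live-coral faces, i.e. within a tolerance of `(aspect + 180) mod 360`.
Comparing it with the unconditional mean, and ranking sites by facies
proportions against current statistics, quantifies whether coral
preferentially occupies (and faces) the calmer component of the local flow.

`reefscape` implements this pipeline end to end, together with a synthetic
scene and current generator so that every stage can be exercised against
known ground truth without any field data.

## One azimuth convention

All azimuths are degrees clockwise from geographic north. Current
directions use the oceanographic **flow-toward** convention; aspect is the
**downslope facing** direction of a surface. The coral-facing statistic is
the one place the two meet, and a convention mix-up there flips the answer
silently, so every report written by `habitat_report()` embeds the
convention string.

## Synthetic study conditions

The generator emulates the *statistical shape* of photogrammetric products
and lander records, not their photographic appearance.

**Terrain** (`gen_dem()`): a gently dipping base plane (default gradient
0.02), `n_mounds` (default 8) superposed two-dimensional Gaussian mounds,
and smoothed small-scale roughness. Defaults are chosen for geometric
coherence at survey scale: 2 cm cells, mound heights 0.3–1 m over
footprints of a metre or two, and roughness with a 5 cm standard deviation
at a ~4 cm correlation length. The roughness amplitude matters more than it
looks: coral framework *is* rough at the decimetre scale, and when
micro-relief gradients are comparable to mound-flank gradients the aspect
distribution of a scene is close to isotropic. With roughness much weaker
than the mounds, a handful of flanks dominate the aspect histogram and any
aspect-conditional statistic inherits their sampling noise.

**Facies** (`gen_facies_map()`): one Gaussian-smoothed white-noise field
per class; each cell takes the class whose field plus a per-class offset is
largest. The offsets are calibrated by a damped fixed-point iteration
(step 1.5 times the fraction error, inner tolerance 0.4 pp, at most 400
iterations) so realized class fractions land well inside the generator's
±2 pp contract. Smoothing (`facies_smooth`, cells) controls patch size;
argmax over smooth fields yields contiguous patches rather than
salt-and-pepper noise. Because the iteration stops at the first iterate
inside the inner tolerance, the realized error tends to sit just below
0.4 pp rather than at zero — a property of the stopping rule, not a bias.

**Aspect-biased live coral** (`lcf_aspect_bias`): when set, the LCF field
receives a dominant bonus term, `exp(3 (cos Δ - 1))` of the angular
distance Δ between cell aspect and the chosen azimuth, lightly smoothed
(σ = 1 cell), standardized and weighted ×6. Live coral then settles on
slopes facing the chosen direction, giving the aspect-extraction stage a
recoverable ground truth. The kernel sharpness, light smoothing and strong
weight were designed together: smoothing the bonus to the full patch scale
lets patches drift onto off-aspect terrain, while a near-pointwise bonus
keeps the circular mean of LCF aspects within a few degrees of the target
across seeds.

**Orthomosaic** (`gen_orthomosaic()`): per-class mean colour plus
spatially autocorrelated noise with the requested per-band standard
deviation, clipped to 0–255. Class palettes are separable by design; the
package makes no claim that classification accuracy on these textures
transfers to real imagery (see *Limitations*).

**Currents** (`gen_adcp()`): velocity vector = steady vector + sinusoidal
tidal vector (default period 12.42 h, the M2 constituent; axis defaults to
the steady heading, configurable for bimodal roses) + isotropic Gaussian
noise. Speed and direction derive from the vector, so speeds are
non-negative by construction and no clipping is ever applied. Tilt rides
at a ~2° baseline and steps above 40° at an optional topple time,
emulating a lander falling over. Timestamps are UTC on the half-open
window `[start, start + duration)`.

All generators save and restore the global RNG state and are bit
reproducible given `(params, seed)`.

## Terrain derivatives

`slope()` and `aspect()` use Horn's 3×3 weighted finite differences, the
convention of mainstream GIS toolboxes, with row 1 as the northernmost
row. Aspect is the downslope azimuth `atan2(-gx, -gy)`; cells whose
gradient magnitude falls below `flat_tol = 1e-8` m/m are flat and return
nodata (exported to ESRI ASCII as −1, the GIS convention). Border cells
and cells whose window touches nodata are nodata. Geographic convergence
is ignored — scene extents are tens of metres at most.

## Object-based image analysis

`segment_scene()` implements multiresolution region merging in the
Baatz–Schäpe family. Starting from single-pixel regions, the pair with the
globally cheapest merge cost is merged while that cost stays below
`scale^2`. The cost is

```
f = (1 - w_shape) * dh_colour + w_shape * dh_shape
dh_colour = sum over layers  w_l (n_m sd_m - n1 sd1 - n2 sd2)
dh_shape  = w_cmpct * dh_compactness + (1 - w_cmpct) * dh_smoothness
```

with population standard deviations, compactness `n·perimeter/sqrt(n)` and
smoothness `n·perimeter/bounding-box-perimeter`. The global minimum pair is
always a mutual best fit, and ties break on lower cost then lower smaller
region id, so results are deterministic. Two consequences worth knowing:

* the merge sequence is identical whatever the scale until the threshold
  stops it, so the segment count is non-increasing in scale by
  construction; and
* executed merge costs are only *near*-monotone — a merge can create a
  cheaper adjacent pair than the one just consumed — so the package
  asserts the auditable contract instead: every executed merge cost is
  below `scale^2`, and at termination no remaining adjacent pair falls
  below it (verified against an independent cost recomputation in the
  tests).

Scale parameters are tool- and data-specific; values quoted for commercial
software do not transfer. `suggest_scale()` merges a scene to completion
and back-solves the threshold that would stop near a target segment count.
The synthetic-site analyses here use scale 26 on 96×96 scenes, calibrated
that way for roughly 150 segments.

`compute_features()` returns per-segment area, centroid and per-layer mean
and population standard deviation, exact by construction.
`classify_nn()` assigns each unlabeled segment the class of its nearest
training segment in z-standardized feature space (statistics from the
training rows only); `k = 1` is the classic behaviour and the default.
Which layers feed the feature space is an analysis choice. The worked
pipeline segments on colour + elevation but classifies on colour + slope:
raw elevation has an arbitrary datum, and once z-scored it can dominate
the distance and pair segments by height rather than appearance, while
slope is datum-free. The operator protocol for accuracy assessment — hold
back a stratified fraction of the training segments (default 30%,
seeded) — is provided by `holdout_split()`, and `accuracy_assessment()`
reports the confusion matrix, overall accuracy, producer's and user's
accuracies and Cohen's kappa (undefined kappa, e.g. a one-class reference,
is `NA` with a warning).

## Current-record quality control and summaries

`read_adcp()` enforces strictly increasing timestamps and non-negative
speeds, flags cadence gaps without failing, and names the first offending
row on error. `trim_and_despike()` drops a configurable head/tail margin
(default 1 h — deployment and retrieval periods are low quality) and flags
records whose speed deviates from a centred 13-record running median by
more than 6 rolling median absolute deviations; flagged records stay in
the table with a reason code and are excluded from every statistic.
`detect_topple()` takes the median tilt of the first six hours as
baseline and returns the first timestamp where tilt exceeds baseline
+ 10° for at least three consecutive records; analyses then use only
records strictly before it.

`summarize_currents()` reports mean and maximum kept speed, exceedance
percentages with strict inequalities exactly as conventionally printed
(< 5, < 10, > 30 cm s^-1^), the dominant direction as the centre of the
modal 10° sector, and temperature statistics. `current_rose()` builds the
joint direction-sector × speed-bin frequency table (16 sectors centred on
north; bins 0–5–10–20–30–∞ cm s^-1^) whose fractions sum to one.

## Integration statistics

`facies_proportions()` is an equal-area cell-count percentage.
`lcf_aspect()` takes the circular (unit-vector) mean of aspect over
LCF-classified cells — equivalent to aggregating segment aspects up to
area weighting — and reports both the 45° compass sector of that mean and
the modal sector, since published habitat tables report orientation
categorically and do not say which summary they use.
`coral_facing_mean()` operationalizes "opposing" as flow heading within
±22.5° (one 45° compass sector) of the direction into the coral face; the
tolerance is configurable because published analyses rarely state one. At
`tol = 90°` two opposite windows tile the circle, and the two conditional
means recombine exactly into the unconditional mean — a useful sanity
check. `feeding_window_pct()` additionally requires speed at or below the
flume-derived thresholds (2.5 or 5 cm s^-1^).

`cross_site_trend()` is a Spearman rank correlation with average ranks for
ties. Site surveys of this kind have 4–7 sites; the statistic is
descriptive and no p-value is attached. `reduction_pct()` returns the
unrounded percentage reduction of the coral-facing mean against the
overall mean; reports round it to integer percent, speeds to 0.1 cm s^-1^
and percentages to 0.1%.

The package ships the printed per-site summary table of a seven-site
cold-water coral survey of the upper Porcupine Bank Canyon
(`upbc_site_stats()`, sites a–g) as the input for the cross-site
statistics; facies percentages never printed for a site are `NA`, not
guesses.

## Problem sizes and numerical choices

The shipped analyses use 96×96-cell scenes (9216 pixels, ~150 segments)
and 27-day simulated deployments at 10-minute cadence (3888 records) —
large enough for stable fractions and circular means, small enough that
the whole suite runs in well under a minute. Other choices collected in
one place: population (not sample) standard deviations throughout the
segmentation and feature code; flat-aspect tolerance 1e-8 m/m; facies
calibration inner tolerance 0.4 pp; despike window 13 records with k = 6;
dominant-direction sector 10°; opposing-window tolerance 22.5°; degenerate
inputs (all-nodata rasters, empty references, zero kept records,
single-class kappa) raise errors or warn-and-`NA` rather than guessing.

## Limitations

* The synthetic orthomosaic has class-separable colour by construction.
  High classification agreement on these scenes validates the OBIA
  plumbing (segmentation, features, nearest-neighbour logic, accuracy
  bookkeeping) — it says nothing about accuracy on real imagery, where
  operator skill, lighting and biological ambiguity dominate.
* Published per-site accuracy figures from commercial OBIA tools are not
  reproducible numerically: the imagery, operator labels and tool
  internals are unavailable. They are context, not targets.
* The current simulator is a two-component kinematic model (steady +
  one tidal constituent + noise). It does not model topographic steering,
  baroclinic variability or storm events; conclusions about those belong
  to hydrodynamic modelling, which is out of scope.
* Segmentation is quadratic-ish in pixel count in this pure-R
  implementation; it is comfortable to a few hundred thousand pixels, not
  for full survey orthomosaics at native resolution.
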