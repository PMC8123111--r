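---
title: "Methods: simulating and classifying water-column targets"
author: "wcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying water-column targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dual-head multibeam echosounders record backscatter through the whole water
column, not just the seafloor return. Surveys around offshore gas platforms
contain four kinds of mid-water scatterers that an analyst wants separated
automatically: fish schools, gas-seep bubble columns, the platform structure
itself, and acoustic noise (sidelobe artefacts, entrained air). `wcpipe`
implements the full processing chain from raw ping fans to per-target class
labels, together with a survey simulator that provides ground truth, so every
stage of the chain is testable end to end.

## Acquisition geometry the simulator emulates

The simulated system forms two fans of 256 equiangular beams, each 75.1
degrees wide, tilted so their union is a single 130.1-degree across-track
swath of 512 beams (the fans overlap by 20.1 degrees). Pings repeat at
2.6 Hz; each sample occupies 0.64 m of range; the along-track beam width is
1 degree. Transects are straight, parallel, run in alternating directions,
and the vessel moves at 2–2.6 m/s, so consecutive pings are less than a
metre apart and a persistent target is cut into several cross-section
"slices". Samples more than 10 m beyond the per-beam seafloor echo are
no-data. Vessel attitude is not simulated: real-time motion compensation is
treated as already applied, since the downstream stages consume corrected
geometry anyway.

The water column sits on a flat seabed at a nominal depth (default 85 m,
muddy-sand-like, with a smooth seeded roughness of about ±0.5 m and no
pockmark microtopography). Background backscatter is a configurable constant
(default −75 dB, uncalibrated) plus additive Gaussian speckle in the dB
domain (σ = 2 dB by default); no published noise model exists for this
quantity, so the simplest one is used and is configuration-exposed.

### Target models

No parametric target shapes are published, so the simulator uses minimal
forms that reproduce the qualitative structure the classes are known for:

* **FISH** — an anisotropic Gaussian ellipsoid (default ~10–16 m wide, 6–8 m
  tall) drifting horizontally below 5 m/s. Echo strength tapers with the
  Mahalanobis distance.
* **GAS** — a narrow vertical column anchored at the seabed containing a
  train of bubble packets (cylinders with seeded radius jitter) that rise
  and respawn at the seabed, so the seep's footprint spans seabed to surface
  while individual packets move. The default packet rise speed is 1.5–2 m/s,
  a typical bubble-plume value; the class accepts any rising speed,
  including the >10 m/s extremes reported for vigorous seeps. At 2.6 Hz a
  10 m/s packet moves 3.85 m between pings, which the prescribed 5-ping
  smoothing kernel (below) would smear into a continuous column; the
  moderate default keeps the simulated seep consistent with the smoothing
  the pipeline itself applies.
* **PLATFORM** — static rectangular pillars spanning the water column
  (default 2.5 m square, four legs). Echo strength grows with depth,
  reproducing the observation that platform slices carry their backscatter
  mass deeper than their geometric centre.
* **NOISE** — diffuse Gaussian patches emulating entrained-air clouds.
  Additionally, `inject_noise()` adds sidelobe arcs (constant-range
  elevations across the beams neighbouring any strong target sample, 20 dB
  down — a typical first-sidelobe level — plus 2 dB per beam of separation)
  and a near-surface entrained-air layer (default 5 m deep, +15 dB).

Ground truth is written cell by cell at injection time; a cell belongs to
the first component that claims it, so every non-background cell is
attributable to exactly one target or noise component.

## The cleaning and extraction chain

1. **Stacking**: the Maximum Intensity operator collapses each ping to a
   range profile holding the per-range maximum over all 512 beams.
2. **Bad-ping rejection** removes pings whose stacked profile exceeds
   background + 15 dB over at least a fraction *f* of the valid range bins.
   The operation's default is *f* = 0.9; the pipeline runs it at 0.98
   because a legitimate platform-spanning ping plus the outer-beam seafloor
   smear already lights up ~93% of the range extent, while genuine
   interference reaches ~100%.
3. **Median and erosion** 3×3 filters clean the stacked echogram (order
   statistics are computed in dB — they are order-preserving, so the domain
   does not matter); edges use replicate padding.
4. **Surface-exclusion line**: per ping, the range nearest the transducer
   where Sv first drops below background + 12 dB, plus a 1 m offset. The
   per-ping crossings are median-smoothed over a 61-ping window: entrained
   air varies slowly, and without the consensus a strong mid-water target
   (or its sidelobe arcs) drags the line down locally. Note the line is a
   *range*: a 5 m-deep layer extends to 5/cos(65°) ≈ 11.8 m of slant range
   in the outer beams, and the exclusion follows the range view.
5. **Bottom line**: per ping, the shallowest range whose median-filtered
   stacked Sv exceeds background + 38 dB — the minimum range of the
   seafloor — followed by a 5-ping median consensus. The scan starts below
   the surface-exclusion line so shallow strong scatterers are never taken
   for the seabed. This is a deliberate simplification of Echoview's
   proprietary Best Bottom Candidate pick.
6. **Ping selection**: after a 3×3 dilation (maximum of the eight
   *surrounding* cells — the centre is excluded), a ping is kept when at
   least one above-threshold sample survives between the two lines.
7. **Seafloor TIN**: per-beam bottom picks (maximum Sv beyond the near
   field and below the surface line) from every third retained ping and
   every fourth beam are triangulated (Bowyer–Watson Delaunay, written
   in-package because no triangulation package is available in the stack)
   and resampled to a 2 m grid with a 20 m maximum triangulation distance.
8. **Fan smoothing**: retained pings are smoothed with the 45-cell kernel —
   3 beams × 5 pings × 3 range bins — as a mean in the *linear power*
   domain (no-data cells excluded; the kernel axes are an assumption, as
   only the cell count is published). The box kernel is separable, which is
   how it is computed.
9. **Exclusion and school detection**: samples within 4 m of the transducer,
   above the surface-exclusion range, below TIN − offset, or no-data are
   masked. The pipeline uses a 3 m offset — the above-threshold shoulder of
   the simulated seafloor echo after smoothing extends ~2 m — while the
   `exclusion_mask()` operation defaults to 1 m. 8-connected components of
   above-threshold samples (default background + 10 dB) that are at least
   1 m tall and 1 m wide become polygon slices; the polygon is the traced
   boundary of the member cells in the across-track/depth plane.
10. **Extrusion and tracking**: each polygon is extruded ±0.4 m along-track
    into a 0.8 m prism; slices in pings at most one apart whose 3D world
    centroids lie within 5 m are linked, and multi-ping objects are the
    connected components of the link graph (centroid linkage is an
    assumption; the reference tracker's criterion is unpublished).

## The 24-metric schema

Each slice is characterised by 24 features (position, shape, backscatter,
swath intersection, kinematics, and a k-means cluster code). Conventions
worth noting:

* Mass centres weight sample positions by linear power, `10^(Sv/10)`.
* The sample mean is a linear-domain mean reported in dB, so
  `Sv_UNCAL diff = max − mean` is never negative.
* `Base = surface area / height` uses the full polyhedron surface area
  (two caps plus walls), so `Base × Height = Surface area` holds
  identically.
* The bounding box is transect-aligned: 0.8 m (along) × width (across) ×
  height; `Length 1 ≥ Length 2` are the two longest dimensions.
* `Relative depth in time` differentiates the *geometric*-centre depth of
  consecutive slices in an object (positive = rising); the mass-centre
  depth was evaluated as an alternative and is distinctly less stable
  under partial insonification at a pass's edges. Slices sharing a ping
  within one object are aggregated per ping before differencing; the last
  slice inherits the previous value and singletons are 0.
* The flattened x/y are the mass-centre coordinates (the schema's
  definition; the workflow description says geometric centres — the schema
  was followed) in a local equirectangular projection about the survey
  origin: x is northing from latitude, y is easting from longitude.
* `Cluster` is k-means (k = 4) on standardized Vertices, mass-centre
  latitude and longitude, with codes relabelled by ascending centre vertex
  count so a refit under the same seed is stable.

## Semi-supervised classification

An operator labels a stratified ~8% of slices (the simulator stands in for
the operator using ground truth). Labels then:

1. **extend** within multi-ping objects (majority; ties stay unlabelled),
2. **normalize**: per-feature Yeo-Johnson maximum-likelihood transform plus
   standardization, fitted on the training survey, with the six raw
   coordinate columns exempt,
3. **pseudo-label**: a distance-weighted kNN (k = 5, Euclidean) fitted on
   the labelled rows labels the rest. The kNN operates on the 18
   non-coordinate features: metre-scale x/y would dominate a Euclidean
   metric and reduce the labeller to a spatial smoother. Quality is
   reported on a stratified 30% hold-out of the labelled rows.
   Pseudo-labels are accepted unconditionally in a single pass; an optional
   confidence threshold exists but is off by default.
4. **split** 70:30 stratified, **train** a gradient-boosted ensemble
   (xgboost) by exhaustive grid search — learning rate {0.05, 0.1}, trees
   {100, 300}, depth {2, 3}; the published search grid is unavailable —
   with stratified 5-fold cross-validation, ties broken toward fewer trees
   then shallower depth, and **evaluate** on the held-out 30%.

The six coordinate columns are excluded from the ensemble so the model
transfers to other sites; `Cluster` is retained. On unseen surveys the
cluster feature is refit per survey (k = 4, stored seed) because stored
centroids encode site geometry; the stored Yeo-Johnson parameters and
feature schema are applied as fitted. Mutual-information scores
(plug-in estimate on quantile-discretised features; discrete features use
their values as categories) are reported for inspection only — the schema
is fixed.

All randomness flows from one survey-level seed through stable per-stage
derived seeds; boosters run single-threaded, so reruns are bit-identical.

## Ground truth for detected slices

A detected slice is labelled with the ground-truth class carrying the most
linear-domain power among its member samples — across the same 5-ping
window the smoother used, because a slice can be the temporal smear of a
target insonified in a neighbouring ping (this genuinely happens where a
seep is seen twice, once per transect, at the far swath edge). A slice with
no target power anywhere in its window is residual clutter and is labelled
NOISE. Without the power weighting, a target would be out-voted by the
weak sidelobe-arc cells it drags along.

## Problem sizes and what the tests show

The packaged study conditions are a compact survey: two 220 m transects
100 m apart in 85 m of water, ~500 pings of 512 beams × ~330 range bins,
with four platform legs, five fish schools, four gas seeps and three noise
patches. This yields roughly 250–300 slices in 40–50 multi-ping objects —
about a tenth of the slice count of a full survey — and processes end to
end in about a minute on one core. Unit tests run on a further-reduced fan
(128 beams, 30 m of water).

Passing tests demonstrate that the chain recovers *this simulator's*
targets: simple parametric shapes, a flat seabed, Gaussian speckle, no
attitude errors, no calibration drift, and ground-truth operator labels.
They do not demonstrate performance on real surveys, where target shapes
are irregular, labels are imperfect and the noise field is richer; the
class-confusion structure (gas vs noise hardest, fish and platform easy)
does, however, mirror what is reported for real data.

## Known limitations

* Slices are 2D cross-sections; full 3D single-object delineation is out of
  scope, as is kinematic (velocity-model) tracking.
* The stacked-beam view conflates slant range with depth, so ping selection
  can miss targets that appear only beyond the nadir seafloor range in the
  outer beams; slices from far off-nadir views are heavily smeared and are
  the main source of gas/noise confusion.
* Platform slices at the first and last pings of a pass are partially
  insonified (the along-track beam footprint widens with range, so a pass
  begins and ends seeing only the deep part of a leg). Their
  relative-depth-in-time values are therefore biased — the exit edge is
  negative, and the last-slice-inherits convention repeats it — so the
  per-class median sits slightly below zero and varies by a tenth of a
  metre per second or so between survey realisations.
* Bathymetry-derived features (slope, curvature) are not computed.
* The Bowyer–Watson triangulation is O(n²) in the worst case; soundings are
  decimated to at most 1500 points before triangulation.
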