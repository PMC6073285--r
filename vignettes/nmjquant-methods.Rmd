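---
title: "Quantifying marker accumulation and 3D proximity at neuromuscular junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker accumulation and 3D proximity at neuromuscular junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neuromuscular junctions (NMJs) are classically studied as tripartite
synapses, but sympathetic axons are frequently found in their immediate
vicinity, and quantifying that relationship from multichannel confocal
images raises two recurring measurement questions:

1. **Accumulation**: in a muscle cross-section, is a given marker protein
   (e.g. tyrosine hydroxylase, neuropeptide Y, the β2-adrenergic receptor,
   or the vesicular acetylcholine transporter as a positive control)
   *enriched* at an NMJ relative to the surrounding muscle fiber?
   Summed over many NMJs this yields a "percent immunopositive NMJs"
   statistic that can be followed across postnatal development.
2. **Proximity**: in a 3D volume, how far is each NMJ postsynapse — defined
   by α-bungarotoxin (BGT) labelling of acetylcholine receptors — from the
   nearest object in a marker channel, measured edge-to-edge in physical
   units?

`nmjquant` implements both readouts as a reusable, fully tested pipeline,
together with a ground-truthed synthetic image generator so that every
stage can be validated without any external data.

## The accumulation model

The postsynapse channel of a planar section is median filtered (radius 1,
i.e. a 3×3 window — the ImageJ "Median… radius 1" convention) and
thresholded on the inclusive grey-value range 30–255. Eight-connected
components of at least `min_roi_area_px` pixels (default 20) become NMJ
regions of interest (ROIs), ordered by centroid for determinism.

For each ROI a paired *muscle fiber* reference region is required. The
original procedure outlined a fiber area interactively and does not state
how; we define it deterministically as the ring obtained by dilating the
ROI with a square structuring element of radius `fiber_ring_radius_px`
(default 10), minus the ROI itself and minus the pixels of every other ROI.
This perisynaptic ring samples the same fiber(s) that carry the NMJ,
scales with ROI size, and cannot overlap a neighbouring synapse. A ROI
whose ring is empty (degenerate, e.g. a ROI filling the field) is flagged
"undefined fiber region" and excluded from the percentage denominator; the
exclusion is counted, never silent.

The call itself, computed on the *marker* channel, is

> positive  ⇔  mean(NMJ ROI) > mean(fiber) + sd(fiber)

with a strict inequality: equality is negative. Because both sides are
affine-equivariant, the call is invariant under any positive affine
rescaling of the marker channel — an important robustness property for
8-bit data with arbitrary gain, and one of the property tests of the suite.
The standard deviation is the sample standard deviation; a single-pixel
region has sd 0.

## Segmentation and edge-to-edge distances

The 3D analysis mirrors a classical threshold segmentation:

* **Binarization** at inclusive intensity bounds per channel: BGT 20–255,
  TH 6–255, neurofilament L 22–255, VAChT 20–255.
* **Connected components** under 26-connectivity by default. The upstream
  tooling does not state its connectivity; 26 is the common default for 3D
  particle analysis, and 6/18 are available and tested. Labels are
  assigned in array storage order, so labelling is deterministic.
* **Size filtering** with inclusive bounds: 50–20,000,000 voxels for the
  postsynapse channel, 3–2,000,000,000 for marker channels (filamentous
  stains need the larger maximum). Bare object sizes are interpreted as
  voxel counts.
* **Edge exclusion** for the postsynapse channel only: any BGT object with
  a voxel on an x, y or z face of the grid is removed, since its size and
  border are unknowable. Marker channels keep edge objects. For
  single-slice data the z faces are ignored (every object would otherwise
  touch them — a degenerate case the 3D analysis never meets).

**Edge-to-edge distance** between two objects is realized as the minimum
anisotropic Euclidean distance between voxel centres over the two objects'
border voxels, where a border voxel has at least one face-neighbour outside
the object; objects that share a voxel (possible after independent
per-channel segmentation) have distance 0. Voxel centres of border voxels
are the only sub-voxel-model-free choice; the convention is documented and
its recovery error is bounded by tests (below). Distances weight the axes
by the physical voxel size (dz, dy, dx), e.g. two voxels three lateral
pitches apart at 0.785 µm are 2.355 µm apart.

The per-NMJ nearest-marker search prunes candidates with a bounding-box
lower bound and early termination; a dedicated test verifies on hundreds of
random volumes that it returns exactly the brute-force all-pairs minimum,
with ties broken toward the lower object id.

The summary statistic is the fraction of NMJs with distance strictly below
a cutoff (default 2 µm, matching the published "less than 2 µm" phrasing;
an NMJ at exactly 2 µm is not counted), plus a histogram over right-open
0.5 µm bins and an empirical CDF whose value at the cutoff equals that
fraction. NMJs with no marker object anywhere are reported as an overflow
count with infinite distance.

## The synthetic generator

The generator emulates the stained structures, not the biophysics:

* **Postsynaptic plaques**: spheres of radius 3 µm placed without overlap
  inside a central *synapse band* (default 20 % of the y extent). In 3D
  they are rendered as hollow shells (thickness 1 µm), matching the
  ring-like appearance of en-face postsynapses and of marker plaques that
  outline rather than fill the BGT footprint; planar sections use filled
  discs.
* **Apposed boutons**: for a deterministic `round(fraction × n)` of NMJs
  (selected by a seeded shuffle, avoiding binomial jitter on small test
  images), a marker sphere of radius 1.5 µm placed so that the
  surface-to-surface gap is drawn uniformly from `apposition_gap_um`
  (default 0–0.5 µm).
* **Filamentous axons**: capsules of half-length 15 µm and radius 0.5 µm,
  routed tangentially past positive NMJs at the sampled gap, plus
  background axons at a configurable length density. Both are
  rejection-sampled so that no axon passes within the far bound of a
  marker-negative NMJ. In planar cross-sections, filament-positive NMJs
  additionally receive a plaque-like marker footprint inside the plaque
  (filament-marker-positive NMJs show the marker underlying the
  postsynapse in a plaque-like manner, and a thin crossing axon alone
  barely lifts the ROI mean while inflating the fiber ring's standard
  deviation).
* **Diffuse receptor signal**: a uniform fiber-level background with a
  perisynaptic enrichment footprint at positive NMJs.
* **Forward imaging**: rasterization at configured intensities (plaque
  200, marker 200, filament 120, enrichment 120, diffuse background 10,
  fiber background 40 on the 0–255 scale), separable Gaussian blur with
  sigma 0.5 µm weighted per axis by the voxel size (the generator applies
  forward blur; deconvolution is therefore unnecessary), then Poisson shot
  noise at 4 photons per grey level followed by additive Gaussian noise
  (sd 2), clipped to 8 bits.

Default grid geometry is 12 × 1024 × 1024 voxels at 1 × 0.785 × 0.785 µm —
the acquisition geometry of the quantitative distance analysis. Continuous
coordinates are authoritative: every NMJ's *true gap* to the nearest marker
structure is recorded analytically before voxelization, which makes
recovery tolerances explicit (a voxelized measurement can differ from the
analytic truth by at most one voxel diagonal, ≈ 1.49 µm at these voxel
sizes, and typically far less).

Three placement rules keep the truth labels meaningful:

* minimum surface separation between plaques of 9 µm, which exceeds the
  far bound (5 µm) plus the largest apposition gap plus a bouton diameter —
  so a *negative* NMJ can never sit within the far bound of a neighbour's
  marker;
* a placement margin of plaque radius + 2 µm from every image face, so
  that at the default PSF the thresholded contour of a blurred plaque
  never touches a face and edge exclusion removes nothing by construction
  (objects near edges are still exercised by dedicated fixtures);
* in planar cross-sections, positive marker structures are placed
  *overlapping* the plaque footprint (a section through the
  plaque-underlying marker structure), because the accumulation readout
  measures enrichment within the ROI; their true gap is 0, and
  surface-gap sampling applies to the 3D geometry.

### Developmental time-course defaults

The per-(marker, age) positivity fractions bundled with the generator
follow the reported developmental trends: TH 0.40 → 0.90 and NPY 0.08 →
0.60 from birth to adulthood, β2AR constant at 0.85 with a decline to 0.70
in the adult, VAChT constant at 0.95 (the midpoint of the reported
90–100 % range). The intermediate ages P21 and P30 are monotone
interpolations chosen once, not reported values. The time-course runner
renders `n_replicates` (default 3) independent fields per age and reports
the mean ± SEM of the percent-positive statistic over replicates.
Significance testing between ages is deliberately out of scope (the
original test is unspecified); the output is descriptive.

## What passing tests do and do not show

The generator produces plaque-like, filament-like and diffuse structures
with realistic sizes, intensities, blur and mixed noise, but it does not
model spectral bleed-through, depth-dependent attenuation, tissue-clearing
artifacts, anisotropic PSF side lobes, or segmentation-adversarial shapes
(touching NMJs, branching terminal arbors). Recovery results on synthetic
data therefore validate the *computational* pipeline — thresholds applied
as stated, inclusive boundaries, exact nearest-object minima, strict
cutoffs, determinism — not the biological accuracy of any particular
threshold choice on real tissue, which has no deposited raw data to
recompute.

## Numerical choices and degenerate inputs

* Median filter borders use edge replication; the window is always the
  full (2r+1)² square.
* Threshold and size bounds are inclusive at both ends; positivity and
  proximity cutoffs are strict.
* An empty ROI set, an empty fiber ring, an all-edge postsynapse channel
  and an empty marker channel are all reported (flag, warning, or infinite
  distance) rather than raised, except that a study with *zero* retained
  postsynaptic objects aborts with a diagnostic.
* Ties in the nearest-marker search break toward the lower object id;
  object labels themselves are storage-order deterministic.
* All randomness (placement, noise) derives from a single integer seed;
  the analysis stages are seed-free, and two runs with the same
  configuration and seed produce byte-identical result files (provenance
  records deliberately exclude wall-clock time).
* Intensities above 8 bits are rejected on input unless an explicit linear
  rescale is requested, because every threshold in the pipeline is defined
  on the 0–255 scale.

## Problem sizes used by the shipped tests

The suite validates the pipeline at deliberately compact scales: random
16³–24³ volumes against brute-force oracles (connected components via an
independent graph library; distances via all-pairs minima), 128²–512²
synthetic fields for classifier recovery, 50 seeded small volumes for
gap-recovery bounds, and one full-scale run (200 NMJs on the default
12 × 1024 × 1024 grid) reproducing the headline result that essentially
all apposed postsynapses are recovered below the 2 µm cutoff. The same
full-scale computation is what `scripts/acceptance.R` re-runs from scratch.

## Known limitations

* The fiber reference ring is a deterministic stand-in for an
  interactively outlined fiber area; absolute percent-positive values on
  real data may shift slightly with ring radius (the call's affine
  invariance limits, but does not remove, this sensitivity).
* Edge-to-edge distances are voxel-centre based; sub-voxel surface models
  (marching cubes, distance transforms with linear interpolation) could
  reduce the discretization bound below one voxel diagonal but introduce
  their own conventions.
* Watershed splitting of merged objects and the upstream tool's other
  colocalization measures (centre–centre distances, overlap volumes) are
  out of scope.
* The generator's axon-length density has no published reference value and
  is a free parameter.
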