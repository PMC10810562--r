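---
title: "Quantifying niche aging in the C. elegans distal gonad: models and methods"
author: "nicheQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying niche aging in the C. elegans distal gonad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheQuant)
```

## The biological problem

The single distal tip cell (DTC) caps the distal end of each *C. elegans*
gonad arm and acts as the niche of the germline stem cell (GSC) pool: it
activates Notch signaling in nearby germ cells, which switches on target
genes such as *sygl-1*. Transcription at an individual gene copy shows up
in single-molecule FISH (smFISH) as a bright nuclear focus where an
intron-targeted probe and an exon-targeted probe colocalize — an active
transcription site (ATS). Because each germ-cell nucleus carries up to four
copies of the locus, a nucleus can hold 0–4 ATS. Mature mRNAs appear as
dim, uniform cytoplasmic spots in the exon channel.

During early adult aging (Days 1–4), the DTC nucleus drifts away from the
distal tip, and the spatial pattern of Notch activation — the fraction of
cells with at least one ATS as a function of distance from the tip —
flattens and shifts proximally with it. `nicheQuant` implements the
quantitative machinery needed to measure this: 3D nucleus reconstruction
from DAPI, ATS/mRNA calling from the smFISH channels, radius-capped
Voronoi assignment of spots to cells, the spatial statistics of the
activation gradient and of the DTC, and DTC membrane morphology (cap,
gaps, processes, fragments). A seeded generative model of an aging distal
gonad provides rendered stacks with ground truth, so every stage is
testable end to end without microscope data.

## The synthetic gonad

### Geometry

The distal analysis window is modeled as a straight cylinder: distal tip
at the origin, gonad axis along +x, microns everywhere. Defaults
(`GonadGeometry()`): a 60 µm window of a 20-µm-diameter tube holding 200
germ-cell nuclei of diameter 3.8 ± 0.3 µm, packed by dart-throwing with
rejection (centers at least 0.9 × the radius sum apart, fully inside the
tube). Only the distal window is modeled — the bent, U-shaped remainder of
the gonad arm is out of scope, which is also why axial (arc-length)
distance and straight-line x coincide here.

The rendered grid extends 2.5 µm distal of the tip and 1.5 µm beyond the
tube laterally, as a real crop does; without the distal margin the DTC
nucleus — which hugs the tip in young adults — would be clipped by the
image border and its measured position biased proximally.

### Biology

`BiologyModel(ageDay)` fixes the age-dependent laws:

* **Activation profile** p(d): the probability that a cell at axial
  distance d has at least one active locus, interpolated piecewise-linearly
  through a per-day anchor table. The published constraints are anchors,
  not a full curve — roughly 70% activation in the distal-most region, a
  peak near 5 µm and a fall below 2.5% by ~25 µm at Day 1; a flattened
  profile peaking near 15 µm at Day 4. The free anchors between them were
  calibrated by Monte Carlo so that (a) statistics computed directly on
  ground truth and (b) statistics recovered by the full image pipeline both
  hit those anchors; the detection stage attenuates percentages by a few
  points, and the calibration deliberately accounts for that jointly, which
  is why the table values are not exactly the published percentages.
* **Per-locus law**: each of the 4 loci is an independent Bernoulli draw
  with q(d) solving 1 − (1 − q)^4 = p(d), so the per-cell activation
  probability matches the profile by construction.
* **DTC drift**: lognormal, truncated at 55 µm by resampling.
  Day 1: meanlog = log 2 − 0.18, sdlog = 0.6 (mean ≈ 2 µm, ~97% below
  5 µm). Day 4: meanlog = 2.13, sdlog = 1.35, moment-matched under
  truncation to a mean of ~12 µm with P(drift ≤ 5 µm) ≈ 0.38 and samples
  reaching past 40 µm. Days 2–3 interpolate the progression.
* **Activation–DTC coupling**: the per-gonad profile is translated by
  `activationCoupling × (drift − driftRef)` along the axis (defaults:
  coupling 0.7, reference drift 2/5/8/11 µm for Days 1–4), with the
  vacated distal region decaying exponentially instead of inheriting
  distal-level activation. This encodes the central observation the
  package exists to quantify — Notch activation clusters around the niche
  nucleus wherever it sits — and it is what keeps the mean distance
  between ATS-positive cells and the DTC nucleus nearly age-invariant
  (~10–13 µm) even as the DTC wanders; with independent draws that
  distance would inflate to ~17 µm at Day 4. It also reproduces the high
  per-gonad variability of Day-4 peak positions: because each gonad's
  profile is a translated copy under a heavily skewed drift law, the
  Day-4 cohort-averaged profile is intrinsically flat-topped, and its
  argmax reproduces within one bin in only about three of four random
  25-gonad cohorts — a property of the modeled biology, not of the
  estimator. The Day-4 anchor table peaks at 18 µm so that this skewed
  averaging puts the cohort-level peak near the published ~15 µm.
* **ATS intensities**: lognormal (meanlog = log 3, sdlog = 0.55) in units
  of one mRNA equivalent. Only ATS at least as bright as a single mRNA are
  *callable* (that is the published filter), so the sub-unit tail of the
  truth law is unobservable in real data; the law was chosen jointly with
  the detection stage so that cell-level ATS sensitivity stays above 0.9.
* **mRNA counts**: negative-binomial per cell (dispersion 5) with mean
  tracking the (shifted) activation profile, scaled to 20 at the peak.
  The source measurements publish no absolute counts; these are simulator
  defaults chosen so the ">10 mRNA per cell" region used for region-center
  analysis is non-empty and co-located with the ATS region. They are not
  claims about real transcript numbers.
* **Morphology**: beyond the meiotic onset (35 µm at Day 1, moving
  distally with age), cells are crescent-class with probability 0.35;
  crescents are rendered as lunes (sphere minus an offset sphere). Germ
  nucleoli are dark DAPI cores of diameter 1.5 ± 0.15 µm; the DTC nucleus
  is an ellipsoid (semi-axes 3 × 1.5 × 1.5 µm, long axis in the imaging
  plane) without a dark core.
* **Membrane**: cap shell over the distal ~6 µm with Poisson-count angular
  gaps whose mean length grows with age (2 → 4.4 µm), two long external
  process (LEP) ribbons reaching 35–46 µm, short intercalating process
  (SIP) spokes attached to the membrane, and detached fragments (count
  falling with age, lengths ~1.6 µm).

### Optics

`OpticsModel()`: 0.13 µm pixels, 0.3 µm z-step, Gaussian PSF with
σ~xy~ = 0.15 µm and σ~z~ = 0.45 µm, per-channel backgrounds (photons),
500 photons per 1 a.u. spot, Poisson shot noise plus Gaussian read noise
(σ = 2). Nuclei are rasterized and convolved; RNA spots are rendered as
analytic Gaussians with sub-voxel placement, which preserves their
integrated intensity exactly. The renderer is deterministic given a seed.
Values other than the z-step are plumbing choices of the simulator, not
published numbers. Photophysics beyond this model (aberrations,
deconvolution artifacts of computational clearing, depth-dependent
scattering, autofluorescence structure) is deliberately out of scope —
passing recovery tests on these renders shows the pipeline's logic is
correct at realistic SNR, not that it is robust to every real-microscope
artifact.

## The measurement pipeline

### Nucleus reconstruction

Each DAPI plane is normalized to the mean intensity of its nucleus-free
background (pixels below the plane's Otsu split, eroded 2 px). A circular
Hough transform with Sobel gradient voting (radius range 1.0–3.5 µm,
2-px radius step, votes normalized by circumference) detects per-plane
circles; circles are chained across consecutive z-planes by proximity to
the chain's running mean center. A chain becomes a nucleus only if it
spans ≥ 4 consecutive planes and its centers spread < 0.5 µm in XY — both
criteria enforced exactly — and the sphere is fit by linear least squares
on r² + z² (XY center: score-weighted mean). Chains fitting spheres below
1.3 µm are discarded as slicing artifacts: real germ nuclei are never
that small, and such chains arise when circle detection slices the
elliptical DTC.

Chaining alone misses a few percent of nuclei in dense packing (in-plane
suppression between abutting neighbors) and cannot represent the DTC,
whose elliptical cross-sections scatter Hough votes along the major axis.
A rescue pass therefore labels bright 3D components not claimed by any
fitted sphere, splits components larger than any single nucleus
(deterministic farthest-point-seeded Lloyd clustering), volume-gates them,
and admits them as nucleus records. With it, recall and precision against
ground truth exceed 0.95 at default noise.

Morphology classification uses the geometry of the dark sub-region at the
nucleus mid-plane: a centered enclosed dark core → mitotic ("donut"); an
offset dark region or a concave (low-solidity) bright mask → crescent; no
dark core with mid-plane eccentricity ≥ 0.6 and a center at least as
bright as the rim → DTC candidate. The DTC is the candidate maximizing
eccentricity × central-to-rim ratio, ties broken toward the tip. The
enclosure test (dark pixels must see bright mask on all four axis
directions) prevents background beyond an elliptical rim from being
mistaken for a core. Thresholds are recorded tuning decisions, set once
against rendered ground truth.

Nucleolus diameters are estimated from the second moment of the darkness
deficit at the mid-plane (three central planes averaged), PSF-corrected
and affinely calibrated against the forward model. Cores below the axial
resolution of the modeled optics (σ~z~ = 0.45 µm, FWHM ≈ 1.1 µm) are
reported as absent; the estimator is validated on 1.25–2 µm cores, which
covers the default 1.5 µm germ nucleolus.

### RNA detection

The intron and exon channels are processed independently. Candidates are
3D local maxima of the PSF-smoothed channel above an adaptive floor
(median + 6 MAD of the smoothed germline signal), refined to sub-voxel
precision by per-axis parabolic fits. Two filters mirror the published
rules exactly: peak / mean-overall-germline-background > 1.0, and
peak / local-background > 1.05, where the local background is the mean in
the 1–3 spot-radius shell (the operationalization of "within 3× the
distance from the center"; the shell excludes the spot core). Spot
intensity is the background-subtracted integral over a 2σ ball; the
integration fraction cancels in normalized units.

Exon candidates inside a nuclear sphere are nuclear; the rest are
cytoplasmic mRNAs, whose mean raw intensity defines 1 a.u. per gonad, so
the mean cytoplasmic intensity is exactly 1 a.u. by construction. A true
ATS must (1) lie inside a nucleus, (2) colocalize with an exon nuclear
spot (mutual nearest neighbor within 0.4 µm), and (3) be at least 1 a.u.
bright in both channels; its reported intensity is the exon-channel a.u.
Spots are assigned to cells by the nearest nucleus center within a 3 µm
cap — exactly the bounded 3D Voronoi cell model. Unresolvable proximate
mRNAs (closer than the PSF) merge into single detections; this inflates
the single-mRNA unit by ~8% and is the main detection bias at default
density. Overlapping-ATS deblending is out of scope, as in the source
method.

### Spatial statistics

The per-cell table joins nuclei and spots (one row per non-DTC nucleus)
with axial distance, Euclidean distance to the DTC nucleus, ATS count,
summed ATS a.u. and mRNA count. On it the package computes: binned
percent-positive profiles (2.5 µm half-open bins by default; per-gonad
profiles averaged across gonads with equal weight), the profile peak
(maximum bin center, distal on ties), the pool boundary (first
sub-threshold bin at/after the peak, with a one-bin excursion forgiven),
nearest-neighbor distances, the DTC shift (3D Euclidean, not arc length —
as specified for DTC-relative quantities), mean distance of qualifying
cells to the DTC, Pearson correlation with line fit of summed ATS (over
ATS-positive cells) or mRNA count (over all cells) on DTC distance,
mRNA-rich region centers (> 10 mRNA/cell) and their separation, region
extents, and the progenitor-zone extent (most distal position where more
than one crescent falls within a one-cell-diameter axial window; full
window length, flagged, when no such pair exists).

Group comparisons follow the published recipe: Anderson–Darling normality
at α = 0.05 on every group (the publication states no α; 0.05 is our
recorded choice), then Welch t-test (2 groups) or one-way ANOVA (> 2) if
all pass, otherwise Kolmogorov–Smirnov, applied pairwise for more than two
groups (pooled vs pairwise is unstated in the source; pairwise recorded).
No multiple-testing correction is applied, mirroring the source. Stars:
\* < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001.

## Numerical and design choices

* Bins are half-open [lo, hi); a cell exactly at the top profile edge
  joins the last bin. Voxel indices are 0-based internally; world
  coordinates are voxel centers.
* Ties in capped-Voronoi assignment go to the lower nucleus id; profile
  peak ties go distal; DTC score ties go to the tip.
* "Consecutive planes" is read strictly: a one-plane gap breaks a chain.
* The colocalization matcher is mutual-nearest-neighbor; on instances
  where pairs are separated by more than twice the tolerance it coincides
  with optimal assignment (verified against an enumeration oracle).
* Degenerate inputs: empty gonads yield a truth table with only the DTC;
  packing failure reports the achievable count; spheres smaller than a
  voxel still integrate their containing voxel; a gonad with no
  cytoplasmic spots has no intensity unit and errors; a profile never
  crossing the threshold has no boundary (NA).
* Problem sizes: the test suite analyzes two 25-gonad cohorts at default
  geometry/optics plus smaller fixtures; the acceptance script simulates
  40 gonads per age day, running the full detection pipeline on 25 of
  them and DAPI-only DTC localization on the remainder (the drift
  statistics need no RNA channels). A full gonad renders and analyzes in
  roughly 10–15 s on one CPU.

## Known limitations

* The simulator is the only test bed: real widefield stacks carry
  artifacts the forward model omits, so recovery rates here bound the
  pipeline's logic, not its field performance.
* The nucleolus protocol measures the DAPI dark core; a dedicated
  nucleolar stain is a different measurement and may differ
  systematically.
* Sub-resolution structure (nucleoli < ~1.2 µm, mRNAs closer than the
  PSF, overlapping ATS) is not resolved, only flagged or merged.
* The straight-tube geometry makes arc length trivial; on a curved gonad
  the medial-axis projection would need a real centerline.
* mRNA counts per cell are simulator placeholders; statistics that depend
  only on their spatial arrangement (region centers, extents) are
  meaningful, absolute counts are not.
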