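---
title: "Quantifying worm morphometry, defecation rhythm and receptor assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying worm morphometry, defecation rhythm and receptor assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormpheno)
```

## Scope and model

`wormpheno` implements the measurement side of a *C. elegans* phenotyping
study: body morphometry from calibrated micrographs, intestinal luminal
width, defecation motor-program (DMP) rhythm statistics from behavioral
event logs, and cAMP-reporter bioluminescence normalization. It makes no
inferential claims — every output is a descriptive quantity in a tidy
table, ready for whatever statistics package the analyst prefers.

The geometric model underlying morphometry is deliberately simple and
shared between the estimator and the synthetic generator: the worm is a
tube of circular cross-section swept along a smooth planar midline. Total
volume is estimated by dividing the midline into 30 equal-arc-length
segments, measuring the body radius at the 31 segment boundaries, and
summing frusta of cones:

$$V = \sum_{i=1}^{30} \frac{\pi h}{3}\left(r_{i-1}^2 + r_{i-1} r_i + r_i^2\right),
\qquad h = L/30 .$$

Two identities anchor the implementation: a constant profile reduces the
sum exactly to the cylinder $\pi r^2 L$, and the sum is *exact* for any
radius profile that is linear within each segment (hence the cone closed
form). For smooth profiles with bounded curvature the 30-segment sum
tracks a $10^5$-point quadrature of $\pi r(s)^2\,\mathrm{d}s$ to well
under 0.5 %; the test suite checks this on random trigonometric profiles.

## Measurement pipeline

`measure_worm()` chains five stages, each exported on its own:

1. **Segmentation** (`segment_worm`): global Otsu threshold (override via
   `config$threshold`), hole filling, removal of objects below
   `min_area_px` (default 100 px), retention of the largest connected
   component. A mask that touches the image border is rejected
   ("worm clipped"), as are featureless images ("no worm found").
2. **Midline extraction** (`extract_midline`): Zhang–Suen thinning to the
   topological skeleton, then the longest geodesic path between skeleton
   endpoints on the 8-connected pixel graph (diagonal steps weigh
   $\sqrt2$), with ties broken toward the lexicographically smallest
   endpoint pair. Skeletons with more than `max_branches` (default 10)
   side branches are rejected as coiled/overlapping: the study images
   anesthetized, extended animals, and untangling is out of scope.
3. **Tip handling.** Thinning skeletons misbehave within about one
   *local* body half-width of each end: blunt-ended masks sprout oblique
   branches toward outline corners and the medial axis stops short of the
   end face, while genuinely pointed tips are reached almost exactly. The
   path is therefore trimmed per end by 1.7× the maximum of the distance
   transform along that end's terminal stretch (a window of twice the
   global half-width), and the trimmed span is replaced by a straight
   extension along the local tangent out to the sub-pixel mask boundary.
   The factor 1.7 exceeds the $\sqrt2 \approx 1.41$ arc length of a
   corner branch; the trim is capped at 25 % of the path per end so short
   objects degrade gracefully. Keying the trim to the local half-width is
   what makes the straight extension safe: where the trim is long the
   body is correspondingly wide, so the extension cannot drift out
   sideways through a thin taper, and where the body tapers the trim is
   short and the extension spans almost no curvature. (A global-maximum
   trim was measurably worse on short, thick, strongly bent bodies —
   up to 2 % length error versus under 0.3 % with the local rule.)
4. **Widths** (`width_at`, `width_profile`): at normalized arc position
   $s$, a transect perpendicular to the local tangent (central differences
   over a 5-point window) is marched in 0.25 px steps; the mask edge is
   located by linear interpolation of bilinearly sampled mask values at
   the 0.5 level. "Middle width" is the transect at $s = 0.5$, i.e. the
   arc midpoint, not the bounding-box middle. The 31 boundary radii are
   half-widths; where the transect degenerates at the first or last
   boundary the radius falls back to 0, consistent with a body that
   tapers to a point.
5. **Volume** (`frustum_volume`): the sum above.

Coordinates are 1-based (row, col) with sub-pixel values, R's native
matrix convention. Lengths are converted to micrometres by the
calibration factor (pixels/µm) carried by `calibrated_image`, never baked
into intermediate pixel quantities.

## The synthetic generator as ground truth

`generate_worm_image()` renders the same tube model the estimator
assumes, so discrepancies isolate pipeline error rather than model
mismatch. Ground truth is computed purely from the specification —
length from the curve construction, volume as
$L\int_0^1 \pi r(s)^2 \mathrm{d}s$ by $10^5$-point trapezoid quadrature —
never from the rendered image. The rendered mask's pixel count is
carried along only as an oracle for the segmentation test.

Rendering details that matter:

* Pixels are assigned to their nearest curve sample; samples are spaced
  adaptively at $\sqrt{1.6\,d}$ px where $d$ is the distance of the
  smallest rendered feature (body radius, or lumen half-width inside the
  lumen's extent), keeping the boundary placement error below ~0.2 px.
* The tube is cut flat at the curve ends rather than capped with
  hemispheres, so the rendered solid equals the solid of revolution that
  defines the ground-truth volume.
* Tip radii are clamped to ≥ 0.5 px so the mask stays 8-connected and the
  skeleton has endpoints.
* Self-intersecting poses and geometry leaving the image are rejected;
  the generator emulates anesthetized extended specimens only.

Default study conditions: calibration 5 px/µm, adult lengths
800–1200 µm, mid-body radii 25–40 µm, a parabolic taper
$r(s) = 4 r_{\max} s(1-s)$ (constant and user-supplied profiles are
available), sinusoidal bends of 20–60 µm amplitude, foreground/background
intensities 0.75/0.10 with additive Gaussian noise (sd 0.02). Bit depth,
illumination and background texture of the original acquisitions are not
stated anywhere authoritative, so these are free parameters with
documented defaults rather than fixed constants.

What passing recovery tests do **not** show: robustness to uneven
illumination, touching or overlapping animals, internal texture
(pharynx, gonad, eggs), debris, or out-of-focus edges. The generator's
worms are cleaner than real micrographs; on real data the Otsu threshold
and the single-component assumption are the first things to revisit.

## Luminal width

`measure_lumen()` measures the dark intestinal band at two posterior arc
positions (defaults $s = 0.70$ and $0.85$; both must lie in (0.5, 1)).
On each perpendicular transect the local body intensity is estimated as
the 90th percentile of in-mask samples and the lumen intensity as the
central minimum; a band must dip at least 20 % below the body estimate
(`min_contrast`) or the position is reported as having no dark band. The
luminal width is the contiguous sub-threshold run crossing the midline,
with edges interpolated to the mid-intensity threshold. Because the
midline's tip-to-tip orientation is lexicographic rather than anatomical,
`orientation = "auto"` (default) picks the direction that places the
darker band at the requested posterior positions. The classic workflow
for this measurement is manual two-point annotation in ImageJ; `average_lumen_width()`
and the CLI's `--manual-widths` mode replicate exactly that, and the
automated transect mode is this package's own addition.

The generator draws the lumen as a darker band over the posterior 40 %
of arc length (extent configurable), with a stated absolute width; the
dilation-series tests check strict monotonicity and 10 % recovery.

## Defecation rhythm

One DMP cycle is the interval between successive pBoc events. The
statistics follow fixed definitions: `mean_cycle_length` averages the
*first* 10 cycles (animals with fewer are an error, mirroring the
requirement of at least 10 consecutive scored cycles; when more are
available the later ones are deliberately ignored), and aBoc/expulsion
frequencies are event-count ratios over pBoc counts. The expulsion
frequency is defined by analogy with the aBoc ratio (only the latter has
a conventional printed definition). Events are point events; BORIS state rows are collapsed
to their start time with a warning. A pBoc sharing a timestamp with
another event sorts first, so cycle boundaries win ties.

The generator draws inter-pBoc intervals from a normal distribution
truncated at zero — no particular period distribution is established for
this rhythm, and the truncated normal reproduces the wild-type regime
(mean ≈ 50 s, sd ≈ 5 s) while guaranteeing positive intervals; realized intervals
are returned so recovery tests are exact rather than statistical.
Per-cycle aBoc events are placed uniformly in the first half of the
cycle and expulsions in the second half, reflecting their order within
the motor program; only their counts enter any statistic.

## Receptor assay

Each well is read twice (0 s and 5 s); reads are averaged by default
(`mean`), with `first` and `max` policies available since the original
combination rule is unstated. Normalization is strictly per assay: every
collapsed value is divided by that assay's ligand-free control mean, so
the control maps to exactly 1 and a uniform gain change within an assay
cancels exactly. Condition summaries first average wells within an
assay and then treat the assay, not the well, as the replication unit
(triplicate wells nested in ≥ 4 independent experiments). Basal receptor
activity is the per-assay ratio of ligand-free receptor wells over
empty-vector wells, averaged across assays. Hypothesis testing is
deliberately excluded.

The plate generator emits `baseline × fold × lognormal(cv)` per well
(unit-mean noise, CV 0.1 by default) as two identical reads — read
collapsing is exercised by hand-built records in the tests, not by the
generator.

## Numerical choices and degenerate inputs

* Quantiles everywhere use linear interpolation between order statistics
  (R type 7); summary CSVs carry the rule in a header comment.
* Transect sampling step 0.25 px; mask and intensity values are sampled
  bilinearly; edges are located by linear interpolation between samples.
* Path smoothing is a running mean (window 9 px) with shrinking windows
  at the ends, so endpoints stay anchored.
* Ties in the longest-path search break toward the lexicographically
  smallest endpoint pair; midline orientation is lexicographic.
* Degenerate inputs error loudly and specifically: featureless images,
  border-touching masks, ring-shaped skeletons, paths shorter than
  `min_length_px`, fewer than two pBocs, fewer cycles than requested,
  assays without control wells, zero control means.

## Problem sizes in the validation suite

The acceptance-style tests run 20 worms at full study conditions
(5 px/µm, 800–1200 µm — a graded length series whose 21 µm spacing keeps
the rank-order check away from near-ties), a 4-point luminal dilation
series, 1000 synthetic animals for the rhythm grand mean, the triplicate
× 4-assay plate design, and 20 repetitions of a two-cohort end-to-end
comparison (20 animals per group at 2.5 px/µm, 15 % true length
difference). The end-to-end cohorts use smaller, coarser worms than the
recovery battery; the separation check needs relative, not absolute,
accuracy.

## Known limitations

* 2-D only; volume assumes a circular cross-section, as the frustum
  model itself does.
* Coiled, self-touching or clipped worms are rejected, not recovered.
* Automated lumen detection needs the band to be darker than the body by
  the configured contrast at the measured positions; faint lumina fall
  back to the manual two-point workflow.
* The BORIS parser reads the aggregated-events export dialect with
  configurable column names; other exports need reshaping first.
* Head/tail identity is not assigned; "posterior" in the lumen module is
  resolved by intensity, not anatomy.
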