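---
title: "Quantifying microvascular architecture and hemodynamics with ulmvasc"
author: "ulmvasc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvascular architecture and hemodynamics with ulmvasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ultrasound localization microscopy (ULM) breaks the diffraction limit of
vascular ultrasound by localizing individual, sparsely distributed
microbubble contrast agents across thousands of ultrafast frames and
accumulating their sub-wavelength positions and velocities into a
super-resolved map of the vascular bed. The scientific use case this package
addresses is the quantitative comparison of microvascular *architecture*
(density, caliber, branching, tortuosity, fractal complexity, orientation
disorder) and *hemodynamics* (flow velocity, flow volume) between tissue
regions — typically a tumor core, its invasive margin, and normal tissue —
where the invasive margin is expected to carry denser, more tortuous, more
disordered and more branched microvasculature than either other region.

Because real acquisitions of this kind are not publicly deposited, the
package ships a first-class synthetic-data module: vascular phantoms with
exact analytic ground truth, microbubble transit simulation under laminar
(Poiseuille) flow, and a renderer that produces movies with the statistical
structure the processing chain assumes (sparse Gaussian bubble spots over
high-amplitude low-rank tissue clutter plus noise). Every stage of the
pipeline is therefore testable against known truth without any downloads.

## The processing chain

`run_pipeline()` chains seven stages, each available as a standalone
function:

1. **Phantom generation** (`generate_phantom`): vessels grow as
   biased-persistent random walks with a sinusoidal heading perturbation
   (tortuosity) and stochastic side branching, confined to their tissue
   region. Geometry is a list of centerline polylines (micrometers) with a
   radius and a mean axial speed per segment, so all nine regional metrics
   have closed-form truth values (`phantom_truth_metrics`).
2. **Flow simulation** (`simulate_bubble_flow`): bubbles arrive as a Poisson
   process, sample a position uniformly over the circular lumen
   cross-section, and advect along the centerline at the parabolic-profile
   speed for that radial position (centerline = 2x the mean axial speed,
   zero at the wall). The ensemble mean of sampled speeds equals the
   segment's mean speed.
3. **Rendering** (`render_movie`): unit-peak isotropic Gaussian spots
   (default sigma 20 um = 2 px) plus tissue clutter built as a sum of
   `rank` outer products of smooth spatial and slowly varying temporal
   modes — the Casorati matrix of the clutter has exactly that rank, and the
   leading mode is 100x the bubble peak by default — plus white noise.
4. **Clutter filtering** (`svd_filter`): singular value decomposition of the
   (pixels x time) Casorati matrix; the low-order components carry the
   temporally coherent tissue signal and are removed. The automatic
   threshold sits at the inflection of the singular-value curve.
5. **Localization and tracking** (`localize_stack`, `link_tracks`): local
   maxima above a robust threshold are refined to sub-pixel precision with
   the gradient-based radial-symmetry estimator, then linked frame-to-frame
   by optimal (Hungarian) assignment with a distance gate; a missed
   detection terminates a track, and tracks shorter than 15 frames are
   discarded.
6. **Map accumulation and segmentation** (`accumulate_maps`,
   `binarize_density`, `skeletonize_mask`, `extract_graph`,
   `estimate_diameters`): localization counts, mean speeds and circular-mean
   flow directions per super-resolution pixel; a deterministic
   count-threshold binarization with morphological cleanup; Zhang-Suen
   thinning; and a node/segment graph with per-point radii from the
   Euclidean distance transform.
7. **Metrics and statistics** (`region_metrics`, `compare_regions`): the
   nine regional quantities and the normality-gated group comparison and
   correlation machinery.

## The quantitative parameters

For a vessel segment with path length $L_c$ and end-to-end chord $L$:

$$\mathrm{curvature} = L_c / L \ge 1.$$

For a binary vascular mask, box counting with grids of side $r$ anchored at
the origin gives $M(r)$, the number of boxes containing vessel; the fractal
dimension is the least-squares slope of $\log M(r)$ against $\log(1/r)$,
fitted over the contiguous sub-range of at least four scales with the
highest $R^2$, which must exceed 0.99 for the fit to count as clean (the
sub-range rule guards against the break-down of scaling at box sizes
comparable to the image or to single pixels).

For flow directions $\theta_i$ with circular mean $\bar\theta$:

$$\mathrm{orientation\ variance} = \frac{1}{N}\sum_i
\operatorname{wrap}(\theta_i - \bar\theta)^2,$$

with differences wrapped into $(-\pi, \pi]$. Two modes are provided: signed
(flow directions as-is) and axial ($\theta \equiv \theta + \pi$; angles are
doubled before wrapping and deviations halved after).

Per-segment flow volume under the Poiseuille assumption of cylindrical
laminar flow:

$$Q = A \times V, \qquad A = \pi (d/2)^2,$$

with the diameter from the distance transform and $V$ the mean of
velocity-map values along the centerline; $Q$ is reported in nL/s
($1\,\mathrm{nL} = 10^6\,\mu m^3$).

The histology-style indices are area ratios of binary masks: VD-H is the
endothelial-positive fraction of the region, VMI-H the mural-cell-co-positive
fraction of the endothelial-positive area.

## Design choices in detail

**Inflection threshold.** The singular-value threshold is the discrete
curvature argmax: the interior index maximizing the second difference of
$\log_{10}\sigma_i$, minus one. The log domain makes the rule scale
invariant; the "minus one" places the cutoff *before* the knee pixel, so a
spectrum like (100, 99, 1, 0.9, ...) cuts after the two-value plateau. Ties
break toward the smallest index; values at the numerical-noise floor
($<10^{-9}\sigma_1$) are excluded from the knee search because a collapsing
tail in noiseless synthetic data would otherwise fake an inflection.

**Radial-symmetry localization.** Gradients on the half-pixel midpoint grid
(diagonal differences, 3x3 box smoothing) define lines through each midpoint
along the local gradient; the center is the weighted least-squares point
minimizing perpendicular distance to all lines, with weights proportional to
squared gradient magnitude over distance to the intensity centroid. The
normal-equation form avoids the slope singularities of a slope/intercept
parameterization. Noiseless accuracy on the test fixtures is about 0.03 px
RMS.

**Tracking.** Cost is squared Euclidean distance; pairings beyond the gate
(default: twice the fastest configured mean speed — the profile maximum —
times the frame interval, with a 1.5x margin) are forbidden, and leaving a
detection unmatched costs the squared gate. The assignment is solved exactly
(Jonker-Volgenant shortest augmenting paths) on the standard padded matrix;
detections are processed in a canonical order so results are reproducible.
There is deliberately no gap closing: a missed detection terminates the
track, which keeps velocity estimates honest at the cost of fragmentation.

**Orientation variance: signed vs axial.** The function default is the
signed mode. The *pipeline* default is axial, because pooled signed
directions are dominated by the arbitrary polarity of a region's few root
vessels — two anti-parallel straight vessels would score near $\pi^2$
"disorder" while being perfectly ordered architecture. Axial statistics
measure the architectural disorder the regional comparison is after; the
signed map remains available for hemodynamic questions.

**Regional curvature.** Recovered skeletons carry discretization noise: an
8-connected chain overestimates continuous arc length (staircase bias), and
very short fragments have meaningless $L_c/L$. Arc length is therefore
measured on a 5-point moving-average-smoothed polyline, and the regional
mean is length-weighted over segments with chord $\ge 20\,\mu m$
(`min_chord_um`). Both choices are estimator decisions about noisy skeletons,
not changes to the curvature definition, which remains $L_c/L$.

**Segmentation and its quality gate.** The trainable pixel classifier used
in comparable workflows is replaced by a deterministic rule: density
$\ge k$ localizations (default 2), morphological closing, small-component
removal. The quality gate is the Dice overlap with the phantom's true mask
after both masks are reduced identically to the acquisition grid (a coarse
pixel is vessel if any of its fine pixels is). The reduction matters: a
finite number of transits traces lumens without saturating them at
super-resolution, so super-res Dice measures sampling depth rather than
segmentation quality. Well-sampled phantoms pass at Dice >= 0.7; default
end-to-end runs land around 0.65-0.75.

**Flow-profile sampling.** Bubbles sample the lumen cross-section
area-uniformly, so sampled speeds average to the mean axial speed, and
near-wall bubbles are nearly static. SVD filtering removes quasi-static
scatterers by construction — the well-known slow-flow blind spot of ULM —
so fixtures that quantify clutter rejection per se use centerline transits
(`rho = 0`), and track-recovery statistics exclude nothing but the
unlocalizable 3-px image border.

## Study conditions and problem sizes

The default configuration simulates a 128 x 128 px field at 10 um pixels
(1.28 mm), 400 frames at 500 Hz, one expected bubble arrival per frame
(about 20-40 concurrent bubbles), clutter rank 2 at 100x bubble amplitude,
noise 5% of bubble peak, super-resolution factor 4 (2.5 um), and the
three-strip core | invasive | normal phantom. Region parameters encode the
expected biology: the invasive strip has more seeds (8 vs 3), a four-fold
branching rate, four-fold tortuosity amplitude, larger caliber than the core
(16-24 um vs 10-16 um diameter), and intermediate flow speed (core slightly
faster than invasive, normal slowest). Vessel calibers are capillary-to-
venule scale for rodent brain; speeds span 2-7 mm/s. These sizes keep a full
simulate-to-statistics run around 15 s and a ten-phantom recovery study
around 3 min on one core while leaving every regional contrast decisively
expressed in the analytic truth (verified over 25 generator seeds in the
test suite).

What the phantom deliberately does not emulate: nonlinear bubble acoustics,
RF-domain speckle and beamforming artifacts, tissue motion beyond low-rank
drift, out-of-plane bubble transit, and 3D geometry. Passing recovery tests
on these phantoms therefore demonstrates the internal consistency and
statistical calibration of the chain — not robustness to every artifact of
in vivo acquisition.

## Statistics

Group comparisons follow a normality gate: one-sample Kolmogorov-Smirnov
against a normal with estimated mean and SD (the estimated-parameter caveat
of the Lilliefors kind applies; with it the gate is conservative, i.e.
biased toward calling samples normal). If all three groups pass, one-way
ANOVA with Bonferroni-adjusted pairwise Welch t tests; otherwise
Kruskal-Wallis with Bonferroni-adjusted pairwise Mann-Whitney U tests. The
Mann-Whitney p-value is exact — enumeration of the full permutation
distribution with midranks — for combined n up to 12, and a tie-corrected
normal approximation beyond. Correlations auto-select Pearson (both
variables gate as normal) or Spearman, with strength labels at |r| >= 0.700
(strong) and 0.400-0.699 (moderate). All tests are two-sided; null
calibration (rejection rate at the 5% level within [0.03, 0.08] over 2,000
seeded replicates at n = 6 per group) is enforced by the test suite.

## Degenerate inputs and numerical corner cases

Empty ROIs, empty masks and constant localization windows raise errors;
ROIs that contain no vessel yield flagged zero metrics rather than errors,
and an over-strict track-length minimum propagates empty-but-valid outputs
through every downstream stage. Self-loop skeleton segments with coincident
endpoints are excluded from curvature (zero chord). Box-counting scale
ranges need at least four scales; masks smaller than 64 px per side are
rejected. TIFF output stores samples normalized to [0, 1] at 32-bit
precision with the affine restore parameters in a JSON sidecar (round trip
exact to about 1e-9 relative).

## Known limitations

Slow (near-wall) flow is invisible to the SVD filter; crossing or
closer-than-PSF parallel vessels merge at detection; no gap closing means
fragmented tracks under intermittent detection; diameters of vessels thinner
than the super-res pixel are floored at one pixel; and the statistics stage treats
each segment as an independent observation when comparing regions within a
single run, which is a within-phantom convenience, not a claim about animal-
level inference (animal-level inputs should be pre-averaged, one value per
animal, as `GroupSample` requires).
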