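---
title: "Quantifying collagen fibril networks: skeleton morphometry, bending ratio and persistence length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen fibril networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmorph)
```

## The problem

Scanning electron micrographs of extracellular matrix show networks of thin
collagen fibrils (single fibrils are on the order of 20–30 nm across, i.e.
2–3 pixels at a typical 10 nm/px magnification). The degree to which these
fibrils are straight or tangled tracks the mechanical state of the tissue:
enzymatically degraded or osteoarthritic cartilage shows more branched,
more tortuous fibrils than healthy tissue. `fibrilmorph` turns a grayscale
micrograph into a skeleton graph of fibril centerlines and summarizes each
specimen with two structural statistics:

* the **bending ratio**, the mean-squared end-to-end distance of skeleton
  line segments divided by their mean-squared contour length,
  $\mathrm{BR} = \langle R^2\rangle / \langle L^2 \rangle$ — exactly 1 for
  perfectly straight segments and decreasing with curvature and tangling;
* the **persistence length** $L_p$, the arc length over which the tangent
  direction of a fibril decorrelates.

Because micrographs of this kind are rarely published with raw data, the
package ships a synthetic generator with known ground truth, so that every
stage — edge detection, skeletonization, graph decomposition, estimation —
is validated by parameter recovery rather than by eye.

## The worm-like chain model

Fibrils are modeled as planar worm-like chains (WLC). The generator draws a
discrete chain with step length $\delta$: each step turns by a Gaussian angle
with mean zero and variance $\delta / L_p$. This gives the planar
tangent-correlation law

$$\langle \cos\theta(s) \rangle = e^{-s / (2 L_p)}$$

and, by integration, the closed-form mean-squared end-to-end distance

$$\langle R^2(s) \rangle = 4 L_p s - 8 L_p^2\left(1 - e^{-s/(2L_p)}\right).$$

The planar (2-D) form is used throughout — in the generator and in both
estimators — because SEM micrographs are two-dimensional projections and a
self-consistent 2-D treatment lets generated truth and estimate be compared
directly. Note the 2-D decay constant is $2L_p$ where the 3-D chain has
$L_p$; mixing conventions silently halves or doubles every estimate. The
factor-of-2 is fixed here consistently by the generator's turning-angle
variance.

A straight fibril is represented by $L_p = \infty$ (zero turning variance),
and estimators flag all-straight ensembles as non-estimable rather than
reporting a number.

## The extraction chain

1. **Canny edge detection** (`detect_edges`): Gaussian smoothing
   (`gaussian_sigma`, default 1 px), Sobel gradients, non-maximum
   suppression perpendicular to the edge, double-threshold hysteresis with
   8-connected linking. Gradient magnitudes are rounded to 10 significant
   digits so that plateau ties in the suppression step resolve
   deterministically, and a gradient field below $10^{-12}$ (a constant
   image) short-circuits to an empty mask.
2. **Morphological closing** (`close_edges`, disc radius `closing_radius`,
   default 2 px): a Canny detector responds to a bright ridge with *two*
   parallel contours, one per side. Closing with a radius comparable to the
   fibril diameter fuses the pair into one solid band so that thinning
   yields a single centerline per fibril.
3. **Thinning** (`skeletonize_mask`): two-subiteration Guo–Hall thinning,
   which preserves connectivity and holes, leaves endpoints in place, and is
   idempotent on an already-thin skeleton.
4. **Graph decomposition** (`build_skeleton_graph`): an endpoint is a
   skeleton pixel with exactly one 8-neighbor; a junction is a pixel whose
   *crossing number* — the number of distinct foreground runs around its
   8-neighborhood ring — is at least 3. The crossing number equals the
   number of incident chains; a raw neighbor count would misclassify the
   pixels orthogonally adjacent to every crossing (their neighbors are
   mutually adjacent) and systematically shorten chains. Mutually adjacent
   junction pixels are merged into one junction node at their centroid,
   which stabilizes junction counts against the small clusters thinning can
   emit. Chains are traced between node pixels with two corner rules —
   never step to a pixel that also touches the previous pixel, and prefer
   orthogonal over diagonal steps — which prevent corner-cutting near
   junctions. Isolated closed loops receive a single cycle-anchor node.
5. **Segment emission** (`extract_segments`): endpoint-to-junction chains
   shorter than `prune_spurs_shorter_than` (default 5 px) are removed as
   thinning artifacts; surviving chains shorter than `min_segment_length`
   (default 10 px) are excluded. Pruned chains are *not* re-merged across
   their junction: a crossing cuts fibrils into separate segments, exactly
   as junctions do in the tissue images this emulates.

An alternative first stage (`threshold_fibrils`, extraction mode `"otsu"`)
skeletonizes a global Otsu threshold mask directly; it is provided for
sensitivity analysis on bright-ridge images.

### Hysteresis threshold defaults

`detect_edges` accepts absolute thresholds in $[0,1]$. When unset, they
default to the 0.70 and 0.90 quantiles of the gradient magnitude — but taken
over magnitudes above a robust noise floor (twice the median positive
magnitude), not over all pixels. Fibril fields are sparse: in a 512 px field
holding a few thin fibrils, far less than 1 % of pixels carry edge signal,
so raw whole-image quantiles would sit inside the noise distribution and
keep speckle. The floored quantiles adapt to image contrast while staying
above the noise.

## Estimating the persistence length

Two estimators are provided (`estimate_persistence_length`), and which one
the pipeline uses is a configuration choice:

* **`end_to_end_fit`**: every internal sub-chain of every segment, up to arc
  separation `max_arc_fraction` (default 0.5) of its contour length,
  contributes an $(s, R^2)$ pair; binned means (bin width 2 px) are fitted
  to the closed-form $\langle R^2(s)\rangle$ law by weighted
  Levenberg–Marquardt. The cap at half the contour length avoids the long
  separations that junction censoring makes scarce and noisy.
* **`tangent_correlation`**: tangent directions are estimated by chords
  spanning a `tangent_window` arc (default 5 px) — raw per-step directions
  on a pixel lattice can only take multiples of 45°, and the chord window
  suppresses that quantization. Binned means of $\cos\theta(s)$ are fitted
  on the log scale by weighted regression through the origin; separations
  below one window length are excluded because overlapping chords are
  trivially correlated.

Two numerical corrections keep the estimators honest:

* **Chord-overlap correction.** For chord-averaged directions the angular
  variance between two chords at midpoint separation $s$ is
  $(s - w/3)/L_p$, not $s/L_p$; fitting against the raw separation reads
  systematically high, worst in the (heavily weighted) small-$s$ bins. The
  tangent estimator therefore fits against the effective separation
  $s - w/3$.
* **Digitized arc length.** King-move pixel chains overestimate the length
  of the underlying smooth curve (up to ~8 % depending on direction); fed
  into the $R^2$ law this surplus is read as bending and biases $L_p$ low
  by tens of percent. Inside both estimators, arc positions along lattice
  chains use the classical corrected step weights for digitized curves
  (0.948 per orthogonal step, 1.343 per diagonal step; Kulpa, Dorst &
  Smeulders). The `contour_length` stored on a [segment] remains the
  literal king-move sum. Pre-smoothing the traced chains was evaluated
  instead of the weight correction and rejected: windows wide enough to
  remove the lattice signal also remove genuine curvature and over-correct
  in the opposite direction.

With both corrections the two estimators agree on continuous ground-truth
chains and on traced pixel chains alike. `estimate_persistence_length`
defaults to the end-to-end fit, the literal $R^2$ law;
`pipeline_config()` defaults to `tangent_correlation`, which is the less
sensitive of the two to residual lattice structure in traced chains.

The bending ratio is reported as the ratio of means
$\langle R^2\rangle / \langle L^2\rangle$ (its literal definition); a
mean-of-per-segment-ratios variant is available behind
`bending_method = "mean_of_ratios"` for sensitivity analysis. No correction
is applied for junction censoring (dense junctions shorten segments and
thereby raise the bending ratio toward 1 while cutting the range of usable
arc separations); the median segment length is reported alongside as a
diagnostic.

## The synthetic generator as study condition

`synthetic_image_spec()` defaults describe the validation field used
throughout the tests:

| parameter | default | rationale |
|---|---|---|
| canvas | 512 × 512 px | typical micrograph crop at 10 nm/px |
| `n_fibrils` | 3 | see below |
| `fibril_length` | 100 px | 1 µm at 10 nm/px, order of the visible free length between crossings |
| `persistence_length` | 50 px | mid-range flexibility; conditions override it |
| `fibril_diameter` | 2.5 px | 25 nm at 10 nm/px, inside the observed 20–30 nm |
| `blur_sigma` | 1 px | mild instrument blur |
| `noise_sd` | 0.05 | visible but not dominant additive noise |
| `background_level` | 0.15 | dark background, bright fibrils (secondary-electron convention; invert upstream if needed) |
| `branch_probability` | 0 | branching is a condition, not a baseline |
| `branch_length` | 40 px | branches shorter than their parent fibril |

`n_fibrils` and `fibril_length` are set so that fibril–fibril crossings are
rare: for randomly placed needles of length $L$ in area $A$, the expected
crossings per pair are $\approx 2L^2/(\pi A)$, which at $L = 100$ px on a
512 px canvas gives ≈ 0.024 per pair, i.e. ≈ 0.07 crossings per 3-fibril
image (about 2 % of the fibril count; curvature raises the realized rate
somewhat above the needle estimate). Each crossing converts two segments
into four, so validation by *per-fibril* segment counting requires this
sparse regime. Denser, more tangled fields — the
degraded-condition emulation — are produced deliberately by raising
`n_fibrils` and `branch_probability`, not by the baseline.

What the generator does **not** emulate: 3-D network projection, fibril
bundling and twisting into thick cables, diameter variation along a fibril,
charging and shading artifacts of real SEM, or anisotropic (oriented)
networks. Passing the recovery tests therefore shows the pipeline is
self-consistent on planar, isotropic, well-separated fibrils of known
statistics — not that it is unbiased on any particular real micrograph.

Starting points are uniform over the canvas, initial directions uniform over
$[0, 2\pi)$, and branch take-off angles are drawn from the same
turning-angle distribution as the chain itself, so branches leave their
parent at shallow angles. Paths leaving the canvas are clipped at
rasterization, not an error.

## Reproducibility and numerics

* One global seed drives the whole pipeline; each stage derives its own seed
  by hashing a stage label into the global seed (`derive_seed`), so adding a
  condition or stage never perturbs the random stream of another.
* Two runs with the same configuration and seed write byte-identical CSV and
  JSON artifacts; every output directory contains the fully resolved
  configuration, the seed, and a manifest with an MD5 hash per file.
* CSV floating point is written with 9 significant digits; 16-bit TIFF
  round-trips intensities to within 1/65535.
* Degenerate inputs are contracts, not crashes: empty images yield empty
  graphs; all-straight ensembles yield a non-estimable flag ($L_p = \infty$)
  rather than a fitted number; a zero within-group variance with unequal
  means is flagged as a degenerate (infinite-F) ANOVA.
* Fits: the $R^2$ law is fitted with `minpack.lm` bounded
  Levenberg–Marquardt (start value $s_{max}/4$, bounds $[10^{-3}, 10^9]$ px,
  weights = bin counts); the log-linear tangent fit uses weighted least
  squares through the origin, and a non-negative fitted slope is reported
  as non-estimable.

## Group comparison

Per-image summaries (the image is the statistical unit) are compared across
conditions with a Mann–Whitney test for two groups — exact by enumeration
for combined $n \le 12$ without ties, normal approximation with continuity
and tie corrections otherwise — or one-way ANOVA with Bonferroni-adjusted
post hoc pairwise tests for three or more. The post hoc pairwise test is a
Welch two-sample $t$ test by default (the usual reading of
"ANOVA with Bonferroni post hoc"), with pairwise Mann–Whitney available by
configuration. Percent change between conditions is reported relative to the
reference condition: positive values are reductions.

## Problem sizes used in the validation suite

The test suite validates the Monte-Carlo laws with $10^4$ chains, estimator
recovery with 500 segments of 200 px at $L_p = 50$ px, pipeline recovery
with 30 clean 512 × 512 images, and the two-condition contrast
("healthy-like" $L_p = 100$ px, branch probability 0.005 versus
"degraded-like" $L_p = 30$ px, branch probability 0.05) with 30 images per
condition. These sizes make the Monte-Carlo standard errors small compared
with the tolerances being asserted while keeping a full run comfortably on
one CPU.

## Known limitations

* Measured segments are a *selected* subset of the underlying chains: a
  floppy fibril that bends back within roughly the closing diameter of
  itself is fused into a loop or junction by the closing step and is cut
  into short pieces, so the long, measurable segments are systematically
  straighter than the generating ensemble. This tube self-contact
  censoring grows with contour length relative to $L_p$; it is the reason
  pipeline recovery is validated against the statistic computed on the
  same dataset's ground-truth polylines rather than against the nominal
  generator parameter alone.
* Segments are inter-node chains: fibrils are *not* re-connected across
  junctions, so in dense networks the measured statistics describe the
  network's free segments, not whole fibrils. This matches the intended
  use — the statistics are deterioration markers, and junction density is
  part of the signal — but it means absolute $L_p$ values from dense and
  sparse networks are not directly comparable.
* The end-to-end $L_p$ estimator is reliable on continuous chains and
  biased low on lattice chains (see above); the package deliberately keeps
  both rather than hiding one, and records which was used in every result.
* The bending ratio computed on traced chains inherits a small downward
  bias from lattice arc-length inflation in its denominator. Group
  *contrasts* are unaffected because the bias is common to all conditions.
* Persistence lengths approaching or exceeding the typical segment length
  are estimated with large variance; the per-image estimates feeding group
  comparisons are noisy at high $L_p$, which the nonparametric tests
  tolerate but an absolute calibration would not.
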