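---
title: "Saliency-based keyframe extraction for diagnostic hysteroscopy video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-based keyframe extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diagnostic hysteroscopy (DH) produces continuous, unedited video of the
uterine cavity at roughly 30 frames/s for several minutes. Unlike edited
footage there are no shot boundaries to anchor a summary on, frames are
highly self-similar in color and texture, and many are useless for
diagnosis — saturated by specular glare, smeared by motion blur, or
showing nothing but a fast pan between regions of interest. The clinical
browsing pattern supplies the signal: a gynecologist pans quickly over
unimportant tissue and dwells slowly on suspicious regions, so
diagnostically important frames sit in low-motion segments with clear,
richly textured views of lesioned tissue.

`keysal` turns that observation into a pipeline: four per-pixel saliency
operators, frame-level score aggregation, weighted linear fusion into an
attention curve, and two keyframe selection rules, plus evaluation against
reference annotations and a synthetic video generator with planted ground
truth.

## The saliency operators

All operators use reflective (symmetric, edge-including) border padding,
so a flat image stays flat at its edges and no spurious border saliency is
created. All return non-negative finite per-pixel maps.

**Motion (MS).** The current frame is partitioned into blocks (default
16×16) and each block's displacement relative to the previous frame is
found by exhaustive search over integer shifts within ±`search_radius`
(default 8 px), minimizing the sum of absolute luminance differences.
Exhaustive block matching was chosen over off-the-shelf optical flow
because it is fully deterministic, has a three-line mathematical
definition, and can be verified exactly against a brute-force oracle; the
estimator behind the motion model is not otherwise pinned down. Ties in
the SAD objective are broken by smallest displacement magnitude, then
smallest vertical, then horizontal component, so static content yields an
exactly zero field; mathematically tied objectives are recognized with a
1e-9 absolute slack so that floating-point summation order cannot override
the tie-break. The saliency map is the per-pixel displacement magnitude
`sqrt(dx² + dy²)`. The first frame of a sequence has no predecessor and is
assigned a zero field.

**Texture (TS).** Local gray-level entropy over an odd window (default
15×15), with the luminance histogram binned into `gray_levels` = 256
equal-width bins and entropy normalized by `log2(gray_levels)` to `[0, 1]`.
The segmentation threshold τ = 0.8 then operates on a scale-free quantity.
Two parameter constraints interact here and drove the window default: the
largest achievable normalized entropy is `log2(window²) / log2(gray_levels)`,
so at 256 gray levels an 11×11 window caps at 0.86 — leaving real textured
tissue hovering around the 0.8 threshold and producing speckly,
noise-driven masks — while a 15×15 window caps at 0.977 and gives the
threshold genuine headroom. The thresholded mask is cleaned by
morphological closing with a disk (radius 5; the structuring element is
not otherwise constrained, and a disk matches the isotropy of the
operator) and by binary hole filling, both via EBImage. The per-pixel
texture saliency is the luminance inside the mask; the frame-level score
is the masked ("injurious") area fraction, following the reading that a
frame is texture-salient in proportion to how much of it is injurious
tissue. The alternative frame score — mean of the non-zero texture map —
is also computable via `frame_score()` on the returned map; the area
fraction is the default because it is what the segmentation step actually
measures.

**Multi-scale contrast (MSCM).** At each level of a Gaussian pyramid
(default 3 levels; binomial 5-tap smoothing, factor-2 downsampling), the
per-pixel color contrast is the sum over the three RGB channels (scaled to
`[0, 1]`) of squared differences against every neighbor in a 5×5 window.
The channel combination is a plain sum, consistent with the channel
subscript disappearing when levels are aggregated. Cross-scale summation
requires a resolution alignment choice: each level's map is upsampled back
to base resolution by bilinear interpolation (pixel-center convention)
before summing. The contrast is computed by direct summation of squared
differences rather than the algebraically equivalent expanded form
`n·v² − 2·v·S₁ + S₂`, because the direct form is exactly zero on constant
regions while the expanded form leaves rounding residue.

**Curvature (CM).** The luminance image is smoothed with an isotropic
Gaussian of scale σ (default 1.5 px, kernel truncated at 3σ) and the map
is `sqrt(g_xy² + g_xx² + g_yx² + g_yy²)` from central finite differences.
The mixed derivatives coincide analytically; they are nevertheless
computed independently (x-then-y and y-then-x), preserving the four-term
structure. Built from second derivatives in all axis combinations the
operator is approximately rotation invariant — the property that motivates
it for endoscopic footage captured at arbitrary orientations — and the
test suite checks 90° commutation to within 5% on smooth blobs.

## Scores, fusion, and extraction

Per-pixel maps are collapsed to frame scores as the mean of strictly
positive map values (zero for an identically zero map); zeros are excluded
because the maps are sparse by design and including them would score frame
area rather than salient content. TS uses the injurious area fraction, as
above. Each model's per-frame score vector is normalized by its maximum —
not min–max — so that zero keeps meaning "no saliency" and ratios between
frames survive; an all-zero vector (e.g. a static video) normalizes to
all zeros rather than erroring. The scoring-then-normalization order
(collapse maps to frame scalars first, then normalize the scalar vector
across frames) is one of two readings of the published description; it is
the one under which "normalized in the range 0–1" refers to the per-frame
scores that are subsequently fused.

Fusion is a weighted linear combination with weights normalized to sum 1,
making every attention value a convex combination of per-model scores
(hence in `[0, 1]`, monotone in each input, and inside the per-frame
min/max envelope — all property-tested). No published weighting is
available, so the default is equal weights, and any model can be ablated
by setting its weight to 0 — which is also how per-model and subset
ablation tables are produced.

Two extraction rules operate on the attention curve:

* **Threshold mode** — the threshold is the arithmetic mean of the curve;
  keyframes are frames strictly above it. On curves with broad plateaus
  this rule extracts many frames (it bounds segments, not single
  representatives); it is the evaluation-protocol rule.
* **NKF mode** — the video is split into `NKF` contiguous shots of
  near-equal length (the first `n mod NKF` shots one frame longer — a
  deterministic arithmetic partition, since no partition rule is otherwise
  specified); each shot contributes its attention maximum, ties to the
  earliest frame.

## Evaluation

Extracted keyframes are matched one-to-one to ground-truth indices within
±`tolerance` frames, processing ground truth in increasing order and
taking the earliest unmatched extracted frame in the window. For sorted
index sets and interval windows this greedy scheme attains the maximum
possible matching (verified exhaustively against brute force in the
tests); a nearest-first variant would not, and since only the match
*counts* enter the metrics, the choice of partner within the window never
changes a reported number. Accuracy is `100·tp/|truth|` — identical to
recall up to the percent scale, which is asserted once in the tests —
and F is the harmonic mean of precision and recall. With tolerance 0 the
matching reduces to set intersection. An empty ground truth yields
accuracy 0 by convention rather than an error.

## The synthetic generator

`synth_generate()` emulates the statistical structure the pipeline keys
on, not photoreal tissue:

* a pinkish low-contrast canvas textured with band-limited (smoothed)
  noise — raw white noise would maximize entropy everywhere and erase the
  lesion/background contrast the texture operator needs;
* a camera path alternating fast pans (default 6 px/frame) with slow
  dwells (1 px/frame) centered on circular "lesion" patches of
  brightness speckle. The speckle is shared across RGB channels so the
  luminance histogram inside a lesion is near-uniform (high entropy);
  independent per-channel noise would mix into a bell-shaped, lower-
  entropy luminance distribution;
* a steep-rimmed circular field stop (dark vignette) safely inside the
  frame. Steepness matters: windows straddling a *sharp* light/dark edge
  see a near-bimodal histogram (low entropy), whereas a wide smooth
  falloff is itself a high-entropy gradient ring. The default lesion
  roughly fills the field stop — as when the hysteroscope dwells close to
  the uterine wall — so any off-center view strictly loses visible lesion
  area to the dark surround and the dwell center is the texture-score
  maximum;
* motion blur on non-dwell frames (Gaussian, scale tied to pan speed):
  real 30 fps pans are motion-blurred, and this is exactly why pan frames
  adjacent to a dwell are not near-duplicates of the keyframe;
* glare contamination on a fraction (default 30%) of non-dwell frames:
  clipped-sensor white blobs composited with steep rims, then whole-frame
  defocus blur — over-exposed endoscopic frames bloom and wash out.

Ground truth is the middle frame of each dwell, matching the premise that
keyframes lie where inter-frame motion is least. Contamination is applied
only to non-dwell frames so the planted truth stays unambiguous for
recovery tests. Generation is bit-reproducible from the `synthetic_spec()`
parameters and seed.

What passing recovery tests on this generator shows: the operators measure
what they claim (entropy contrast, motion contrast, glare response) and
the fused pipeline turns those measurements into the planted keyframes.
What it does not show: performance on clinical DH video, whose texture
statistics, illumination, fluid turbidity, and lesion appearance are far
richer than speckle discs on a pink canvas. Published accuracies on
clinical material cannot be reproduced here because no clinical videos are
deposited; the package's claims are correspondingly structural, not
clinical.

## Choosing the fusion for dwell recovery

Motion saliency is displacement *magnitude*: it is largest on fast pans —
precisely the frames the clinical browsing pattern marks as unimportant.
In a linear fusion with positive weight it therefore pushes selection
toward pans and away from dwells. For keyframe selection the package's
recommended configuration ablates it (`weights = c(TS = 1, MSCM = 1,
CM = 1)`), which is what the end-to-end tests and the acceptance script
use; the motion score vector remains available (and is computed, reported
in the curve CSV, and usable in ablation tables) for analyses where the
motion profile itself is of interest, such as verifying that dwell
segments are low-motion.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline on 90-frame
64×64 videos (ten seeds), a size at which each of the four operators is
exercised at full fidelity while a complete run stays interactive; the
operators themselves are resolution-independent, and oracle equivalence is
checked exhaustively on ≤15×15 images where brute force is exact.
Numerical conventions, collected: reflective padding everywhere; entropy
uses `0·log 0 = 0` and exact integer-count histograms
(`H = log2 n − (1/n) Σ c log2 c`); SAD ties recognized at 1e-9 absolute;
attention values clamped to `[0, 1]` against rounding at the boundary;
0-based frame indices in every user-facing artifact (annotation files,
keyframe sets, curve CSV, output filenames), a single convention chosen
because the annotation format is language-neutral.

## Known limitations

* No video-container ingestion: frame directories (PNG/TIFF) only; split
  containers with an external tool first.
* Block matching recovers displacements only up to `search_radius`; pans
  faster than the radius alias. The generator's default pan speed (6
  px/frame) sits inside the default radius (8) deliberately.
* The mean-threshold rule marks whole above-average segments, not single
  representatives; expect many extracted frames on plateaued curves and
  use NKF mode when a fixed-size summary is wanted.
* Operator defaults (τ, window sizes, σ, pyramid depth) are tuned to
  8-bit endoscopy-like imagery at tens-of-pixels lesion scales; other
  imagery may need different settings via `operator_params()`.
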