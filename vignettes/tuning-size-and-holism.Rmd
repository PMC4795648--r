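---
title: "Neural tuning size and holistic face processing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural tuning size and holistic face processing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holoface)
```

## The scientific question

Faces are said to be processed *holistically*: as integrated wholes rather
than as independent parts.  Three classic behavioral markers operationalize
this claim — the composite face effect (CFE), the face inversion effect
(FIE) and the whole-part effect (WPE).  `holoface` implements a
computational account in which a single model property, the **spatial
tuning size** of face-selective model neurons, produces all three markers
when large and abolishes (or strongly reduces) them when small.

The model is a four-layer feedforward hierarchy of the HMAX family:

* **S1** — oriented Gabor filtering of a 10-scale image pyramid
  (downscale factor $2^{1/4}$ per scale), 4 orientations.  Each response
  is the absolute normalized dot product between a zero-mean, unit-norm
  11×11 Gabor (wavelength 5.6 px, envelope σ 4.5 px, aspect ratio 0.3)
  and the local patch, giving values in [0, 1].
* **C1** — local max pooling over 8×8 S1 units from 2 adjacent scales
  (128 values per C1 unit), stride 3; 10 S1 scales yield 9 C1 bands.
* **S2** — Gaussian radial-basis matching of stored templates against
  every C1 position and band: $r = \exp(-d^2 / 2\sigma^2)$ with
  $\sigma = 1/3$, where $d$ is the Euclidean distance between the
  template and the C1 patch.
* **C2** — a global max over each template's S2 pyramid: one
  position- and scale-tolerant response in (0, 1] per template.

Templates are *learnt* by storing C1 patches at random positions inside
the face's C1 footprint at band 7 (of 9): 20 patches from each of 50
training faces, i.e. 1000 templates per tuning size.  The tuning sizes
are **large** 12×12×4, **medium** 8×8×4 and **small** 4×4×4 C1 units,
with medium and small cut as the central sub-blocks of the same large
patch, so the three sizes are position-matched.  At band 7 the whole
face spans roughly 17×22 C1 units, so even a large template covers well
under half a face, and a small one roughly a single part.

## Distance convention in the S2 layer

The radial-basis similarity uses the *raw* Euclidean distance between
the template and the C1 patch (`s2_normalize = FALSE`).  We also provide
a per-entry-normalized variant (distance divided by the square root of
the template entry count), which makes σ formally comparable across
tuning sizes; with it, however, distances on these stimuli are of order
0.01–0.05 and every C2 response saturates above 0.996, leaving the model
without discriminative range and the neural response band (see below)
empty.  The raw distance puts mean large-template responses to upright
faces around 0.6–0.8 — the working range the neural-level analyses
presuppose — and is the convention of the reference implementations of
this architecture.  Mean response levels then necessarily differ across
tuning sizes (a 4×4 patch accumulates one ninth of the squared distance
of a 12×12 patch at similar per-entry error); the analyses that compare
sizes at the neural level control for this explicitly.

## Synthetic face stimuli

The face photographs behind the original behavioral simulations are not
redistributable, so the package generates synthetic identities that
emulate their format and statistics: a 256×256 black field containing an
oval-cropped face of 80×120 px, pixel-normalized so that every identity
has the same in-oval mean (0.5) and standard deviation (0.08), with the
background exactly black.

Each identity is drawn deterministically from `(identity_id, seed)`:

* six parts (two eyes, two brows, nose shading, mouth) as anti-aliased
  ellipses and soft bars on a radially shaded skin base (darker toward
  the oval boundary, like an illuminated convex surface);
* independent truncated-Gaussian jitter of every part's position
  (SD 2.5 px), size (18%), orientation (6°) and intensity (0.06);
* an identity-specific smooth texture field (a 16×16 Gaussian grid,
  amplitude 0.035, bilinearly upsampled), standing in for the
  idiosyncratic shape and shading variation that makes every region of a
  real face informative about identity.

Two calibration facts drove these defaults.  First, C1 pooling makes the
model tolerant to ±4 S1 units of displacement at the template band
(≈ 11 px at full resolution), so identity differences must exceed that
scale to be visible to the templates at all; jitter much below ~2 px
produces identities the model cannot tell apart.  Second, the overall
contrast and texture level sets where C2 responses sit on the
radial-basis curve; the defaults put the large-template response
distribution across the 0.75–0.80 band used by the neural-level
inversion analysis.  What the generator does *not* emulate: photographic
skin microtexture, 3-D pose and lighting changes, hair or external
features, and any correlation structure between parts (parts jitter
independently).  Passing the package's directional tests on these
stimuli therefore shows that the mechanism produces the effects on
part-structured, identity-discriminable faces — not that effect *sizes*
on real photographs are reproduced.

A loader hook (`load_stimulus_dir()`) accepts a directory of real
256×256 grayscale face images with an identity manifest wherever the
generator's output is used.

## The three paradigms

**Composite face effect** (`run_cfe`).  Same-trials pair two composites
with identical top halves and different bottom halves (2-px background
gap at the face midline), aligned or with the bottom shifted by half the
face width.  Attending the top is simulated by multiplying bottom-half
pixels by 0.1 and recentring on the top half.  Two composites are judged
"same" when their C2 distance falls below a threshold calibrated, per
tuning size, to bring the aligned hit-rate as close to 75% as possible
(candidate thresholds are midpoints of consecutive sorted aligned
distances plus both extremes; ties resolve to the lower threshold; the
threshold is recalibrated inside every bootstrap resample).  The effect
is the misaligned-minus-aligned hit-rate.

**Face inversion effect** (`run_fie_behavioral`, `run_fie_neural`).
Behavioral: mean C2 distance over all face pairs, upright versus
inverted; bootstrap runs use random neuron subsets (100 of 1000 for
large, 150 for medium, all for small) to compensate for the larger
spatial coverage of big templates.  Neural: only neurons whose mean
upright response falls in a fixed band are analyzed, then counts are
equalized across sizes — controlling for the size-dependent response
levels noted above.  The band defaults to 0.75–0.80; with `band = NULL`
the narrowest band (width 0.05, widening only if needed) that holds at
least `n_min` neurons of every size is chosen automatically.  On the
default synthetic faces the automatic band typically lands at ≈
0.78–0.86.

**Whole-part effect** (`run_wpe`).  Trials are ordered triples of
distinct identities (eye donor, foil eye donor, rest-of-face).  The
study face is the whole blend of correct eyes and rest.  Whole-condition
choices are whole blends weighted toward the eye region (non-eye × 0.5)
and recentred on it; part-condition choices crop the eye region out of
the whole-condition stimuli.  The model picks the choice with the
smaller C2 distance to the study face; distance ties are scored as half
correct (the expected value of a coin flip, kept deterministic so that
the choice rule stays exactly scale-invariant).

## Attention weighting under a contrast-normalized front end

Because S1 responses are normalized by the local patch norm, a purely
multiplicative attenuation of a region is almost invisible to the model:
the weighted region produces the same normalized responses, and only the
new contrast step along the weighting boundary changes anything.  Two
consequences are documented here deliberately.  First, the attentional
manipulations inherited from the behavioral procedures act mainly
through the recentring step and the weighting boundary, not through
response attenuation.  Second, the weighting boundary injects a
stimulus-independent contrast edge that the oriented filters respond
to; the `feather` argument of `apply_attention()` optionally applies
the weighting with a graded transition (a few pixels wide), as a
spatial attention field would.  An optional S1 contrast-saturation
constant (`s1_saturation` in `hmax_config()`) makes low-amplitude
regions genuinely weaker in the model; it is off by default because it
does not change the package's conclusions and departs from the pure
normalized-dot-product response.

## Inference

The paired neuron bootstrap resamples the C2 population uniformly with
replacement (or draws the per-size subset without replacement where
subsampling is specified), evaluates both conditions of a paired
statistic on the same neurons, and reports the proportion of resamples
in which the test statistic is false under the alternative — i.e. true
under the null — as the p-value, with the SD of resample statistics as
the SEM.  All tests are directional, matching the directional hypotheses
(misaligned > aligned, upright > inverted, whole > part, larger tuning >
smaller tuning).  The Wilcoxon signed-rank test drops zeros, uses
mid-ranks for ties, enumerates all sign assignments exactly up to n = 15
and uses the tie-corrected normal approximation with continuity
correction beyond.  SEMs are reported over bootstrap resamples for
bootstrap analyses and over items (faces) for the neural inversion
analysis; both conventions are labelled in the result objects.

## Numerical choices and degenerate inputs

* Pyramid sizes: floor rounding; bilinear interpolation; every scale is
  resized from the original image, not cascaded.
* Convolution: valid region only — no padding; every response comes from
  real pixels.  Patches with near-zero norm respond 0.
* C1's two-scale pooling defines the grid on the finer scale and pools
  the coarser scale's 8×8 window at the proportionally mapped position
  (nearest index).
* Max pooling needs no tie-break (values only); where positions are
  reported for diagnostics, first-in-scan-order wins.
* S2 bands smaller than the template are skipped, never padded.
* The renderer refuses faces whose in-oval contrast cannot be
  standardized (SD below 1e-3) or whose normalized intensities leave
  [0, 1]; overlapping parts saturate rather than stack.
* The face footprint threshold is 10% of the band maximum (relative, so
  invariant to global contrast).
* Distance ties in the 2AFC rule score half correct, deterministically.

## Problem sizes

The package's own analyses (tests and the acceptance script) run at the
study's design sizes where those are printed — 1000 templates per tuning
size from 50 training faces, 20 identities for the composite and
whole-part pools, 50 identities (1225 pairs) for inversion — and at
reduced trial caps and resample counts for the repeated directional
checks (a few hundred bootstrap resamples, a few dozen trials per
condition), which the result objects record in their metadata.

## Known limitations

* Effect sizes and p-values on synthetic faces are not comparable to
  values measured on face photographs; only directions and orderings
  are.
* The small-tuning composite effect on synthetic faces tends to be
  *negative* (misaligned composites are slightly easier to tell apart
  than aligned ones, driven by the exposed cut edge of the shifted
  bottom half), rather than exactly zero; the holism marker — a positive
  composite effect — still appears only with large tuning.
* The whole-part simulation is at the edge of what these synthetic
  faces support: the two test choices differ only in the eye region,
  and on synthetic eyes that difference produces a C2 distance gap of
  the same order as the response perturbation caused by the attention
  transform itself, so whole-condition accuracies sit near chance and
  the large-versus-small ordering of the whole-part effect is not
  reliably reproduced.  Photographic eyes carry far more
  template-visible identity information; with the loader hook and real
  face images the paradigm runs unchanged.
* The fixed 0.75–0.80 neural band can be empty for the small tuning size
  on synthetic faces (small-template responses have a floor around 0.87
  here); the automatic band preserves the *logic* of the control —
  equalized response levels — at a level appropriate to the stimulus
  set.
* S1's contrast invariance makes multiplicative attention weighting
  mostly inert, as discussed above.
* In the raw-distance response regime, C2 position and scale tolerance
  is graceful rather than absolute: a one-C1-stride shift of a face
  changes individual responses by ≈ 0.2–0.3 (median) while preserving
  the response structure (Pearson correlation ≈ 0.8 with the unshifted
  responses), and a one-pyramid-step rescale changes them more.  On the
  per-entry-normalized distance convention responses saturate near 1
  and the same shifts move them by < 0.05 — but at the cost of the
  discriminative range (see the distance-convention section).
```
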