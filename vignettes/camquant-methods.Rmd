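---
title: "Quantifying CAM vasculature: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CAM vasculature: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camquant)
```

## The problem

The chorioallantoic membrane (CAM) of the ex ovo chick embryo carries a
dense, planar vascular network that is the standard in vivo readout for
angiogenic and anti-angiogenic effects. There is no accepted gold
standard for quantifying it: manual branch-point counting, per-pixel
color classifiers, skeleton analyzers and learned segmentation models
all produce different numbers from the same photograph, and the
disagreement typically grows with the density of the network. This
package implements the full measurement stack — synthesis with known
truth, segmentation, morphometry, a manual-protocol emulation, a
positive pixel count — together with the agreement statistics
(Bland–Altman limits of agreement, paired t-tests) needed to compare
any two methods on equal footing.

Because no public CAM image corpus with per-pixel truth exists, all
validation in this package is against its own synthetic generator,
where every morphometric quantity is known exactly by construction.

## The synthetic generator

`generate_network()` grows recursive bifurcating trees: each segment is
a polyline with a small random-walk curvature; at a bifurcation the two
daughters leave at `±branch_angle` around the parent heading; radii and
segment lengths shrink by fixed per-level factors. Trees are clipped at
the image border, a daughter that would collide with a non-adjacent
vessel is truncated at one pixel of clearance (the real membrane is
planar — in-plane vessels do not cross), and a branch shorter than its
own diameter is not emitted at all, since it would be entirely
swallowed by its parent's junction cap. After these operations the
ground truth (branch nodes of degree ≥ 3, summed chord length,
length-weighted mean radius) is recomputed from the final geometry, so
truth always describes exactly what is rendered.

Default study conditions, chosen once as representative of a 10×
magnification CAM field and used by the tests and the acceptance
script: 320 × 320 px images, one root, 3 bifurcation levels (2–4 in the
recovery suite), root radius 4 px (4–6 px in the recovery suite, so
that all radii lie in roughly 2–6 px), radius taper 0.8–0.85 per level,
branch angle 32° ± 8°, root segment length 60 ± 9 px with a 0.85
per-level length taper, curvature jitter 0.03 rad per ~4 px step.
Rendered radii are clamped at 1 px.

**The mask contract.** A pixel belongs to the truth mask iff its center
lies within the local vessel radius of the centerline (per polyline
edge: clamped-projection distance ≤ linearly interpolated radius).
Vessel ends are therefore capped with half-disks. The same rule,
written as an independent per-pixel loop, is the rasterization oracle
in the tests.

**Rendering.** Dark red vessels (half-pixel anti-aliased edge, kept
narrow so the colored fringe beyond the mask contract stays small) over
a warm bright background with low-amplitude smoothed noise. Two
artifact classes can be injected, emulating what real CAM photographs
show: specular light reflections (bright ellipses) and out-of-focus
deeper vessels (blurred low-contrast reddish curves, deliberately
rendered inside the positive color range of the pixel classifier).
Artifacts alter the image only; the truth mask is by definition
untouched and `artifact_mask` records exactly the altered pixels.

**What the generator does not emulate:** loop-forming
(intussusceptive) topologies, vessel-wall texture, depth-dependent
focus gradients, uneven illumination, lens distortion. Passing the
recovery suite therefore shows that the measurement stack is correct on
clean planar trees — not that it is robust to every property of real
photographs.

## Morphometry conventions

All metrics operate on a skeleton graph built by `skeletonize_mask()`:

* **Thinning** is Zhang–Suen followed by a redundant-pixel cleanup that
  sequentially deletes any pixel with ≥ 2 skeleton neighbors whose
  neighbors remain a single 8-connected set without it (parallel
  thinning leaves staircase doublets on oblique strokes; each such
  extra pixel would otherwise read as a false junction).
* **Dihedral canonicalization.** Parallel thinning has a directional
  sweep bias, so the skeleton of a rotated mask is not the rotation of
  the skeleton. The mask is therefore thinned in a canonical
  orientation (the lexicographically smallest of its 8 rigid
  transforms) and the skeleton mapped back, which makes every scalar
  metric exactly invariant under 90° rotations and mirrors.
* **Spur pruning** iteratively removes terminal branches shorter than
  5 px (configurable) that end at a junction; junction blobs of wide
  vessels otherwise sprout short false arms. Isolated short structures
  are kept — a blob's skeleton is legitimate.
* **Branch points** are 8-connected clusters of junction pixels
  (≥ 3 skeleton neighbors); one cluster = one count, which mirrors what
  a human annotator marks. The raw junction-pixel count is exposed as a
  secondary field (`n_junction_pixels`), and
  `count_branch_points(skel, merge_radius_px =)` provides a deliberately
  coarser counter that single-links clusters within a radius — useful
  for studying how junction-merging policy drives between-method
  disagreement: the resulting undercount grows with network size, the
  proportional-bias pattern that dominates comparisons of automated
  counters.
* **Total length** is the sum over 8-adjacent skeleton pixel pairs of
  the step length (1 orthogonal, √2 diagonal), each pair counted once.
  This convention is stated prominently because it differs from a pixel
  count by up to √2, and because on digital straight lines it
  *overestimates* true length by up to ~8% at angles near 22.5° — an
  intrinsic property of the 1/√2 chain code, not of this
  implementation. Averaged over the angles of a whole network the error
  is ~2%, which is why the recovery suite checks the mean relative
  error rather than a per-sample worst case.
* **Mean thickness** is the mean over skeleton pixels of `2·r − 1`,
  where `r` is the exact Euclidean distance to the nearest background
  pixel center (EBImage's exact distance transform of the unpruned
  mask). The pixel-center convention makes an ideal odd-width bar
  measure exactly its width and a 1-px line measure 1.
* **Lacunarity** is the gliding-box statistic
  `Λ(r) = var(mass)/mean(mass)² + 1` over all fully contained `r × r`
  windows, with population variance (a half-covered plane at `r = 1`
  then gives exactly 2). It is undefined on an all-background mask and
  raises a typed error.

Degenerate inputs follow one rule: empty masks give empty skeletons and
zero counts (valid); metrics that would divide by zero (mean thickness
of an empty skeleton, lacunarity of an empty mask, a positive
percentage with every pixel excluded) raise a
`camq_undefined_metric` condition rather than returning `NaN`.

## Segmentation

The segmenter is a classical stand-in with the same contract a learned
model honors (RGB in, binary mask at input resolution out; external
masks enter via `load_mask()`). Vessels are dark red on a bright
membrane, so tubularity is computed on the inverted green channel —
dark-ridge polarity is the single most important setting, and is why
bright specular highlights cannot create vessels. The pipeline:
Frangi-style multiscale Hessian ridge filter (scales 1.5–6 px,
bracketing the expected radii; β = 0.5; structureness scale set per
scale from the maximum Hessian norm; edge-replicated boundary handling
so image borders do not respond), Otsu threshold on the normalized
response, darkness-gated refinement (the thresholded response seeds
dark-pixel components, recovering the full vessel width the ridge
filter under-covers), then removal of components < 60 px and filling
of enclosed holes ≤ 120 px. Hole filling and small-object removal are
this package's declared cleanup choices; commercial tools do not
publish theirs.

The two-stage transfer-learning regimen used by commercial CNN tools
(pretraining on retinal fundus vessels, fine-tuning on a small CAM set,
256 × 256 patches with flip augmentation) is documented here as the
contract any learned substitute must honor; training such a model is
out of scope because its data and weights are not public.

## Positive pixel count

A pure per-pixel classifier in HSV: positive iff the hue lies within
`hue_center ± hue_width` (circular), saturation ≥ `saturation_min`,
and the 8-bit value ≤ `iwp`; positives are banded weak/medium/strong by
value with strong = darkest. Defaults (hue 0° ± 30°, saturation ≥ 0.15,
thresholds 220/175/130) target dark vessel red and are this package's
own choices — the commercial tool's settings are unpublished, so
comparisons to its numbers are qualitative. The five class counts are
asserted to sum to the pixel total on every call. Exclusion masks
remove pixels from both the counts and the percentage denominator,
reproducing the "negative pen tool" workflow used to fence off light
reflections.

## Manual-protocol emulation

The emulated human marks every junction once (identical to the
junction-cluster counter, exposed as `manual_branch_points()` so
comparison tables carry an explicit manual arm) and measures thickness
on a random sample of `n = 20` vessels. The sampling unit is the
skeleton segment, not the pixel — pixel sampling would weight long
vessels more — and the measurement is taken at the segment midpoint,
away from junctions, as a human would place a caliper. If fewer than
`n` segments exist, each is used once and the result is flagged
`undersampled`. Sampling is seeded and exactly reproducible;
Monte-Carlo tests verify the sampled mean is unbiased for the
segment-midpoint mean.

## Agreement statistics

For paired per-image series from methods A and B, differences are
oriented A − B (first-named method), stated in every report. Bias is
the mean difference; `sd_diff` uses the n − 1 denominator; the limits
of agreement are `bias ± 1.96·sd_diff` with 1.96 kept literal (a `z`
argument exists but defaults to 1.96); the paired t statistic is
`bias/(sd_diff/√n)` with `df = n − 1` and a two-sided p-value.
`sd_diff = 0` yields a valid report with the t statistic flagged `NA`;
`paired_t()` on such data is an error. Batch comparisons inner-join
methods on image id; unmatched ids are warned about and reported, never
silently dropped. `tidy()`/`glance()` expose per-pair data and the
one-row summary; `autoplot()` draws the Bland–Altman plot (bias in
green, limits of agreement as dashed red lines).

## Pipeline and reproducibility

`run_pipeline()` executes the whole in-silico study design: per image,
generate → render (optional artifacts) → segment → measure with every
arm (reference truth-mask morphometry, tubularity-mask morphometry,
manual emulation, positive pixel count) → one long results table →
all pairwise Bland–Altman reports. One master seed fans out to
per-image child seeds through a fixed integer hash (kept below 2³¹),
so per-image results are reproducible independently of batch size and
two runs with the same master seed are byte-identical. Per-image
failures are logged and skipped; the run aborts if more than 10% fail.
The manifest records package version, seeds, full configuration and
every output path.

## Problem sizes used in validation

The recovery suite measures 50 seeded trees (levels 2–4, root radii
4–6 px) on 320 × 320 px images; oracle equivalence enumerates 200
random blob masks up to 64 × 64; the agreement oracle sweeps 1000
random series; the type-I error simulation uses 2000 paired null
datasets of n = 30; the determinism check runs the full pipeline twice
at n = 30 images. These sizes give stable statistics (binomial SE
≈ 0.5% on the type-I rate) while keeping the whole validation run in
the minutes range on a single CPU.

## Known limitations

* The generator produces planar trees only; anastomoses, loops and
  crossing vessels — all present in real CAMs to some degree — are
  absent, and branch-point truth is only exact because of that.
* The 1/√2 length convention overestimates oblique straight segments
  by up to ~8%; length comparisons between tools using different chain
  conventions will differ systematically.
* Mean thickness inherits a ~half-pixel positive bias from measuring
  distances between pixel centers; it is visible for capillaries a few
  pixels wide and negligible for wide vessels.
* The segmenter is tuned for dark vessels on a bright membrane; stained
  or transmitted-light imagery with inverted polarity requires a
  different channel projection.
* The positive-pixel-count defaults are this package's, not the
  commercial tool's; absolute percentages are not comparable across
  implementations.
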