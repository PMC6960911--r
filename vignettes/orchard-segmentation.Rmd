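---
title: "Citrus crown segmentation under variable brightness and weed cover: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Citrus crown segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunables and why their defaults are what they are, what the
synthetic scenes emulate (and deliberately do not), and the numerical
decisions a maintainer would otherwise have to reverse-engineer from the
code. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The segmentation model

The pipeline treats an orchard frame as a three-layer scene: soil or
withered grass (red/yellow hues), weeds (green hue, fine spatial texture),
and tree crowns (green hue, coarse texture, compact footprint). Two scene
covariates dominate the difficulty: the brightness condition (BC) — mean
HSI intensity of the green foreground below 0.3 is "insufficient
brightness" (IB), at or above 0.3 "sufficient" (SB) — and the weed-cover
condition (WCC) — green-hue cover below 35 % (SWCR), 35–60 % (MWCR), at
least 60 % (LWCR). The stages target these covariates one at a time.

**Selective equalization.** Global histogram equalization fails on
bright-background/dark-foreground frames because the background owns the
histogram. Restricting the equalization to the green-hue selection
`S_g = {π/2 ≤ H ≤ π}` makes the transfer function a property of the canopy
alone. Only intensity is remapped; hue and saturation pass through, so the
later chromatic indices see compensated brightness but unchanged color.
The method assumes the green hue band actually captures vegetation — on
sensors with strong color casts the band bounds are configurable
(`greenHueRange`).

**Brightness-relative chromatic index.** The classic `G − R` aberration
separates vegetation from soil but scales with local illumination, so
shadow lowers it below threshold. Dividing by the pixel's own intensity
removes that first-order effect exactly: `im_p = (G − R)/I` is invariant
under multiplying a pixel's RGB by any positive constant (the test suite
checks this identity in exact arithmetic for dyadic factors). The index
cannot, however, distinguish crowns from green weeds — both sit high — and
that failure mode is embraced rather than patched: it is detected and
rerouted.

**The under-extraction rule.** When weeds flood the index, extracted area
A jumps and the number of separate regions N collapses (crowns fuse into
mats). The rule `A > T_A = 45 % or N < T_N = 20` flags such frames. The
thresholds sit roughly one standard deviation beyond the true per-frame
crown statistics of orchard imagery at the working scale (true area ratio
~34 ± 11.5 %, true count ~28 ± 7.7 trees per frame), so ordinary frames do
not trigger. T_N assumes frame footprints holding a few dozen trees; for
very different flight altitudes it should be re-derived, which is why both
are config keys (`uejrTA`, `uejrTN`).

**Retinex re-extraction.** Multi-scale retinex divides each channel by a
weighted geometric mean of its Gaussian-blurred surrounds (in log space,
with guard `ε = 1e-6`), leaving reflectance `M ≈ 1` wherever a pixel
resembles its neighbourhood at the chosen scales. An extended weed mat is
its own surround, so it flattens; a compact crown is an anomaly against
its surround at the medium and large scales, so it stands out. The
surround triple σ = (15, 80, 250) px is the conventional
small/medium/large retinex choice and is configurable; what matters is
that the large scales exceed the crown diameter (~45–60 px at the working
resolution of ~16 px/m). The excess-green map `2G − R − B` of M then
carries crowns as bright domes — helped by the physical dome shading of
real canopies seen from nadir — and the morphology cascade isolates them:
a 20 px-radius grayscale closing solidifies within-crown texture, a 24
px-radius white top-hat removes everything wider than its disk (the weed
plateau and soil gradients), and Otsu binarizes what remains. Convex-hull
filling (iterated to a fixed point, so every final component is convex)
repairs the edge erosion the large-radius morphology causes, and the 0.05 %
area floor removes residue.

One ordering decision deserves its own paragraph. The cascade is stated in
the literature of this method family with an additional grayscale opening
between the top-hat and the threshold, but the printed descriptions of
that chain disagree internally about whether the threshold consumes the
top-hat output or the opened output. Implementation settles it: at these
radii the opening (disk diameter 41 px) erases the very crown caps the
top-hat just isolated — a crown's top-hat response is a cap narrower than
the opening's support, so thresholding the opened map collapses tree
recovery almost entirely on weedy scenes (measured on calibration scenes
during development), while thresholding the top-hat map directly recovers
most crowns. The package therefore binarizes the top-hat map; the opening
remains available (`openingRadius`, default 0 = off) for data where the
residual speckle is wider than the crowns are peaked.

**Region confirmation.** Extraction is deliberately permissive; the final
arbiter is a linear SVM over 78 per-region descriptors. Color moments use
the full region mask; texture (GLCM, uniform LBP) uses the region's
maximum inner rectangle so ragged boundaries do not leak background
texture into the statistics, while rectangular training patches use their
full extent. Filtering can only remove predicted pixels, so pixel recall
can only fall; the stage pays that known, small price to remove weed
regions and raise precision — the acceptance suite measures both
directions of that trade.

## Tunables

| Key | Default | Units | Why |
| --- | --- | --- | --- |
| `greenHueRange` | (π/2, π) | rad | hue band read as vegetation |
| `heBins` | 256 | levels | classic 8-bit equalization granularity |
| `minAreaFrac` | 0.0005 | fraction | smallest real crown ≈ 0.1 % of a frame; floor at half that |
| `diskRadius` | 5 | px | boundary smoothing without eating crown edges |
| `msrSigmas` | 15, 80, 250 | px | conventional retinex triple; large scales ≫ crown radius |
| `msrEpsilon` | 1e-6 | – | log guard; small enough not to bias mid-tones |
| `closingRadius` | 20 | px | solidify within-crown texture (≈ half a crown radius) |
| `tophatRadius` | 24 | px | pass crowns (width < 49 px caps), delete wider background |
| `openingRadius` | 0 | px | optional pre-threshold speckle suppression (see above) |
| `uejrTA` | 45 | % | ≈ mean + 1 sd of true per-frame crown area ratio |
| `uejrTN` | 20 | trees | ≈ mean − 1 sd of true per-frame tree count |
| `svmCost` | 1 | – | soft-margin C; features are standardized so 1 is a sane scale |
| `matchIoU` | 0.5 | – | standard one-to-one detection-matching threshold |

## The synthetic orchard generator

No public dataset exists for this task, so the generator is a first-class,
tested module that emulates the *structure* of the field data: elliptical
crowns (semi-axes 26–31 × 28–38 px at ~16 px/m, i.e. 2.8 m-class canopies)
with coarse multiplicative mottle (correlation length 4 px, amplitude
35 %) and radial edge shading (canopy curvature seen from nadir); soil
with low-amplitude brightness mottle; weed fields with fine grain (0.8 px)
and slight per-channel chroma jitter, laid out in patches of 40 px
correlation length up to a per-stratum green-cover target (0.28 / 0.42 /
0.70); a weed-free clearance ring around crowns (24 px; 12 px on LWCR
scenes where weed pressure encroaches on the canopy), as herbicide strips
and canopy shade produce in managed orchards; a global brightness factor
(1.0 for SB, 0.5 for IB scenes); then optical blur (σ 0.6 px) and additive
sensor noise (σ 0.008). The MWCR target of 0.42 deliberately places the
primary extraction's area ratio astride the T_A = 45 threshold, so
mid-cover frames route to either backend image by image — the behaviour
the rule is designed to produce on real mid-cover data.

All randomness flows through one seeded generator; rendering is
bit-for-bit reproducible, and the truth object records per-tree masks,
centroids, the weed mask, and condition labels *recomputed from the
rendered pixels* so a scene that drifts across a condition boundary is
labelled by what it is, not what was requested.

What the generator does **not** emulate — and therefore what passing tests
do not establish about field data: perspective and terrain relief,
inter-crown occlusion and touching canopies (crowns are packed disjoint),
specular leaf highlights, cast shadows with direction, sensor color
response and compression artifacts, and the long-tailed irregularity of
real weed communities. Results on synthetic scenes bound the method's
behaviour under the modelled variation only; the acceptance quantities are
scaled-down analogues, not field accuracies.

Problem sizes used by the shipped checks: the test suite's study-scale
dataset is 10 scenes per stratum (60 scenes of 640 × 640 px, 24 trees
each) with a 200-patch training set; the acceptance script regenerates 6
scenes per stratum and the same training design. Unit tests use smaller
scenes (192–480 px, 3–10 trees) chosen so each property is exercised at
the smallest size where it is meaningful.

## Numerical decisions

- **HSI variant.** Intensity is the arithmetic mean `(R+G+B)/3`; the
  brightness-relative index divides by a quantity that must scale linearly
  with RGB, which rules out max- or luma-weighted variants. Hue uses the
  arccos form reflected to [π, 2π] when B > G; achromatic pixels take
  hue 0, saturation 0; black pixels are all-zero.
- **Gamut policy.** Synthesized HSI triplets can exceed the RGB cube.
  Generic conversion clips (`hsiToRgb(gamut = "clip")`), but the
  equalizers use `gamut = "desaturate"`: saturation is compressed per
  pixel just enough to fit, keeping hue and the compensated intensity
  exact. Per-channel clipping instead corrupts the S_g intensity
  histogram, and a second equalization pass then moves pixels by far more
  than one gray level — desaturation is what makes the documented
  idempotence property true.
- **Equalization transfer.** Scaled to 255/256 (the classic discrete-HE
  output range). Mapping the top bin to exactly 1.0 forces complete
  desaturation — the pixel turns white, loses its hue, and silently leaves
  the green selection between passes. Binning adds a 1e-9 guard because
  equalized values land exactly on bin edges by construction and
  round-trip noise otherwise splits tied groups across bins.
- **Otsu on continuous maps.** Min–max scaling, 256 bins, first maximum
  (smallest threshold) on ties; foreground is strictly above the
  threshold. A constant map is a degenerate histogram and errors (the
  extraction wrappers convert that to an empty region set with a warning).
- **Morphology on real-valued maps.** EBImage's grayscale morphology
  expects [0, 1]; the chromatic map is min–max normalized first, which is
  harmless because morphology and the Otsu split both commute with affine
  rescaling.
- **Connectivity and coordinates.** 8-connectivity everywhere (a diagonal
  touch joins), labels ordered by first pixel in column-major order so
  labelling is a pure function of the mask. Coordinates are 1-based
  (row, column) from the top-left pixel — the native convention of R and
  of every installed imaging package; a 0-based convention would fight
  the entire ecosystem.
- **Texture conventions.** GLCM: 16 gray levels by min–max quantization,
  distance-1 symmetric co-occurrences averaged over 0°/45°/90°/135°
  (standard Haralick practice), entropy in base-10 logs with
  `0·lg 0 = 0`, correlation defined as 0 when a marginal variance
  vanishes. LBP: 8 neighbours at radius 1 with bilinear diagonal
  sampling, bit set when neighbour ≥ centre (so a constant patch maps to
  the all-ones uniform pattern), 58 uniform bins in ascending code order
  plus one pooled bin. Hue means and variances are circular (resultant
  direction and 1 − resultant length): hue is an angle and a linear mean
  across the 0/2π wrap would be meaningless. Variances are population
  variances.
- **Matching rule.** The field reports a correct-segmentation rate without
  defining region-to-tree matching; the package uses greedy one-to-one
  matching by descending IoU with acceptance at IoU ≥ 0.5, ties broken by
  region id for determinism, and CTR defined as matched trees over true
  trees (a recall-like rate). Both the threshold and the rule are exposed
  (`matchIoU`).
- **Degenerate regions.** Regions whose maximum inner rectangle is
  smaller than 3 × 3 cannot carry texture statistics; they are dropped
  from classification and recorded in the provenance rather than
  silently scored.
- **SVM determinism and orientation.** Features are z-scored with
  training-set statistics (zero-variance dimensions pass through); the
  dual solution is collapsed to a primal weight vector, oriented so
  positive scores mean `tree`; a score of exactly 0 is `background`.

## Known limitations

- Touching or overlapping crowns are returned as one region; splitting
  fused canopies (watershed or learned instance separation) is out of
  scope.
- The retinex chain's fixed radii presume the ~16 px/m working scale; at
  other ground resolutions the images should be resampled or the radii
  rescaled together.
- The SVM is trained on rectangular patches but applied to arbitrarily
  shaped regions; the full-mask / inner-rectangle asymmetry is inherited
  from the training design and is visible as a small domain gap on
  heavily eroded regions.
- On scenes whose green cover hovers at the T_A threshold, backend choice
  is sensitive to small changes — by design, but it means per-image
  provenance (recorded in every result) matters when comparing runs.
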