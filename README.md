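# orchardseg

Segmentation of individual citrus tree crowns in nadir RGB images of
orchards taken from low-altitude agricultural UAVs. The problem that makes
this hard in practice is not the trees — it is the scene: frames range from
well-lit to badly under-exposed, and the orchard floor ranges from bare soil
to near-continuous weed cover whose color closely matches the canopy. This
package implements a segmentation pipeline designed around exactly those two
axes of variation (brightness condition and weed-cover condition), plus a
deterministic synthetic-orchard generator so every stage can be exercised
and evaluated without any field data.

It is aimed at people building autonomous-operation tooling for orchard
UAVs (per-tree spraying, counting, monitoring) and at anyone who wants a
tested, scriptable reference implementation of this family of
chromatic-index + retinex + texture-SVM segmentation methods.

## The method

For an RGB image with HSI decomposition (hue `H` in [0, 2π], intensity
`I = (R+G+B)/3`), the pipeline is:

1. **Selective illumination compensation (SRIHE).** The green foreground is
   `S_g = {p : π/2 ≤ H(p) ≤ π}`. The 256-bin histogram of `I` restricted to
   `S_g` is equalized; hue, saturation and all non-green pixels are left
   untouched. Unlike global histogram equalization, the transfer function is
   not dominated by the background, so a dark canopy is stretched to full
   contrast even under a bright background.

2. **Primary extraction (ERGCM).** The brightness-relative chromatic index

   `im_p = (G_p − R_p) / I_p` (0 where `I_p = 0`)

   is thresholded by Otsu's between-class-variance criterion; components
   smaller than 0.05 % of the image are removed, boundaries are smoothed by
   a 5 px disk closing, and interior holes are filled. Division by `I`
   makes the index exactly invariant to local brightness, so shaded and
   sunlit canopy segment alike.

3. **Under-extraction judgement (UEJR).** Weeds score high on `im_p` too;
   on weedy scenes the primary extraction fuses crowns and understory. With
   `A` the extracted area ratio (%) and `N` the region count, the result is
   declared under-extracted when `A > 45` or `N < 20`, and the scene is
   re-extracted by:

4. **Retinex re-extraction (EMSRCM).** A multi-scale retinex reflectance
   `M_i = exp Σ_j W_j [log(S_i + ε) − log(S_i ⊗ G_σj + ε)]` (per channel,
   Gaussian surrounds σ = 15, 80, 250 px) suppresses the extended weed
   background and highlights crowns as compact chromatic anomalies. The
   excess-green map `2G − R − B` of `M` is solidified by a 20 px grayscale
   closing, freed of slowly varying background by a 24 px white top-hat,
   Otsu-binarized, convex-hull filled per component, and area-filtered.

5. **SVM confirmation.** Every candidate region gets a 78-dimensional
   descriptor — mean/variance of R, G, B, H, S, a*, b* over the region mask
   (14), five gray-level co-occurrence statistics at 16 levels (CON, ASM,
   ENT, IDM, COR), and the 59-bin uniform LBP histogram, texture taken over
   the region's maximum inner rectangle — and a standardized linear-kernel
   SVM keeps regions scored as `tree`. This removes weed regions that
   survive extraction, raising pixel precision at a small recall cost.

Evaluation follows the same two views the method is judged by in the field:
pixel metrics (IoU, P_I, R_I, F1_I) and tree-count metrics (CTR, P_C, R_C,
F1_C) under greedy one-to-one matching at IoU ≥ 0.5, plus ROC/AUC of the
region scores.

## A worked example

```r
library(orchardseg)

# a linear SVM from synthetic training patches (tree / weed / soil)
model <- trainLinearSvm(generateTrainingPatches(20, 16, 4, seed = 1), seed = 1)

# an under-lit, heavily weed-infested scene with per-tree ground truth
sc <- generateScene(stratumSceneSpec(bc = "IB", wcc = "LWCR", seed = 7))
classifyConditions(sc$image)[c("bc", "wcc")]
#> $bc
#> [1] "IB"
#> $wcc
#> [1] "LWCR"

res <- segmentImage(sc$image, model)
res
#> SegmentationResult: backend EMSRCM, 24 candidate region(s), 24 kept
head(res@table[, c("id", "centroidRow", "centroidCol", "area", "score", "label")], 4)
#>   id centroidRow centroidCol area    score label
#> 1  1   141.98043    55.63225 1482 1.694110  tree
#> 2  2   336.11370    56.75270 1759 1.958496  tree
#> 3  3    42.95655    70.88082 1611 2.154155  tree
#> 4  4   589.34296    88.30686 1385 1.845618  tree

round(evaluateScene(res, sc$truth), 1)
#>  IoU  P_I  R_I F1_I  CTR  P_C  R_C F1_C TP_C FP_C FN_C
#> 55.5 93.6 57.7 71.4 70.8 70.8 70.8 70.8 17.0  7.0  7.0
```

The scene was routed to the retinex backend (the primary extraction's area
ratio exceeded 45 % on this weed mat), and 17 of the 24 trees were
recovered one-to-one — heavy weed cover is the hardest condition, which is
the point of exercising it. On low-weed scenes the primary chain recovers
every crown with IoU above 0.99 (see the pipeline tests).

A thin command-line wrapper over the same functions is installed at
`inst/cli/orchardseg.R`:

```sh
Rscript inst/cli/orchardseg.R generate --out data --n 2 --seed 1
Rscript inst/cli/orchardseg.R train    --out model.json --seed 1
Rscript inst/cli/orchardseg.R segment  --image data/images/scene_001.png \
                                       --model model.json --out seg
Rscript inst/cli/orchardseg.R evaluate --pred seg/labels.png \
                                       --truth data/truth/scene_001.png --out eval
```

## Package tour

| Area | Functions |
| --- | --- |
| Color spaces | `rgbToHsi`, `hsiToRgb`, `rgbToLab` |
| Illumination | `srihe`, `globalHe`, `classifyBrightness`, `greenSelectionMask` |
| Extraction | `relativeGRMap`, `extractRoisErgcm`, `uejrIsUnderExtracted`, `msrReflectance`, `chromatic2grb`, `extractRoisEmsrcm` |
| Regions | `labelRegions`, `maxInnerRectangle`, `otsuThreshold` |
| Features | `colorFeatures`, `glcmFeatures`, `lbpHistogram`, `regionFeatures` |
| Classifier | `trainLinearSvm`, `classifyRegions`, `writeSvmModel` / `readSvmModel` |
| Evaluation | `pixelMetrics`, `treeCountMetrics`, `rocAuc`, `evaluationReport` |
| Synthetic data | `sceneSpec`, `stratumSceneSpec`, `generateScene`, `generateDataset`, `generateTrainingPatches` |
| Pipeline | `pipelineConfig`, `classifyConditions`, `segmentImage`, `writeRegionCsv` |

The methods vignette (`vignettes/orchard-segmentation.Rmd`) documents the
model assumptions, every tunable with its default and rationale, what the
synthetic scenes do and do not emulate, and the numerical edge cases.
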