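#' @include AllClasses.R illumination.R pipeline.R
NULL

#' Construct a synthetic scene specification
#'
#' Defaults render a nadir orchard frame at an effective scale of ~16 px/m
#' (a 2.8 m crown spans ~45 px): two dozen non-overlapping textured
#' elliptical crowns over mottled soil, green weed patches raising the
#' scene's green-cover fraction to `greenTarget`, then a global brightness
#' factor, optical blur and sensor noise. Crown mottle is coarse
#' (leaf-cluster scale) while weed grain is fine — the spatial-frequency
#' contrast the retinex re-extraction chain exploits. All randomness flows
#' through one generator seeded with `seed`.
#'
#' @param width,height scene size in px.
#' @param nTrees number of crowns.
#' @param crownSemiMinor,crownSemiMajor semi-axis ranges in px.
#' @param minGap minimum clearance between crown bounding circles (px).
#' @param crownColor,weedColor,soilColor base RGB triplets.
#' @param crownMottleSigma,crownMottleAmp crown texture correlation length
#'   (px) and relative amplitude.
#' @param crownEdgeShade radial darkening towards the crown rim (canopy
#'   curvature self-shading; 0 renders flat discs).
#' @param weedGrainSigma,weedGrainAmp weed texture correlation length (px)
#'   and relative amplitude.
#' @param weedChromaAmp amplitude of per-channel (hue-perturbing) weed jitter.
#' @param weedPatchSigma correlation length (px) of the weed patch layout.
#' @param weedClearance weed-free ring around crowns (px); canopy shade
#'   suppresses understory growth at crown margins (~0.75 m at this scale).
#' @param greenTarget target green-cover fraction (crowns + weeds).
#' @param colorJitter per-crown brightness jitter half-range.
#' @param brightness global multiplicative brightness (1 = sufficient
#'   brightness; ~0.5 renders an insufficient-brightness scene).
#' @param blurSigma optical blur sigma (px).
#' @param noiseSigma additive Gaussian sensor noise s.d.
#' @param allowOverlap allow crowns to overlap.
#' @param seed integer seed.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(width = 640L, height = 640L, nTrees = 24L,
                      crownSemiMinor = c(26, 31),
                      crownSemiMajor = c(28, 38), minGap = 18,
                      crownColor = c(0.28, 0.62, 0.22),
                      weedColor = c(0.38, 0.60, 0.25),
                      soilColor = c(0.45, 0.36, 0.24),
                      crownMottleSigma = 4, crownMottleAmp = 0.35,
                      crownEdgeShade = 0.3,
                      weedGrainSigma = 0.8, weedGrainAmp = 0.25,
                      weedChromaAmp = 0.05, weedPatchSigma = 40,
                      weedClearance = 24, greenTarget = 0.28,
                      colorJitter = 0.12,
                      brightness = 1.0, blurSigma = 0.6, noiseSigma = 0.008,
                      allowOverlap = FALSE, seed = 1L) {
  obj <- new("SceneSpec", width = width, height = height, nTrees = nTrees,
             crownSemiMinor = crownSemiMinor, crownSemiMajor = crownSemiMajor,
             minGap = minGap, crownColor = crownColor, weedColor = weedColor,
             soilColor = soilColor, crownEdgeShade = crownEdgeShade,
             crownMottleSigma = crownMottleSigma,
             crownMottleAmp = crownMottleAmp, weedGrainSigma = weedGrainSigma,
             weedGrainAmp = weedGrainAmp, weedChromaAmp = weedChromaAmp,
             weedPatchSigma = weedPatchSigma, weedClearance = weedClearance,
             greenTarget = greenTarget,
             colorJitter = colorJitter, brightness = brightness,
             blurSigma = blurSigma, noiseSigma = noiseSigma,
             allowOverlap = allowOverlap, seed = seed)
  validObject(obj)
  obj
}

#' Scene specification for a named study stratum
#'
#' Maps a brightness condition (`IB`/`SB`) and weed-cover condition
#' (`SWCR`/`MWCR`/`LWCR`) to generator settings: green-cover targets 0.28 /
#' 0.42 / 0.70 (inside the < 35%, 35-60%, >= 60% bands) and brightness
#' factors 0.5 (IB) / 1.0 (SB), which place the mean foreground intensity on
#' the intended side of the 0.3 boundary. Heavily infested (LWCR) scenes get
#' a narrower weed clearance ring (12 px instead of 24): with weed pressure
#' that high, growth encroaches on the canopy edge.
#'
#' @param bc `"IB"` or `"SB"`.
#' @param wcc `"SWCR"`, `"MWCR"` or `"LWCR"`.
#' @param seed integer seed.
#' @param ... further overrides passed to [sceneSpec()].
#' @return a [SceneSpec-class].
#' @export
stratumSceneSpec <- function(bc = c("SB", "IB"),
                             wcc = c("SWCR", "MWCR", "LWCR"),
                             seed = 1L, ...) {
  bc <- match.arg(bc); wcc <- match.arg(wcc)
  args <- list(greenTarget = switch(wcc, SWCR = 0.28, MWCR = 0.42, LWCR = 0.70),
               brightness = switch(bc, SB = 1.0, IB = 0.5),
               seed = seed, ...)
  if (wcc == "LWCR" && !("weedClearance" %in% names(list(...))))
    args$weedClearance <- 12
  do.call(sceneSpec, args)
}

# Rejection-sample non-overlapping rotated ellipses. Returns a data.frame
# (row, col, a, b, theta) or errors on infeasible packing.
packCrowns <- function(spec) {
  n <- spec@nTrees
  if (n == 0L) return(data.frame(row = numeric(), col = numeric(),
                                 a = numeric(), b = numeric(),
                                 theta = numeric()))
  placed <- data.frame(row = numeric(n), col = numeric(n), a = numeric(n),
                       b = numeric(n), theta = numeric(n))
  maxTries <- 400L * n
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("infeasible packing: cannot place ", n, " crowns in ",
           spec@height, " x ", spec@width)
    a <- runif(1, spec@crownSemiMajor[1L], spec@crownSemiMajor[2L])
    b <- runif(1, spec@crownSemiMinor[1L], spec@crownSemiMinor[2L])
    if (b > a) { tmp <- a; a <- b; b <- tmp }
    margin <- a + 2
    if (2 * margin >= min(spec@height, spec@width))
      stop("infeasible packing: crowns larger than the scene")
    row <- runif(1, margin, spec@height - margin)
    col <- runif(1, margin, spec@width - margin)
    ok <- TRUE
    if (!spec@allowOverlap && i > 1L) {
      j <- seq_len(i - 1L)
      d2 <- (placed$row[j] - row)^2 + (placed$col[j] - col)^2
      ok <- all(d2 > (placed$a[j] + a + spec@minGap)^2)
    }
    if (ok) {
      placed[i, ] <- c(row, col, a, b, runif(1, 0, pi))
      i <- i + 1L
    }
  }
  placed
}

# Paint ellipse `crown` into a label map and a squared-elliptical-radius map
# (0 at the crown centre, 1 at the rim; drives edge shading). `canvas` is a
# list(label, rho2); returns the updated list.
paintEllipse <- function(canvas, crown, id) {
  labelMap <- canvas$label
  h <- nrow(labelMap); w <- ncol(labelMap)
  rr <- max(1L, floor(crown$row - crown$a)):min(h, ceiling(crown$row + crown$a))
  cc <- max(1L, floor(crown$col - crown$a)):min(w, ceiling(crown$col + crown$a))
  dy <- matrix(rr - crown$row, length(rr), length(cc))
  dx <- matrix(cc - crown$col, length(rr), length(cc), byrow = TRUE)
  ct <- cos(crown$theta); st <- sin(crown$theta)
  u <- (dx * ct + dy * st) / crown$a
  v <- (-dx * st + dy * ct) / crown$b
  rho2 <- u^2 + v^2
  inside <- rho2 <= 1
  subL <- labelMap[rr, cc]; subR <- canvas$rho2[rr, cc]
  subL[inside] <- id
  subR[inside] <- rho2[inside]
  canvas$label[rr, cc] <- subL
  canvas$rho2[rr, cc] <- subR
  canvas
}

#' Render a synthetic orchard scene with ground truth
#'
#' Deterministic given `spec@seed`: the same spec renders bit-identical
#' pixels and truth. The truth's condition labels (`bc`, `wcc`) are
#' recomputed from the rendered pixels with the same thresholds the pipeline
#' uses, so they remain correct even when blur/noise move a scene across a
#' boundary.
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements `image` ([RGBImage-class]) and `truth`
#'   ([SceneTruth-class]).
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  withSeed(spec@seed, {
    h <- as.integer(spec@height); w <- as.integer(spec@width)
    # soil with coarse + fine brightness mottle (hue-preserving)
    soilField <- 1 + 0.10 * smoothNoise(h, w, 30) + 0.05 * smoothNoise(h, w, 1.5)
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- spec@soilColor[ch] * soilField
    # crowns
    crowns <- packCrowns(spec)
    canvas <- list(label = matrix(0L, h, w), rho2 = matrix(0, h, w))
    for (i in seq_len(nrow(crowns)))
      canvas <- paintEllipse(canvas, crowns[i, ], i)
    treeLabelMap <- canvas$label
    crownMask <- treeLabelMap > 0L
    # weed patches filling up to the green-cover target; kept clear of a
    # shaded ring around each crown. Painted area overshoots by the fraction
    # of boundary/jittered weed pixels whose rendered hue leaves the green
    # band (~10%), so the rendered green cover lands on target.
    weedField <- smoothNoise(h, w, spec@weedPatchSigma)
    excl <- crownMask
    if (spec@weedClearance > 0 && any(crownMask))
      excl <- EBImage::dilate(asImage(crownMask * 1),
                              discBrush(spec@weedClearance)) > 0.5
    needed <- (spec@greenTarget * h * w - sum(crownMask)) / 0.95
    weedOnly <- matrix(FALSE, h, w)
    if (needed > 0) {
      avail <- weedField[!excl]
      p <- min(1, needed / length(avail))
      thr <- quantile(avail, 1 - p, names = FALSE)
      weedOnly <- weedField > thr & !excl
    }
    if (any(weedOnly)) {
      grain <- smoothNoise(h, w, spec@weedGrainSigma)
      for (ch in 1:3) {
        chroma <- smoothNoise(h, w, spec@weedGrainSigma)
        plane <- img[, , ch]
        plane[weedOnly] <- (spec@weedColor[ch] *
          (1 + spec@weedGrainAmp * grain[weedOnly]) *
          (1 + spec@weedChromaAmp * chroma[weedOnly]))
        img[, , ch] <- plane
      }
    }
    # crown texture: shared multiplicative mottle + per-crown jitter
    if (nrow(crowns) > 0L) {
      mottle <- 1 + spec@crownMottleAmp * smoothNoise(h, w, spec@crownMottleSigma)
      dome <- 1 - spec@crownEdgeShade * canvas$rho2   # curvature self-shading
      jB <- runif(nrow(crowns), 1 - spec@colorJitter, 1 + spec@colorJitter)
      jH <- runif(nrow(crowns), -0.06, 0.06)   # slight green-red balance shift
      for (ch in 1:3) {
        base <- spec@crownColor[ch] *
          (1 + jH * switch(ch, -1, 1, 0)) * jB   # per-crown channel multiplier
        plane <- img[, , ch]
        sel <- crownMask
        plane[sel] <- base[treeLabelMap[sel]] * mottle[sel] * dome[sel]
        img[, , ch] <- plane
      }
    }
    # global brightness, optics, sensor
    img <- img * spec@brightness
    if (spec@blurSigma > 0)
      for (ch in 1:3) img[, , ch] <- gaussianBlur(img[, , ch], spec@blurSigma)
    img <- img + array(rnorm(length(img), sd = spec@noiseSigma), dim(img))
    img <- clip01(img)
    image <- RGBImage(img)
    cond <- classifyConditions(image)
    centroids <- as.matrix(crowns[, c("row", "col")])
    truth <- new("SceneTruth", treeLabelMap = treeLabelMap,
                 weedMask = weedOnly, centroids = centroids,
                 bc = cond$bc, wcc = cond$wcc)
    list(image = image, truth = truth)
  })
}

#' Render a balanced multi-stratum dataset
#'
#' Generates `nPerStratum` scenes for each requested brightness x weed-cover
#' stratum, with per-scene seeds drawn reproducibly from the master seed. The
#' manifest records the requested stratum, the per-scene seed, and the
#' condition labels recomputed from the rendered pixels.
#'
#' @param nPerStratum scenes per stratum.
#' @param strata data.frame with columns `bc` and `wcc` (default: all six
#'   IB/SB x SWCR/MWCR/LWCR combinations).
#' @param seed master seed.
#' @param dir optional output directory; when given, images and per-tree
#'   truth label maps are written as PNG under `images/` and `truth/` with a
#'   `manifest.csv`.
#' @param ... overrides forwarded to [sceneSpec()].
#' @return list with `scenes` (list of `generateScene()` outputs, annotated
#'   with their spec) and `manifest` (data.frame).
#' @export
generateDataset <- function(nPerStratum, strata = NULL, seed = 1L, dir = NULL,
                            ...) {
  stopifnot(nPerStratum >= 1)
  if (is.null(strata))
    strata <- expand.grid(bc = c("IB", "SB"),
                          wcc = c("SWCR", "MWCR", "LWCR"),
                          stringsAsFactors = FALSE)
  total <- nrow(strata) * nPerStratum
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, total))
  scenes <- vector("list", total)
  manifest <- data.frame(scene = seq_len(total),
                         bc = rep(strata$bc, each = nPerStratum),
                         wcc = rep(strata$wcc, each = nPerStratum),
                         seed = seeds,
                         renderedBc = character(total),
                         renderedWcc = character(total),
                         nTrees = integer(total),
                         stringsAsFactors = FALSE)
  for (i in seq_len(total)) {
    spec <- stratumSceneSpec(bc = manifest$bc[i], wcc = manifest$wcc[i],
                             seed = seeds[i], ...)
    sc <- generateScene(spec)
    sc$spec <- spec
    scenes[[i]] <- sc
    manifest$renderedBc[i] <- sc$truth@bc
    manifest$renderedWcc[i] <- sc$truth@wcc
    manifest$nTrees[i] <- max(sc$truth@treeLabelMap)
  }
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    manifest$imagePath <- file.path("images", sprintf("scene_%03d.png",
                                                      manifest$scene))
    manifest$truthPath <- file.path("truth", sprintf("scene_%03d.png",
                                                     manifest$scene))
    for (i in seq_len(total)) {
      writeRGBImage(scenes[[i]]$image, file.path(dir, manifest$imagePath[i]))
      writeLabelPng(scenes[[i]]$truth@treeLabelMap,
                    file.path(dir, manifest$truthPath[i]))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(scenes = scenes, manifest = manifest)
}

#' Render labelled training patches
#'
#' Square patches emulating a manually marked training set: positive patches
#' contain one large crown over soil; negative patches are weed fields or
#' bare soil/withered grass. Per-patch brightness is drawn uniformly over the
#' IB-to-SB range so the classifier sees both regimes. Patches are rendered
#' with the same texture machinery as full scenes and passed through the same
#' illumination compensation as the segmentation pipeline before their
#' descriptors are computed (texture over the full patch rectangle).
#'
#' @param nTree,nWeed,nSoil patch counts per class (defaults 100/80/20 —
#'   a balanced tree vs background design with weeds dominating the
#'   negatives).
#' @param size patch side in px (default 200).
#' @param seed master seed.
#' @return a [RegionFeatures-class] with labels `tree`/`background`.
#' @export
generateTrainingPatches <- function(nTree = 100L, nWeed = 80L, nSoil = 20L,
                                    size = 200L, seed = 1L) {
  total <- nTree + nWeed + nSoil
  kinds <- rep(c("tree", "weed", "soil"), c(nTree, nWeed, nSoil))
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, total))
  rows <- vector("list", total)
  wholePatch <- function(size) {
    lm <- matrix(1L, size, size)
    new("RegionSet", labelMap = lm,
        regions = data.frame(id = 1L, area = size * size,
                             centroidRow = (size + 1) / 2,
                             centroidCol = (size + 1) / 2,
                             rowMin = 1L, rowMax = size,
                             colMin = 1L, colMax = size))
  }
  rsAll <- wholePatch(size)
  for (i in seq_len(total)) {
    img <- withSeed(seeds[i], renderPatch(kinds[i], size))
    img <- srihe(img)
    rows[[i]] <- regionFeatureVector(img, rsAll, 1L, mode = "full_mask")
  }
  feat <- do.call(rbind, rows)
  labs <- factor(ifelse(kinds == "tree", "tree", "background"),
                 levels = c("background", "tree"))
  new("RegionFeatures", features = feat, labels = labs,
      regionIds = seq_len(total))
}

# Render one training patch (tree / weed / soil); consumes the RNG stream.
renderPatch <- function(kind, size) {
  spec <- sceneSpec(width = size, height = size, nTrees = 0L,
                    greenTarget = 0, seed = 0L)
  h <- size; w <- size
  soilField <- 1 + 0.10 * smoothNoise(h, w, 30) + 0.05 * smoothNoise(h, w, 1.5)
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- spec@soilColor[ch] * soilField
  if (kind == "tree") {
    a <- runif(1, 0.42, 0.48) * size
    b <- runif(1, 0.38, 0.44) * size
    crown <- data.frame(row = size / 2 + runif(1, -6, 6),
                        col = size / 2 + runif(1, -6, 6),
                        a = a, b = b, theta = runif(1, 0, pi))
    canvas <- paintEllipse(list(label = matrix(0L, h, w),
                                rho2 = matrix(0, h, w)), crown, 1L)
    mottle <- 1 + spec@crownMottleAmp * smoothNoise(h, w, spec@crownMottleSigma)
    dome <- 1 - spec@crownEdgeShade * canvas$rho2
    jB <- runif(1, 1 - spec@colorJitter, 1 + spec@colorJitter)
    jH <- runif(1, -0.06, 0.06)
    sel <- canvas$label > 0L
    for (ch in 1:3) {
      base <- spec@crownColor[ch] * (1 + jH * switch(ch, -1, 1, 0)) * jB
      plane <- img[, , ch]
      plane[sel] <- base * mottle[sel] * dome[sel]
      img[, , ch] <- plane
    }
  } else if (kind == "weed") {
    grain <- smoothNoise(h, w, spec@weedGrainSigma)
    for (ch in 1:3) {
      chroma <- smoothNoise(h, w, spec@weedGrainSigma)
      img[, , ch] <- spec@weedColor[ch] *
        (1 + spec@weedGrainAmp * grain) * (1 + spec@weedChromaAmp * chroma)
    }
  }
  img <- img * runif(1, 0.45, 1.1)
  for (ch in 1:3) img[, , ch] <- gaussianBlur(img[, , ch], spec@blurSigma)
  img <- img + array(rnorm(length(img), sd = spec@noiseSigma), dim(img))
  RGBImage(clip01(img))
}
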