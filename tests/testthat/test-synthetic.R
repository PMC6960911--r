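test_that("scene rendering is bit-for-bit deterministic in its seed", {
  spec <- tinySceneSpec(seed = 42L)
  a <- generateScene(spec)
  b <- generateScene(spec)
  expect_identical(imgData(a$image), imgData(b$image))
  expect_identical(a$truth@treeLabelMap, b$truth@treeLabelMap)
  expect_identical(a$truth@weedMask, b$truth@weedMask)
  # a different seed renders a different field
  c <- generateScene(tinySceneSpec(seed = 43L))
  expect_false(identical(imgData(a$image), imgData(c$image)))
})

test_that("rendered green cover lands within 5 points of the target", {
  for (tgt in c(0.3, 0.5, 0.7)) {
    sc <- generateScene(sceneSpec(width = 320L, height = 320L, nTrees = 6L,
                                  greenTarget = tgt, weedClearance = 12,
                                  seed = 101L))
    A <- classifyConditions(sc$image)$greenFraction
    expect_lt(abs(A - tgt), 0.05)
  }
})

test_that("brightness condition closes the loop with the generator", {
  ib <- generateScene(tinySceneSpec(seed = 7L, brightness = 0.5))
  expect_equal(as.character(classifyBrightness(ib$image)), "IB")
  expect_equal(ib$truth@bc, "IB")
  sb <- generateScene(tinySceneSpec(seed = 7L, brightness = 1.0))
  expect_equal(as.character(classifyBrightness(sb$image)), "SB")
  expect_equal(sb$truth@bc, "SB")
})

test_that("crown chromatic index dominates soil; weeds carry the fine detail", {
  sc <- generateScene(sceneSpec(width = 320L, height = 320L, nTrees = 6L,
                                greenTarget = 0.45, weedClearance = 12,
                                seed = 55L))
  im <- relativeGRMap(sc$image)@data
  crown <- sc$truth@treeLabelMap > 0
  weed <- sc$truth@weedMask
  soil <- !crown & !weed
  expect_gt(median(im[crown]), quantile(im[soil], 0.99))
  # weed texture lives at higher spatial frequency than crown texture
  g <- rgbToHsi(sc$image)@intensity
  hp <- g - orchardseg:::gaussianBlur(g, 2)
  inner <- function(m) {                     # erode masks 3 px off boundaries
    EBImage::erode(orchardseg:::asImage(m * 1),
                   EBImage::makeBrush(7, "disc")) > 0.5
  }
  ratio <- stats::var(hp[inner(weed)]) / stats::var(hp[inner(crown)])
  expect_gt(ratio, 1)
})

test_that("impossible crown packings fail loudly", {
  expect_error(generateScene(sceneSpec(width = 224L, height = 224L,
                                       nTrees = 40L, seed = 3L)),
               "infeasible packing")
  expect_error(generateScene(sceneSpec(width = 48L, height = 48L,
                                       nTrees = 1L, seed = 3L)),
               "infeasible")
})

test_that("datasets are balanced, reproducible and self-consistently labelled", {
  ds <- generateDataset(2L, seed = 99L, width = 320L, height = 320L,
                        nTrees = 6L)
  expect_equal(nrow(ds$manifest), 12L)
  expect_equal(as.integer(table(ds$manifest$wcc)), rep(4L, 3))
  expect_equal(length(ds$scenes), 12L)
  # identical master seed, identical manifest and pixels
  ds2 <- generateDataset(2L, seed = 99L, width = 320L, height = 320L,
                         nTrees = 6L)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(imgData(ds$scenes[[5]]$image), imgData(ds2$scenes[[5]]$image))
  # rendered condition labels agree with the requested strata
  agree <- mean(ds$manifest$bc == ds$manifest$renderedBc &
                ds$manifest$wcc == ds$manifest$renderedWcc)
  expect_gte(agree, 11 / 12)
  # written layout: images/, truth/, manifest.csv
  dir <- tempfile()
  generateDataset(1L, strata = data.frame(bc = "SB", wcc = "SWCR"),
                  seed = 1L, dir = dir, width = 256L, height = 256L,
                  nTrees = 4L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "images", "scene_001.png")))
  lm <- readLabelPng(file.path(dir, "truth", "scene_001.png"))
  expect_equal(max(lm), 4L)
})

test_that("training patches render both classes deterministically", {
  p1 <- generateTrainingPatches(3L, 2L, 1L, size = 64L, seed = 5L)
  expect_equal(dim(featureMatrix(p1)), c(6L, 78L))
  expect_equal(as.integer(table(featureLabels(p1))), c(3L, 3L))
  p2 <- generateTrainingPatches(3L, 2L, 1L, size = 64L, seed = 5L)
  expect_identical(featureMatrix(p1), featureMatrix(p2))
})
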