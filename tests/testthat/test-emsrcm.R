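# Build a RegionSet with a prescribed number of equal blobs on a grid, so
# that A and N can be dialled independently.
gridRegions <- function(n, blobSide, dim = c(100L, 100L), spacing = 3L) {
  mask <- matrix(FALSE, dim[1], dim[2])
  perRow <- floor(dim[2] / (blobSide + spacing))
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% perRow) * (blobSide + spacing) + 1
    c0 <- ((i - 1) %% perRow) * (blobSide + spacing) + 1
    mask[r0:(r0 + blobSide - 1), c0:(c0 + blobSide - 1)] <- TRUE
  }
  labelRegions(mask)
}

test_that("under-extraction fires on large area or low region count", {
  # A ~ 51% with 30 regions: area trigger
  rs <- gridRegions(30, 17, dim = c(130L, 130L))
  expect_gt(100 * areaFraction(rs), 45)
  expect_gte(regionCount(rs), 20)
  expect_true(uejrIsUnderExtracted(rs))
  # A ~ 30% with 10 regions: count trigger
  rs <- gridRegions(10, 17, dim = c(100L, 100L), spacing = 8L)
  expect_lt(100 * areaFraction(rs), 45)
  expect_true(uejrIsUnderExtracted(rs))
  # A ~ 30% with 30 regions: neither
  rs <- gridRegions(30, 10, dim = c(100L, 100L), spacing = 8L)
  expect_false(uejrIsUnderExtracted(rs))
  # thresholds are parameters
  expect_true(uejrIsUnderExtracted(rs, tN = 31))
})

test_that("retinex reflectance limits: constant images and delta kernels", {
  const <- uniformImage(32, 32, c(0.4, 0.6, 0.2))
  for (sig in list(c(3, 10, 30), c(1, 1, 1))) {
    M <- msrReflectance(const, sigmas = sig)
    expect_lt(max(abs(M - 1)), 1e-6)
  }
  # sigma -> 0: the kernel degenerates to a delta and M == 1 for any image
  img <- randomImage(24, 24, seed = 55)
  M <- msrReflectance(img, sigmas = c(1e-4, 1e-4, 1e-4))
  expect_lt(max(abs(M - 1)), 1e-6)
})

test_that("retinex cancels global multiplicative illumination", {
  set.seed(77)
  img <- RGBImage(array(runif(48 * 48 * 3, 0.2, 1), c(48, 48, 3)))
  M1 <- msrReflectance(img, sigmas = c(5, 15, 40), epsilon = 1e-6)
  M2 <- msrReflectance(RGBImage(imgData(img) * 0.55),
                       sigmas = c(5, 15, 40), epsilon = 1e-6)
  expect_lt(max(abs(M1 - M2)), 1e-3)
})

test_that("retinex highlights a bright spot against its surround", {
  a <- array(0.05, c(33, 33, 3))
  a[17, 17, ] <- 0.9
  M <- msrReflectance(RGBImage(a), sigmas = c(5, 5, 5))
  expect_gt(M[17, 17, 2], 1)
  expect_lt(M[2, 2, 2], 1 + 1e-6)
})

test_that("2G-R-B is the superposition of the two aberrations", {
  m <- chromatic2grb(uniformImage(1, 1, c(0.2, 0.6, 0.1)))
  expect_equal(m@data[1, 1], 0.9)
  expect_equal(chromatic2grb(uniformImage(1, 1, c(0.3, 0.3, 0.3)))@data[1, 1], 0)
  img <- randomImage(10, 10, seed = 9)
  d <- imgData(img)
  expect_equal(chromatic2grb(img)@data,
               (d[, , 2] - d[, , 1]) + (d[, , 2] - d[, , 3]))
})

test_that("re-extraction yields convex regions and is deterministic", {
  sc <- generateScene(sceneSpec(width = 320L, height = 320L, nTrees = 5L,
                                greenTarget = 0.6, weedClearance = 12,
                                seed = 61L))
  pre <- srihe(sc$image)
  rs1 <- extractRoisEmsrcm(pre)
  rs2 <- extractRoisEmsrcm(pre)
  expect_identical(labelMap(rs1), labelMap(rs2))
  expect_gt(regionCount(rs1), 0L)
  lm <- labelMap(rs1)
  for (id in regionTable(rs1)$id) {
    sub <- lm == id
    hull <- orchardseg:::convexHullFill(sub)
    expect_equal(sum(hull & !sub), 0)   # already its own convex hull
  }
})

test_that("convex hull filling closes concave notches", {
  mask <- matrix(FALSE, 30, 30)
  mask[5:25, 5:25] <- TRUE
  mask[5:15, 14:16] <- FALSE   # notch from the top edge
  filled <- orchardseg:::convexHullFill(mask)
  expect_true(all(filled[mask]))
  expect_gt(sum(filled), sum(mask))
  expect_true(all(filled[5:15, 14:16]))
})

test_that("retinex enhancement widens the crown-weed chromatic separation", {
  sc <- generateScene(sceneSpec(width = 384L, height = 384L, nTrees = 6L,
                                greenTarget = 0.65, weedClearance = 12,
                                seed = 83L))
  pre <- srihe(sc$image)
  crown <- sc$truth@treeLabelMap > 0
  weed <- sc$truth@weedMask
  fisher <- function(map) {
    (mean(map[crown]) - mean(map[weed]))^2 /
      (var(as.vector(map[crown])) + var(as.vector(map[weed])))
  }
  onS <- fisher(chromatic2grb(pre)@data)
  onM <- fisher(chromatic2grb(msrReflectance(pre))@data)
  expect_gt(onM, onS)
})
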