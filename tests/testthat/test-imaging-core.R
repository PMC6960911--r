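test_that("RGB to HSI matches hand-derived reference pixels", {
  px <- function(r, g, b) RGBImage(array(c(r, g, b), c(1, 1, 3)))
  h <- rgbToHsi(px(0, 1, 0))       # pure green via the arccos form
  expect_equal(h@hue[1, 1], 2 * pi / 3)
  expect_equal(h@sat[1, 1], 1)
  expect_equal(h@intensity[1, 1], 1 / 3)
  g <- rgbToHsi(px(0.5, 0.5, 0.5)) # achromatic convention
  expect_equal(c(g@hue[1, 1], g@sat[1, 1], g@intensity[1, 1]), c(0, 0, 0.5))
  b <- rgbToHsi(px(0, 0, 0))       # black convention
  expect_equal(c(b@hue[1, 1], b@sat[1, 1], b@intensity[1, 1]), c(0, 0, 0))
  # blue-dominant pixel reflects into [pi, 2*pi]
  bl <- rgbToHsi(px(0.1, 0.2, 0.8))
  expect_gt(bl@hue[1, 1], pi)
})

test_that("HSI round trip is the identity for in-gamut images", {
  img <- randomImage(100, 100, seed = 101)   # 10,000 pixels
  rt <- hsiToRgb(rgbToHsi(img))
  expect_lt(max(abs(imgData(rt) - imgData(img))), 1e-6)
  # achromatic inverse example
  hsi <- new("HSIImage", hue = matrix(0), sat = matrix(0),
             intensity = matrix(0.3))
  expect_equal(as.vector(imgData(hsiToRgb(hsi))), c(0.3, 0.3, 0.3))
  # inverse of the pure-green forward example
  hsi <- new("HSIImage", hue = matrix(2 * pi / 3), sat = matrix(1),
             intensity = matrix(1 / 3))
  expect_equal(as.vector(imgData(hsiToRgb(hsi))), c(0, 1, 0), tolerance = 1e-9)
})

test_that("Lab conversion hits the reference white and neutral axis", {
  lab <- rgbToLab(uniformImage(1, 1, c(1, 1, 1)))
  expect_equal(c(lab@L[1, 1], lab@a[1, 1], lab@b[1, 1]), c(100, 0, 0),
               tolerance = 1e-6)
  lab0 <- rgbToLab(uniformImage(1, 1, c(0, 0, 0)))
  expect_equal(c(lab0@L[1, 1], lab0@a[1, 1], lab0@b[1, 1]), c(0, 0, 0),
               tolerance = 1e-6)
  labg <- rgbToLab(uniformImage(1, 1, c(0.5, 0.5, 0.5)))
  expect_equal(c(labg@a[1, 1], labg@b[1, 1]), c(0, 0), tolerance = 1e-6)
  expect_true(labg@L[1, 1] > 0 && labg@L[1, 1] < 100)
})

test_that("Otsu threshold separates bimodal data and matches brute force", {
  v <- c(rep(0.1, 8), rep(0.9, 8))
  thr <- otsuThreshold(v)
  expect_true(thr > 0.1 && thr < 0.9)
  expect_equal(v > thr, v == 0.9)
  set.seed(7)
  for (i in 1:50) {
    x <- c(rnorm(150, 0.3, 0.12), rnorm(100, 0.75, 0.08))
    expect_equal(as.numeric(otsuThreshold(x)), bruteOtsu(x))
  }
  expect_error(otsuThreshold(rep(0.4, 10)), "degenerate")
})

test_that("region labelling counts components under 8-connectivity", {
  mask <- matrix(FALSE, 100, 100)
  mask[1:3, 1:3] <- TRUE
  mask[51:53, 61:63] <- TRUE
  rs <- labelRegions(mask)
  expect_equal(regionCount(rs), 2L)
  expect_equal(100 * areaFraction(rs), 0.18)
  expect_equal(sum(regionTable(rs)$area), sum(mask))
  # full foreground
  full <- labelRegions(matrix(TRUE, 10, 10))
  expect_equal(regionCount(full), 1L)
  expect_equal(areaFraction(full), 1)
  # diagonal touch joins
  diag2 <- matrix(FALSE, 5, 5); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(regionCount(labelRegions(diag2)), 1L)
  # empty mask
  empty <- labelRegions(matrix(FALSE, 4, 4))
  expect_equal(regionCount(empty), 0L)
  expect_equal(areaFraction(empty), 0)
})

test_that("region areas always sum to the foreground pixel count", {
  set.seed(11)
  for (i in 1:20) {
    mask <- matrix(runif(40 * 40) < 0.4, 40, 40)
    rs <- labelRegions(mask)
    expect_equal(sum(regionTable(rs)$area), sum(mask))
    lm <- labelMap(rs)
    if (regionCount(rs) > 0)
      expect_equal(sort(unique(lm[lm > 0])), seq_len(regionCount(rs)))
  }
})

test_that("maximum inner rectangle agrees with exhaustive enumeration", {
  # solid square is its own inner rectangle
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  rs <- labelRegions(sq)
  r <- maxInnerRectangle(rs, 1L)
  expect_equal(unname(r), c(3L, 3L, 12L, 12L))
  # L-shape: one 5 x 10 arm wins (area 50)
  L <- matrix(FALSE, 20, 20); L[1:10, 1:5] <- TRUE; L[1:5, 1:10] <- TRUE
  r <- maxInnerRectangle(labelRegions(L), 1L)
  expect_equal((r["rowMax"] - r["rowMin"] + 1) * (r["colMax"] - r["colMin"] + 1),
               c(rowMax = 50))
  expect_equal(bruteMaxRect(L), 50)
  # rasterized disk and random blobs vs brute force
  set.seed(5)
  xy <- expand.grid(r = 1:19, c = 1:19)
  disk <- matrix((xy$r - 10)^2 + (xy$c - 10)^2 <= 64, 19, 19)
  rDisk <- maxInnerRectangle(labelRegions(disk), 1L)
  expect_equal((rDisk["rowMax"] - rDisk["rowMin"] + 1) *
               (rDisk["colMax"] - rDisk["colMin"] + 1),
               c(rowMax = bruteMaxRect(disk)))
  for (i in 1:15) {
    m <- matrix(runif(12 * 12) < 0.65, 12, 12)
    rs <- labelRegions(m)
    for (id in regionTable(rs)$id) {
      sub <- labelMap(rs) == id
      r <- maxInnerRectangle(rs, id)
      expect_true(all(sub[r["rowMin"]:r["rowMax"], r["colMin"]:r["colMax"]]))
      expect_equal((r["rowMax"] - r["rowMin"] + 1) *
                   (r["colMax"] - r["colMin"] + 1),
                   c(rowMax = bruteMaxRect(sub)))
    }
  }
  expect_error(maxInnerRectangle(labelRegions(matrix(FALSE, 3, 3)), 1L))
})
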