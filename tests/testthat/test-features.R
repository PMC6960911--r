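test_that("color statistics over a region: means, variances, fixed order", {
  img <- uniformImage(6, 6, c(0.1, 0.6, 0.2))
  f <- colorFeatures(img, matrix(TRUE, 6, 6))
  expect_equal(length(f), 14L)
  expect_equal(names(f)[1:6],
               c("mean_R", "var_R", "mean_G", "var_G", "mean_B", "var_B"))
  expect_equal(unname(f[c("mean_R", "mean_G", "mean_B")]), c(0.1, 0.6, 0.2))
  expect_equal(unname(f[c("var_R", "var_G", "var_B", "var_H", "var_S")]),
               rep(0, 5), tolerance = 1e-12)
  # population variance on a two-pixel region
  a <- array(0.5, c(1, 2, 3)); a[1, 1, 1] <- 0.2; a[1, 2, 1] <- 0.4
  f2 <- colorFeatures(RGBImage(a), matrix(TRUE, 1, 2))
  expect_equal(unname(f2["mean_R"]), 0.3)
  expect_equal(unname(f2["var_R"]), 0.01)
  expect_error(colorFeatures(img, matrix(c(TRUE, rep(FALSE, 35)), 6, 6)),
               "at least 2")
})

test_that("hue statistics are circular across the 0/2pi wrap", {
  hsi <- new("HSIImage",
             hue = matrix(c(0.1, 2 * pi - 0.1), 1, 2),
             sat = matrix(0.8, 1, 2), intensity = matrix(0.4, 1, 2))
  img <- hsiToRgb(hsi)
  f <- colorFeatures(img, matrix(TRUE, 1, 2))
  circDist <- min(abs(f["mean_H"] - c(0, 2 * pi)))
  expect_lt(circDist, 1e-6)            # circular mean sits at the wrap
  expect_lt(unname(f["var_H"]), 0.01)  # tight cluster
  # a linear mean would have landed near pi
  expect_gt(abs(pi - f["mean_H"]), 3)
})

test_that("GLCM statistics match brute-force pair enumeration", {
  # constant rectangle: single co-occurrence cell
  f <- glcmFeatures(matrix(0.5, 4, 4))
  expect_equal(unname(f), c(0, 1, 0, 1, 0))
  # alternating two-level strip, horizontal pairs only: CON = 1, IDM = 0.5
  strip <- matrix(rep(c(0, 1), 4), 2, 8, byrow = TRUE)
  f <- glcmFeatures(strip, k = 2L, directions = "0")
  expect_equal(unname(f["glcm_con"]), 1)
  expect_equal(unname(f["glcm_idm"]), 0.5)
  # random patches vs oracle
  set.seed(21)
  for (i in 1:10) {
    g <- matrix(runif(64), 8, 8)
    expect_equal(glcmFeatures(g), bruteGlcm(g), tolerance = 1e-10)
  }
  expect_error(glcmFeatures(matrix(0.1, 1, 5)), "at least 2 x 2")
})

test_that("GLCM probabilities behave like a distribution", {
  set.seed(22)
  for (i in 1:10) {
    g <- matrix(runif(100), 10, 10)
    f <- glcmFeatures(g)
    expect_gte(unname(f["glcm_con"]), 0)
    expect_true(f["glcm_asm"] > 0 && f["glcm_asm"] <= 1)
    expect_gte(unname(f["glcm_ent"]), 0)
    expect_true(f["glcm_idm"] > 0 && f["glcm_idm"] <= 1)
    expect_true(abs(f["glcm_cor"]) <= 1 + 1e-12)
  }
})

test_that("uniform LBP matches brute-force pattern enumeration", {
  # constant rectangle: every pattern is the all-ones uniform code
  f <- lbpHistogram(matrix(0.3, 5, 5))
  expect_equal(sum(f), 1)
  expect_equal(sum(f > 0), 1L)
  expect_equal(unname(f[59]), 0)       # not in the pooled non-uniform bin
  set.seed(23)
  for (i in 1:10) {
    g <- matrix(runif(64), 8, 8)
    expect_equal(unname(lbpHistogram(g)), bruteLbp(g), tolerance = 1e-10)
  }
  expect_error(lbpHistogram(matrix(0.1, 2, 5)), "at least 3 x 3")
})

test_that("LBP histogram is invariant to gray-level offset and gain", {
  set.seed(24)
  g <- matrix(runif(15 * 15, 0, 0.5), 15, 15)
  base <- lbpHistogram(g)
  expect_equal(lbpHistogram(g + 0.2), base)        # offset
  expect_equal(lbpHistogram(g * 1.7 + 0.05), base) # positive affine map
  expect_equal(sum(base), 1)
})

test_that("region descriptors assemble 78 dimensions with the right support", {
  sc <- generateScene(tinySceneSpec(seed = 71, nTrees = 3L, size = 256L,
                                    greenTarget = 0.2))
  rs <- extractRoisErgcm(srihe(sc$image))
  expect_gt(regionCount(rs), 0L)
  v <- regionFeatureVector(sc$image, rs, 1L, mode = "inner_rect")
  expect_equal(length(v), 78L)
  expect_equal(names(v), featureNames78())
  expect_false(any(is.na(v)))
  expect_equal(sum(v[sprintf("lbp_%02d", 1:59)]), 1)
  # full-mask mode on a patch-like single region uses the whole rectangle
  lmAll <- matrix(1L, 20, 20)
  rsAll <- new("RegionSet", labelMap = lmAll,
               regions = data.frame(id = 1L, area = 400L, centroidRow = 10.5,
                                    centroidCol = 10.5, rowMin = 1L,
                                    rowMax = 20L, colMin = 1L, colMax = 20L))
  img <- randomImage(20, 20, seed = 72)
  vf <- regionFeatureVector(img, rsAll, 1L, mode = "full_mask")
  gray <- rgbToHsi(img)@intensity
  expect_equal(vf[15:19], glcmFeatures(gray))
  # a 1-px-wide region is rejected with a message
  thin <- matrix(0L, 10, 10); thin[3, 2:9] <- 1L
  rsThin <- labelRegions(thin > 0)
  expect_message(out <- regionFeatureVector(img, rsThin, 1L), "dropped")
  expect_null(out)
})

test_that("feature tables serialize with a fixed column order", {
  lmAll <- matrix(1L, 12, 12)
  rsAll <- labelRegions(lmAll > 0)
  rf <- regionFeatures(randomImage(12, 12, seed = 73), rsAll,
                       mode = "full_mask", labels = "tree")
  path <- tempfile(fileext = ".csv")
  writeFeatureCsv(rf, path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(names(df), c("regionId", "label", featureNames78()))
  expect_equal(df$label, "tree")
  expect_equal(unlist(df[1, featureNames78()], use.names = FALSE),
               as.vector(featureMatrix(rf)[1, ]))
})
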