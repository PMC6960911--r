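test_that("pixel metrics satisfy their algebraic identities", {
  m1 <- matrix(FALSE, 10, 10); m1[1:3, 1:3] <- TRUE
  expect_equal(unname(pixelMetrics(m1, m1)), rep(100, 4))
  m2 <- matrix(FALSE, 10, 10); m2[8:9, 8:9] <- TRUE
  d <- pixelMetrics(m1, m2)
  expect_equal(unname(d[c("IoU", "P_I", "R_I")]), c(0, 0, 0))
  # |pred| = |truth| = 2, overlap 1
  p <- matrix(FALSE, 4, 4); t <- p
  p[1, 1:2] <- TRUE; t[1, 2:3] <- TRUE
  m <- pixelMetrics(p, t)
  expect_equal(unname(m["IoU"]), 100 / 3, tolerance = 1e-9)
  expect_equal(unname(m[c("P_I", "R_I", "F1_I")]), c(50, 50, 50))
  # swapping prediction and truth swaps P and R, preserves IoU and F1
  sw <- pixelMetrics(t, p)
  expect_equal(unname(sw["P_I"]), unname(m["R_I"]))
  expect_equal(unname(sw["R_I"]), unname(m["P_I"]))
  expect_equal(unname(sw[c("IoU", "F1_I")]), unname(m[c("IoU", "F1_I")]))
  # empty against empty: perfect by convention
  e <- matrix(FALSE, 5, 5)
  expect_equal(unname(pixelMetrics(e, e)), rep(100, 4))
  expect_error(pixelMetrics(m1, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("tree counting matches one-to-one at IoU >= 0.5", {
  # 10 truth squares; 9 predicted faithfully, 1 missed, 1 spurious blob
  truth <- matrix(0L, 60, 120)
  for (i in 1:10) {
    r0 <- 6 + 12 * ((i - 1) %/% 5); c0 <- 4 + 23 * ((i - 1) %% 5)
    truth[r0:(r0 + 8), c0:(c0 + 8)] <- i
  }
  pred <- truth
  pred[pred == 10L] <- 0L                      # miss one tree
  pred[50:55, 100:105] <- 11L                  # one spurious region
  pred <- labelMap(labelRegions(pred > 0L))    # contiguous relabel
  m <- treeCountMetrics(pred, truth)
  expect_equal(unname(m[c("TP_C", "FP_C", "FN_C")]), c(9, 1, 1))
  expect_equal(unname(m[c("P_C", "R_C", "CTR")]), c(90, 90, 90))
  expect_equal(unname(m["F1_C"]), 90)
  # identical region sets
  expect_equal(unname(treeCountMetrics(truth, truth)["CTR"]), 100)
})

test_that("one truth tree cannot absorb two predictions", {
  truth <- matrix(0L, 20, 20); truth[5:16, 5:16] <- 1L
  pred <- matrix(0L, 20, 20)
  pred[5:16, 5:10] <- 1L     # left half
  pred[5:16, 11:16] <- 2L    # right half
  # halves have IoU 0.5 each; only one can match
  m <- treeCountMetrics(pred, truth, iouMin = 0.4)
  expect_equal(unname(m[c("TP_C", "FP_C", "FN_C")]), c(1, 1, 0))
})

test_that("tree counting ignores region label permutations", {
  set.seed(31)
  truth <- labelMap(labelRegions(matrix(runif(400) < 0.3, 20, 20)))
  pred <- truth
  n <- max(truth)
  perm <- sample(n)
  permuted <- truth
  permuted[truth > 0] <- perm[truth[truth > 0]]
  expect_equal(treeCountMetrics(pred, permuted), treeCountMetrics(pred, truth))
})

test_that("AUC equals the rank statistic and resists monotone transforms", {
  # perfectly separated scores
  r <- rocAuc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 100)
  expect_equal(max(r$curve$tpr), 100)
  # random scores vs labels: AUC near 50
  set.seed(33)
  sc <- runif(10000); lb <- runif(10000) < 0.5
  expect_lt(abs(rocAuc(sc, lb)$auc - 50), 2)
  # rank-statistic identity, including heavy ties
  for (i in 1:10) {
    s <- sample(1:6, 60, replace = TRUE)   # discrete: forces tied scores
    l <- runif(60) < 0.4
    if (sum(l) == 0 || sum(l) == 60) next
    expect_equal(rocAuc(s, l)$auc, bruteAucU(s, l), tolerance = 1e-12)
    expect_equal(rocAuc(exp(s / 2), l)$auc, rocAuc(s, l)$auc)
  }
  expect_error(rocAuc(c(1, 2), c(TRUE, TRUE)), "both classes")
  # factor labels: tree is the positive class
  expect_equal(rocAuc(c(2, 1), factor(c("tree", "background")))$auc, 100)
})

test_that("scene evaluation combines pixel and count views", {
  truth <- matrix(0L, 30, 30); truth[3:12, 3:12] <- 1L; truth[18:27, 18:27] <- 2L
  rs <- labelRegions(truth > 0L)
  ev <- evaluateScene(rs, truth)
  expect_equal(unname(ev["IoU"]), 100)
  expect_equal(unname(ev["CTR"]), 100)
  rep <- evaluationReport(data.frame(scene = 1:2, bc = "SB", wcc = "SWCR",
                                     IoU = c(90, 80), CTR = c(100, 90)))
  expect_equal(unname(rep$overall["mean_IoU"]), 85)
  expect_equal(unname(rep$byStratum$mean_CTR), 95)
  dir <- tempfile()
  writeEvaluationReport(rep, dir)
  expect_true(file.exists(file.path(dir, "per_scene.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
})
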