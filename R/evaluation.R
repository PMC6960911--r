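#' @include regions.R
NULL

#' Pixel-level segmentation metrics
#'
#' Intersection-over-union, precision, recall and F1 of a predicted
#' foreground mask against a reference mask, all in percent. `TP` is the
#' overlap area, `FP` predicted-only area, `FN` reference-only area. Two
#' empty masks score 100 everywhere by convention; an undefined precision or
#' recall (empty denominator against a non-empty counterpart) scores 0.
#'
#' @param pred,truth logical matrices of equal shape.
#' @return named numeric vector `(IoU, P_I, R_I, F1_I)` in `[0, 100]`.
#' @export
pixelMetrics <- function(pred, truth) {
  pred <- pred > 0; truth <- truth > 0
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth masks must share dimensions")
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp + fp + fn == 0L)
    return(c(IoU = 100, P_I = 100, R_I = 100, F1_I = 100))
  iou <- 100 * tp / (tp + fp + fn)
  p <- if (tp + fp > 0L) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(IoU = iou, P_I = p, R_I = r, F1_I = f1)
}

# Pairwise IoU between the regions of two label maps, via the pixel
# contingency table. Returns a data.frame (predId, truthId, iou).
regionPairIou <- function(predMap, truthMap) {
  sel <- predMap > 0L & truthMap > 0L
  if (!any(sel)) return(data.frame(predId = integer(), truthId = integer(),
                                   iou = numeric()))
  pa <- tabulate(predMap[predMap > 0L])
  ta <- tabulate(truthMap[truthMap > 0L])
  key <- (as.integer(predMap[sel]) - 1L) * length(ta) + as.integer(truthMap[sel])
  cnt <- table(key)
  k <- as.integer(names(cnt))
  predId <- (k - 1L) %/% length(ta) + 1L
  truthId <- (k - 1L) %% length(ta) + 1L
  inter <- as.integer(cnt)
  data.frame(predId = predId, truthId = truthId,
             iou = inter / (pa[predId] + ta[truthId] - inter))
}

#' Tree-count segmentation metrics
#'
#' Matches predicted regions to reference trees one-to-one, greedily by
#' descending pairwise IoU; a pair with IoU at or above `iouMin` is a true
#' positive. Unmatched predictions are false positives, unmatched reference
#' trees false negatives. `CTR` (the correct-segmentation rate) is the
#' fraction of reference trees matched, in percent; precision, recall and F1
#' follow the usual count definitions. An empty denominator scores 100 by
#' convention (nothing to find / nothing asserted).
#'
#' @param pred,truth [RegionSet-class] objects (or integer label maps) on the
#'   same image.
#' @param iouMin match acceptance threshold (default 0.5).
#' @return named numeric vector
#'   `(CTR, P_C, R_C, F1_C, TP_C, FP_C, FN_C)`; rates in `[0, 100]`.
#' @export
treeCountMetrics <- function(pred, truth, iouMin = 0.5) {
  predMap <- if (is(pred, "RegionSet")) labelMap(pred) else pred
  truthMap <- if (is(truth, "RegionSet")) labelMap(truth) else truth
  if (!identical(dim(predMap), dim(truthMap)))
    stop("prediction and truth must share dimensions")
  nPred <- max(0L, max(predMap))
  nTruth <- max(0L, max(truthMap))
  pairs <- regionPairIou(predMap, truthMap)
  pairs <- pairs[pairs$iou >= iouMin, , drop = FALSE]
  pairs <- pairs[order(-pairs$iou, pairs$predId, pairs$truthId), , drop = FALSE]
  usedP <- logical(nPred); usedT <- logical(nTruth)
  tp <- 0L
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$predId[i]; t <- pairs$truthId[i]
    if (!usedP[p] && !usedT[t]) {
      usedP[p] <- TRUE; usedT[t] <- TRUE; tp <- tp + 1L
    }
  }
  fp <- nPred - tp
  fn <- nTruth - tp
  pc <- if (nPred > 0L) 100 * tp / nPred else 100
  rc <- if (nTruth > 0L) 100 * tp / nTruth else 100
  f1 <- if (pc + rc > 0) 2 * pc * rc / (pc + rc) else 0
  c(CTR = if (nTruth > 0L) 100 * tp / nTruth else 100,
    P_C = pc, R_C = rc, F1_C = f1, TP_C = tp, FP_C = fp, FN_C = fn)
}

#' ROC curve and AUC of region decision scores
#'
#' Sweeps the decision threshold over every distinct score (ties grouped),
#' plotting the true-positive rate against the false-positive rate, and
#' integrates by the trapezoid rule — equivalent to the Mann-Whitney
#' two-sample rank statistic with ties counted half.
#'
#' @param scores numeric decision scores (larger = more tree-like).
#' @param labels logical (or `tree`/`background` factor); `TRUE`/`tree` is
#'   the positive class. Both classes must be present.
#' @return list with `auc` (percent) and `curve` (data.frame of `fpr`, `tpr`
#'   in percent, one row per distinct threshold plus the two endpoints).
#' @export
rocAuc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) labels <- labels == "tree"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(l); fpCum <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(auc = 100 * auc,
       curve = data.frame(fpr = 100 * fpr, tpr = 100 * tpr))
}

#' Evaluate one segmented scene against its ground truth
#'
#' @param result a [SegmentationResult-class] (or [RegionSet-class]).
#' @param truth a [SceneTruth-class] (or integer tree label map).
#' @param iouMin count-metric match threshold.
#' @return named numeric vector combining [pixelMetrics()] and
#'   [treeCountMetrics()].
#' @export
evaluateScene <- function(result, truth, iouMin = 0.5) {
  rs <- if (is(result, "SegmentationResult")) result@regions else result
  tMap <- if (is(truth, "SceneTruth")) truth@treeLabelMap else truth
  c(pixelMetrics(labelMap(rs) > 0L, tMap > 0L),
    treeCountMetrics(rs, tMap, iouMin = iouMin))
}

#' Aggregate per-scene metrics into a stratified report
#'
#' @param perScene data.frame with one row per scene: condition columns `bc`,
#'   `wcc` plus metric columns.
#' @return list with `perScene`, `byStratum` (mean and sd per BC x WCC cell)
#'   and `overall` (mean and sd across scenes).
#' @export
evaluationReport <- function(perScene) {
  metricCols <- setdiff(names(perScene),
                        c("scene", "bc", "wcc", "backend", "seed"))
  agg <- function(df) {
    m <- colMeans(df[, metricCols, drop = FALSE])
    s <- apply(df[, metricCols, drop = FALSE], 2L, stats::sd)
    c(setNames(m, paste0("mean_", metricCols)),
      setNames(s, paste0("sd_", metricCols)), n = nrow(df))
  }
  strata <- split(perScene, interaction(perScene$bc, perScene$wcc, drop = TRUE))
  byStratum <- do.call(rbind, lapply(strata, agg))
  list(perScene = perScene,
       byStratum = as.data.frame(byStratum),
       overall = agg(perScene))
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report output of [evaluationReport()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEvaluationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$perScene, file.path(dir, "per_scene.csv"), row.names = FALSE)
  write.csv(cbind(stratum = rownames(report$byStratum), report$byStratum),
            file.path(dir, "by_stratum.csv"), row.names = FALSE)
  jsonlite::write_json(list(overall = as.list(report$overall)),
                       file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
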