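#' @include features.R
NULL

#' Train the linear region-confirmation SVM
#'
#' Z-score standardizes each feature dimension on the training set
#' (zero-variance dimensions pass through unscaled), then fits a soft-margin
#' linear-kernel SVM (hinge loss, via libsvm). The dual solution is collapsed
#' to a primal weight vector and bias, oriented so that positive decision
#' scores mean `tree`. The fit is deterministic given the data and `seed`.
#'
#' @param x a [RegionFeatures-class], or a numeric matrix of descriptors.
#' @param labels factor/character with levels `background`/`tree`; taken from
#'   `x` when it is a labelled [RegionFeatures-class].
#' @param cost soft-margin cost C (default 1).
#' @param seed integer seed (libsvm itself is deterministic; the seed also
#'   fixes any downstream stochastic use recorded in the model metadata).
#' @return a [TreeSvmModel-class].
#' @export
trainLinearSvm <- function(x, labels = NULL, cost = 1, seed = 1L) {
  if (is(x, "RegionFeatures")) {
    if (is.null(labels)) labels <- featureLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("background", "tree"))
  if (anyNA(labels)) stop("every training sample needs a background/tree label")
  if (nlevels(droplevels(labels)) < 2L)
    stop("training needs at least one sample of each class")
  bad <- which(!stats::complete.cases(x) | !apply(is.finite(x), 1L, all))
  if (length(bad) > 0L)
    stop("non-finite feature values in training rows: ",
         paste(head(bad, 5L), collapse = ", "))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  fit <- withSeed(seed,
                  e1071::svm(xs, labels, kernel = "linear", cost = cost,
                             scale = FALSE, type = "C-classification"))
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  sc <- as.numeric(xs %*% w + b)
  if (mean(sc[labels == "tree"]) < mean(sc[labels == "background"])) {
    w <- -w; b <- -b
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- sprintf("f%03d", seq_len(ncol(x)))
  new("TreeSvmModel", weights = w, bias = b, center = as.numeric(ctr),
      scale = as.numeric(scl), featureNames = nm, cost = cost,
      meta = list(classCounts = as.list(table(labels)),
                  seed = as.integer(seed), version = "1"))
}

#' Decision scores of regions under a trained model
#'
#' @param model a [TreeSvmModel-class].
#' @param x a [RegionFeatures-class] or numeric matrix whose columns match
#'   the model's feature dimensions.
#' @return numeric vector of signed decision scores (`> 0` means tree).
#' @export
svmDecisionScores <- function(model, x) {
  stopifnot(is(model, "TreeSvmModel"))
  if (is(x, "RegionFeatures")) x <- featureMatrix(x)
  x <- as.matrix(x)
  if (ncol(x) != length(model@weights))
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 length(model@weights), ncol(x)))
  xs <- sweep(sweep(x, 2L, model@center), 2L, model@scale, "/")
  as.numeric(xs %*% model@weights + model@bias)
}

#' Classify candidate regions
#'
#' Scores each region and labels it `tree` when the decision score is
#' strictly positive (a score of exactly 0 is `background`). Regions labelled
#' `background` are the ones the pipeline removes from the final
#' segmentation.
#'
#' @inheritParams svmDecisionScores
#' @return data.frame with columns `score` and `label`.
#' @export
classifyRegions <- function(model, x) {
  sc <- svmDecisionScores(model, x)
  data.frame(score = sc,
             label = factor(ifelse(sc > 0, "tree", "background"),
                            levels = c("background", "tree")))
}

#' Save / load a model as versioned JSON
#'
#' All numeric content (weights, bias, standardization, metadata) is written
#' as plain JSON so models are portable text artifacts.
#'
#' @param model a [TreeSvmModel-class].
#' @param path file path.
#' @return `writeSvmModel` the path, invisibly; `readSvmModel` the model.
#' @export
writeSvmModel <- function(model, path) {
  stopifnot(is(model, "TreeSvmModel"))
  obj <- list(format = "orchardseg-svm", version = model@meta$version,
              weights = model@weights, bias = model@bias,
              center = model@center, scale = model@scale,
              featureNames = model@featureNames, cost = model@cost,
              meta = model@meta[setdiff(names(model@meta), "version")])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSvmModel
#' @export
readSvmModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "orchardseg-svm"))
    stop("not an orchardseg SVM model file")
  new("TreeSvmModel", weights = as.numeric(obj$weights),
      bias = as.numeric(obj$bias), center = as.numeric(obj$center),
      scale = as.numeric(obj$scale), featureNames = as.character(obj$featureNames),
      cost = as.numeric(obj$cost),
      meta = c(obj$meta, list(version = obj$version)))
}
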