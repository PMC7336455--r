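#' Gene-wise standardization
#'
#' Centers and scales every feature to mean 0 / sd 1 (divisor n - 1) across
#' the samples of a cohort. Constant features cannot be standardized and are
#' dropped with a warning naming them.
#'
#' @param expr matrix or SummarizedExperiment (features x samples).
#' @return standardized numeric matrix.
#' @export
standardizeFeatures <- function(expr) {
  mat <- .asExprMatrix(expr)
  if (ncol(mat) < 2)
    stop("cannot standardize a single-sample matrix", call. = FALSE)
  sds <- .rowSds(mat)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature(s): ",
            paste(utils::head(rownames(mat)[sds == 0], 5), collapse = ", "),
            if (sum(sds == 0) > 5) ", ..." else "", call. = FALSE)
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (mat - rowMeans(mat)) / sds
}

#' Train the random-forest drug-response model
#'
#' The model-training stage: (1) gene-wise standardize the PDX expression of
#' the given (CCE) features; (2) fit a random-forest regression of percent
#' tumor-volume change on expression (500 trees, mtry = max(p/3, 1), the
#' regression defaults of the randomForest implementation) under the given
#' seed; (3) drop features with non-positive permutation importance
#' (%IncMSE on out-of-bag samples); (4) refit on the survivors; (5) record
#' the correlation between predicted and observed activity, both in-sample
#' and out-of-bag. Deterministic given (data, seed).
#'
#' @param pdxExpr PDX expression (matrix or SummarizedExperiment).
#' @param activity percent tumor-volume changes
#'   (data.frame(sample_id, activity) or named numeric vector).
#' @param features candidate features to train on: a character vector, a
#'   \linkS4class{CceaResults} (its selected features are used), or NULL for
#'   all rows.
#' @param nTrees number of trees (default 500).
#' @param mtry variables tried per split; default max(floor(p/3), 1).
#' @param seed integer seed, mandatory for reproducibility.
#' @param importanceType \code{"permutation"} (default, %IncMSE) or
#'   \code{"impurity"} (IncNodePurity).
#' @param skipImportanceFilter keep all features regardless of importance
#'   (used by ablation studies).
#' @param drugLabel free-form label stored in the model.
#' @return a \linkS4class{GemModel}.
#' @examples
#' set.seed(7)
#' expr <- matrix(rnorm(12 * 20), 12, 20,
#'                dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:20)))
#' act <- setNames(40 * expr["g01", ] - 20 * expr["g02", ] + rnorm(20, 0, 4),
#'                 colnames(expr))
#' fit <- trainGem(expr, act, seed = 11)
#' trainingCor(fit)
#' @export
trainGem <- function(pdxExpr, activity, features = NULL, nTrees = 500,
                     mtry = NULL, seed, importanceType = c("permutation",
                     "impurity"), skipImportanceFilter = FALSE,
                     drugLabel = "") {
  importanceType <- match.arg(importanceType)
  if (missing(seed)) stop("a seed is required for reproducible training",
                          call. = FALSE)
  seed <- as.integer(seed)
  mat <- .asExprMatrix(pdxExpr)
  v <- .activityVector(activity)
  al <- .alignSamples(mat, v)
  mat <- al$mat; v <- al$activity
  if (is(features, "CceaResults")) features <- selectedFeatures(features)
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(mat))
    if (length(miss))
      stop("training features absent from PDX expression: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    mat <- mat[features, , drop = FALSE]
  }
  if (ncol(mat) < 4)
    stop("need at least 4 PDX models for training", call. = FALSE)
  if (nrow(mat) < 2)
    stop("need at least 2 features for training", call. = FALSE)

  z <- standardizeFeatures(mat)
  X <- t(z)
  impType <- if (importanceType == "permutation") 1L else 2L

  fitForest <- function(X, seed) {
    p <- ncol(X)
    m <- if (is.null(mtry)) max(floor(p / 3), 1) else min(mtry, p)
    set.seed(seed)
    randomForest(X, v, ntree = nTrees, mtry = m, importance = TRUE)
  }

  rf1 <- fitForest(X, seed)
  imp <- importance(rf1, type = impType)[, 1]
  keep <- names(imp)[imp > 0]
  if (skipImportanceFilter) keep <- colnames(X)
  if (length(keep) == 0)
    stop("no feature has positive variable importance; consider a larger ",
         "PDX panel or skipImportanceFilter = TRUE", call. = FALSE)
  rf2 <- if (length(keep) == ncol(X)) rf1 else fitForest(
    X[, keep, drop = FALSE], seed)
  # A single filter-then-refit pass: the stored importances are the
  # first-pass ones that drove the selection (all positive by construction
  # unless the filter was skipped).
  impStored <- imp[keep]

  predIn <- predict(rf2, X[, keep, drop = FALSE])
  new("GemModel",
      featureIds = keep,
      forest = rf2,
      importances = impStored,
      trainingCor = cor(predIn, v),
      oobCor = cor(rf2$predicted, v),
      hyperparams = list(ntree = nTrees,
                         mtry = if (is.null(mtry))
                           max(floor(length(keep) / 3), 1) else mtry,
                         importance = importanceType,
                         importance_filtered = !skipImportanceFilter),
      seed = seed,
      standardization = "genewise-z",
      drugLabel = drugLabel)
}

#' @describeIn predictScores score a cohort with a trained
#'   \linkS4class{GemModel}.
#'
#' The cohort's expression is standardized gene-wise \emph{within the
#' cohort} (the only platform-shift-invariant transfer of the training
#' recipe), restricted and ordered to the model's features, and pushed
#' through the forest. Model features absent from the cohort (or constant
#' within it) are imputed at the standardized cohort mean, 0, with a
#' warning; more than 20\% missing features is an error.
#'
#' @param minOverlap minimum fraction of model features that must be present
#'   (default 0.8).
#' @export
setMethod("predictScores", "GemModel",
function(model, expr, minOverlap = 0.8) {
  mat <- .asExprMatrix(expr)
  if (ncol(mat) < 3)
    stop("need at least 3 cohort samples for within-cohort standardization",
         call. = FALSE)
  feats <- model@featureIds
  present <- intersect(feats, rownames(mat))
  overlap <- length(present) / length(feats)
  if (overlap < minOverlap)
    stop(sprintf(paste0("only %.1f%% of the %d model features are present ",
                        "in the cohort (need >= %.0f%%)"),
                 100 * overlap, length(feats), 100 * minOverlap),
         call. = FALSE)
  z <- suppressWarnings(standardizeFeatures(mat[present, , drop = FALSE]))
  imputed <- setdiff(feats, rownames(z))
  if (length(imputed))
    warning("imputing ", length(imputed), " missing/constant model ",
            "feature(s) at the standardized cohort mean (0): ",
            paste(utils::head(imputed, 5), collapse = ", "),
            if (length(imputed) > 5) ", ..." else "", call. = FALSE)
  full <- matrix(0, nrow = length(feats), ncol = ncol(mat),
                 dimnames = list(feats, colnames(mat)))
  full[rownames(z), ] <- z
  scores <- predict(model@forest, t(full))
  setNames(as.numeric(scores), colnames(mat))
})

#' Save / load a trained model
#'
#' Serializes the model in a versioned container so a saved model can be
#' reloaded and produce bit-identical predictions.
#'
#' @param model a \linkS4class{GemModel}.
#' @param path file path (RDS).
#' @return \code{path} (save) or the restored \linkS4class{GemModel} (read).
#' @export
saveGemModel <- function(model, path) {
  stopifnot(is(model, "GemModel"))
  saveRDS(list(format = "pdxgem-gem-1",
               package_version = as.character(packageVersion("pdxgem")),
               model = model), path)
  invisible(path)
}

#' @rdname saveGemModel
#' @export
readGemModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pdxgem-gem-1"))
    stop("not a pdxgem model container: ", path, call. = FALSE)
  obj$model
}

#' Write prediction scores as CSV
#'
#' @param scores named numeric vector from \code{\link{predictScores}}.
#' @param path CSV path.
#' @return \code{path} (write) or a named numeric vector (read).
#' @export
writeScores <- function(scores, path) {
  df <- data.frame(sample_id = names(scores),
                   pdxgem_score = .fullPrecision(scores))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df$pdxgem_score), as.character(df$sample_id))
}
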