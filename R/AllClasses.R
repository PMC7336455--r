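#' Biomarker discovery results
#'
#' A \linkS4class{DFrame} with one row per screened feature and columns
#' \code{feature_id}, \code{method} (\code{"t_test"}, \code{"pearson"} or
#' \code{"spearman"}), \code{statistic}, \code{p_value}, \code{q_value}
#' (Benjamini-Hochberg), \code{direction} (sign of the association with tumor
#' growth: +1 means higher expression in growing/resistant tumors),
#' \code{degenerate} (zero-variance flag) and \code{selected}. The selection
#' regime (\code{"fdr"} or \code{"nominal"}), the test used, and the group
#' sizes live in \code{metadata()}.
#'
#' @seealso \code{\link{discoverBiomarkers}}, \code{\link{alphaMode}},
#'   \code{\link{selectedFeatures}}
#' @export
setClass("BiomarkerResults", contains = "DFrame")

setValidity("BiomarkerResults", function(object) {
  need <- c("feature_id", "method", "statistic", "p_value", "q_value",
            "direction", "degenerate", "selected")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$feature_id))
    return("feature_id must be duplicate-free")
  ok <- function(p) all(is.na(p) | (p >= 0 & p <= 1))
  if (!ok(object$p_value) || !ok(object$q_value))
    return("p_value and q_value must lie in [0, 1]")
  if (!is.logical(object$selected)) return("selected must be logical")
  TRUE
})

#' Concordant co-expression analysis results
#'
#' A \linkS4class{DFrame} with one row per candidate biomarker and columns
#' \code{feature_id}, \code{ccec} (concordance co-expression coefficient, in
#' [-1, 1]), \code{p_value}, \code{q_value}, \code{degenerate} and
#' \code{selected}. \code{metadata()} records the number of candidate
#' features, PDX and patient sample sizes, the correlation flavor, and the
#' \code{fdr} and \code{min_ccec} thresholds used for selection.
#'
#' @seealso \code{\link{runCCEA}}
#' @export
setClass("CceaResults", contains = "DFrame")

setValidity("CceaResults", function(object) {
  need <- c("feature_id", "ccec", "p_value", "q_value", "degenerate",
            "selected")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(abs(object$ccec) <= 1 + 1e-12))
    return("ccec must lie in [-1, 1]")
  if (any(object$selected & object$ccec <= 0))
    return("selected features must have ccec > 0")
  TRUE
})

#' Trained multi-gene expression model
#'
#' Holds the random-forest drug-response predictor: the final feature set
#' (all with positive permutation importance), the fitted forest, the
#' standardization recipe identifier, per-feature importances, and training
#' diagnostics. Created by \code{\link{trainGem}}; used by
#' \code{\link{predictScores}}.
#'
#' @slot featureIds character, final model features.
#' @slot forest the fitted \code{randomForest} object.
#' @slot importances named numeric, permutation importance (%IncMSE scale)
#'   of the final features; all positive.
#' @slot trainingCor numeric, Pearson correlation between in-sample refit
#'   predictions and observed activity.
#' @slot oobCor numeric, same using out-of-bag predictions.
#' @slot hyperparams list: \code{ntree}, \code{mtry}, importance type.
#' @slot seed integer seed used for both forest fits.
#' @slot standardization character, the standardization recipe
#'   ("genewise-z" : each feature centered/scaled within its cohort).
#' @slot drugLabel character, free-form label.
#' @export
setClass("GemModel",
  representation(featureIds = "character", forest = "ANY",
                 importances = "numeric", trainingCor = "numeric",
                 oobCor = "numeric", hyperparams = "list", seed = "integer",
                 standardization = "character", drugLabel = "character"))

setValidity("GemModel", function(object) {
  if (length(object@featureIds) < 1) return("empty feature set")
  if (length(object@importances) != length(object@featureIds))
    return("one importance per feature required")
  filtered <- isTRUE(object@hyperparams$importance_filtered)
  if (filtered && !all(object@importances > 0))
    return("final model features must all have positive importance")
  TRUE
})

#' Validation report for one patient cohort
#'
#' Result of \code{\link{validateCohort}}. For binary endpoints the slots
#' \code{auc}, \code{aucCI}, \code{tTestP} and \code{groupMeans} are filled;
#' for survival endpoints \code{survivalTests} holds the log-rank and trend
#' p-values, per-stratum median survival, and Kaplan-Meier curve coordinates.
#'
#' @slot cohortLabel character.
#' @slot outcomeKind "binary_response" or "survival".
#' @slot auc numeric ROC AUC (binary only; NA otherwise).
#' @slot aucCI numeric length-2 bootstrap CI (NA when not requested).
#' @slot tTestP numeric two-sided two-sample t-test p (binary only).
#' @slot groupMeans named numeric mean score per response group.
#' @slot strata character, stratification mode used for survival.
#' @slot survivalTests list (survival only): \code{logrank_p},
#'   \code{trend_p}, \code{median_survival}, \code{n}, \code{events},
#'   \code{curves}.
#' @export
setClass("ValidationReport",
  representation(cohortLabel = "character", outcomeKind = "character",
                 auc = "numeric", aucCI = "numeric", tTestP = "numeric",
                 groupMeans = "numeric", strata = "character",
                 survivalTests = "list"))

setValidity("ValidationReport", function(object) {
  if (!object@outcomeKind %in% c("binary_response", "survival"))
    return("outcomeKind must be 'binary_response' or 'survival'")
  if (object@outcomeKind == "survival" && !all(is.na(object@auc)))
    return("auc is reported only for binary outcomes")
  if (object@outcomeKind == "binary_response" &&
      length(object@survivalTests))
    return("survivalTests are reported only for survival outcomes")
  TRUE
})

setMethod("show", "GemModel", function(object) {
  cat("GemModel (random-forest drug-response predictor)\n")
  if (nzchar(object@drugLabel)) cat("  drug:        ", object@drugLabel, "\n")
  cat("  features:    ", length(object@featureIds),
      "(all positive importance)\n")
  cat("  forest:      ", object@hyperparams$ntree, "trees, mtry =",
      object@hyperparams$mtry, ", seed =", object@seed, "\n")
  cat("  training r:  ", format(object@trainingCor, digits = 3),
      "(in-sample refit),", format(object@oobCor, digits = 3),
      "(out-of-bag)\n")
  cat("  standardization:", object@standardization, "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", object@cohortLabel, "[", object@outcomeKind, "]\n")
  if (object@outcomeKind == "binary_response") {
    cat("  AUC:", format(object@auc, digits = 3))
    if (!all(is.na(object@aucCI)))
      cat(sprintf(" (95%% CI %.3f-%.3f)", object@aucCI[1], object@aucCI[2]))
    cat("\n  t-test p:", format(object@tTestP, digits = 3), "\n")
    cat("  group means:",
        paste(names(object@groupMeans),
              format(object@groupMeans, digits = 3), collapse = ", "), "\n")
  } else {
    st <- object@survivalTests
    cat("  strata:", object@strata, "\n")
    cat("  log-rank p:", format(st$logrank_p, digits = 3),
        " trend p:", format(st$trend_p, digits = 3), "\n")
    cat("  median survival:",
        paste(names(st$median_survival),
              format(st$median_survival, digits = 3), collapse = ", "), "\n")
  }
})
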