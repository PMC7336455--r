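#' Feature identifiers of a result object
#'
#' @param x a \linkS4class{GemModel}, \linkS4class{BiomarkerResults} or
#'   \linkS4class{CceaResults} object.
#' @return character vector of feature identifiers.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname featureIds
#' @export
setMethod("featureIds", "GemModel", function(x) x@featureIds)

#' @rdname featureIds
#' @export
setMethod("featureIds", "BiomarkerResults",
          function(x) as.character(x$feature_id))

#' @rdname featureIds
#' @export
setMethod("featureIds", "CceaResults",
          function(x) as.character(x$feature_id))

#' Selected feature identifiers
#'
#' Features flagged \code{selected} in a discovery or CCEA table.
#'
#' @param x a \linkS4class{BiomarkerResults} or \linkS4class{CceaResults}.
#' @return character vector.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "BiomarkerResults",
          function(x) as.character(x$feature_id[x$selected]))

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "CceaResults",
          function(x) as.character(x$feature_id[x$selected]))

#' Selection regime of a discovery run
#'
#' \code{"fdr"} when features were selected at q < fdr, \code{"nominal"}
#' when the nominal-alpha fallback was triggered.
#'
#' @param x a \linkS4class{BiomarkerResults} object.
#' @return character scalar.
#' @export
setGeneric("alphaMode", function(x) standardGeneric("alphaMode"))

#' @rdname alphaMode
#' @export
setMethod("alphaMode", "BiomarkerResults",
          function(x) metadata(x)$alpha_mode)

#' Variable importance of the final model features
#'
#' @param x a \linkS4class{GemModel}.
#' @return named numeric vector (permutation importance, all positive).
#' @export
setGeneric("featureImportance",
           function(x) standardGeneric("featureImportance"))

#' @rdname featureImportance
#' @export
setMethod("featureImportance", "GemModel", function(x) x@importances)

#' Training-set correlation diagnostics
#'
#' Pearson correlation between predicted and observed percent tumor-volume
#' changes on the training PDX panel.
#'
#' @param x a \linkS4class{GemModel}.
#' @param oob logical; return the out-of-bag correlation instead of the
#'   in-sample refit correlation.
#' @return numeric scalar.
#' @export
setGeneric("trainingCor", function(x, oob = FALSE)
  standardGeneric("trainingCor"))

#' @rdname trainingCor
#' @export
setMethod("trainingCor", "GemModel",
          function(x, oob = FALSE) if (oob) x@oobCor else x@trainingCor)

#' Score a cohort with a trained model
#'
#' @param model a \linkS4class{GemModel}.
#' @param expr expression for the cohort to score (matrix or
#'   SummarizedExperiment, features x samples).
#' @param ... passed to methods.
#' @return named numeric vector of prediction scores (one per sample, on the
#'   percent tumor-volume-change scale; lower = predicted response).
#' @export
setGeneric("predictScores", function(model, expr, ...)
  standardGeneric("predictScores"))
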