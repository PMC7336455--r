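# Internal coercion and validation helpers shared across stages.

.asExprMatrix <- function(x, arg = "expr") {
  if (is(x, "SummarizedExperiment")) x <- assay(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix or a SummarizedExperiment",
         call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(arg, " needs feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(arg, ": duplicate feature identifiers", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(arg, ": duplicate sample identifiers", call. = FALSE)
  if (!all(is.finite(x)))
    stop(arg, ": non-finite expression values", call. = FALSE)
  x
}

# Accept a DrugActivityTable data.frame (sample_id, activity) or a named
# numeric vector; return a named numeric vector.
.activityVector <- function(activity) {
  if (is.data.frame(activity)) {
    if (!all(c("sample_id", "activity") %in% names(activity)))
      stop("activity table needs columns sample_id and activity",
           call. = FALSE)
    v <- setNames(as.numeric(activity$activity),
                  as.character(activity$sample_id))
  } else if (is.numeric(activity) && !is.null(names(activity))) {
    v <- activity
  } else {
    stop("activity must be a data.frame(sample_id, activity) or a named ",
         "numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(v))) stop("duplicate sample_id in activity",
                                    call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite activity values", call. = FALSE)
  v
}

# Align an expression matrix's columns with an activity vector's names.
.alignSamples <- function(mat, activity) {
  common <- intersect(colnames(mat), names(activity))
  if (length(common) < length(names(activity)) ||
      length(common) < ncol(mat))
    warning("expression and activity sample sets differ; using the ",
            length(common), " shared samples", call. = FALSE)
  if (length(common) == 0)
    stop("no shared samples between expression and activity", call. = FALSE)
  list(mat = mat[, common, drop = FALSE], activity = activity[common])
}

.rowSds <- function(x) {
  n <- ncol(x)
  xc <- x - rowMeans(x)
  sqrt(rowSums(xc * xc) / (n - 1))
}

# Numeric formatting that survives a write -> read round trip exactly.
.fullPrecision <- function(x) sprintf("%.17g", x)
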