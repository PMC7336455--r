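#' Read a genes-by-samples expression matrix
#'
#' Reads tab-delimited expression text: first column feature identifiers,
#' header row sample identifiers, one feature per row. The
#' \code{series_matrix_like} dialect additionally ignores metadata lines
#' beginning with \code{"!"} (tolerates GEO series-matrix exports). Values
#' are assumed to be already normalized, log-scale intensities; no
#' renormalization is performed.
#'
#' Duplicate feature identifiers are collapsed to the row with the highest
#' mean expression (the usual probeset-collapse convention), with a warning.
#' Cells parsed as missing (\code{NA}, \code{NaN}, empty) are imputed by the
#' feature's mean across samples when at most \code{maxMissing} of the row is
#' missing; rows exceeding that are dropped with a warning. Any other
#' non-numeric cell is a parse error naming the offending feature and sample.
#'
#' @param path file path.
#' @param dialect \code{"matrix_tsv"} or \code{"series_matrix_like"}.
#' @param maxMissing maximum tolerated fraction of missing cells per feature
#'   before the feature is dropped (default 0.2).
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#'   \code{"exprs"}; \code{metadata()} records the source path and dialect.
#' @seealso \code{\link{writeExpression}}, \code{\link{alignFeatures}}
#' @export
readExpression <- function(path,
                           dialect = c("matrix_tsv", "series_matrix_like"),
                           maxMissing = 0.2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (dialect == "series_matrix_like")
    lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("malformed expression file (need a header and at least one ",
         "feature row): ", path, call. = FALSE)

  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 2)
    stop("malformed header in ", path, ": expected ",
         "feature_id<TAB>sample1<TAB>...", call. = FALSE)
  sampleIds <- header[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in header of ", path, ": ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "),
         call. = FALSE)

  body <- cells[-1]
  nbad <- which(lengths(body) != length(header))
  if (length(nbad))
    stop("row ", nbad[1] + 1, " of ", path, " has ", lengths(body)[nbad[1]],
         " fields, expected ", length(header), call. = FALSE)
  featureIds <- vapply(body, `[[`, character(1), 1L)
  raw <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                nrow = length(body), byrow = TRUE)

  naMark <- raw %in% c("NA", "NaN", "na", "")
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !naMark)
  if (length(bad)) {
    i <- (bad[1] - 1) %% nrow(raw) + 1
    j <- (bad[1] - 1) %/% nrow(raw) + 1
    stop("non-numeric cell '", raw[bad[1]], "' at feature '", featureIds[i],
         "', sample '", sampleIds[j], "' in ", path, call. = FALSE)
  }
  mat <- matrix(vals, nrow = nrow(raw), dimnames = list(featureIds, sampleIds))

  # Missing-value policy: impute the feature mean when sparse, drop otherwise.
  missFrac <- rowMeans(is.na(mat))
  drop <- missFrac > maxMissing
  if (any(drop)) {
    warning("dropping ", sum(drop), " feature(s) with > ",
            round(100 * maxMissing), "% missing values: ",
            paste(utils::head(featureIds[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "", call. = FALSE)
    mat <- mat[!drop, , drop = FALSE]
  }
  if (anyNA(mat)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1]]
  }

  if (anyDuplicated(rownames(mat))) {
    dups <- unique(rownames(mat)[duplicated(rownames(mat))])
    warning("collapsing ", length(dups), " duplicated feature id(s) to the ",
            "highest-mean row: ", paste(utils::head(dups, 5), collapse = ", "),
            if (length(dups) > 5) ", ..." else "", call. = FALSE)
    means <- rowMeans(mat)
    keep <- !logical(nrow(mat))
    for (d in dups) {
      rows <- which(rownames(mat) == d)
      keep[setdiff(rows, rows[which.max(means[rows])])] <- FALSE
    }
    mat <- mat[keep, , drop = FALSE]
  }

  SummarizedExperiment(assays = list(exprs = mat),
                       metadata = list(source = path, dialect = dialect))
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with 17 significant digits so that
#' \code{writeExpression} followed by \code{\link{readExpression}} is the
#' identity on the stored doubles.
#'
#' @param x matrix or SummarizedExperiment (features x samples).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  mat <- .asExprMatrix(x)
  txt <- matrix(.fullPrecision(mat), nrow = nrow(mat))
  lines <- c(paste(c("feature_id", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Percent change in tumor volume
#'
#' Drug activity of a PDX: \code{100 * (post - pre) / pre}. Negative values
#' mean the tumor shrank under treatment (a sensitive model); values at or
#' above zero mean growth (resistant).
#'
#' @param pre pretreatment tumor volume(s), strictly positive.
#' @param post post-treatment tumor volume(s), nonnegative.
#' @return percent change, same length as the inputs.
#' @examples
#' percentTumorVolumeChange(100, 50)  # -50
#' percentTumorVolumeChange(40, 130)  # 225
#' @export
percentTumorVolumeChange <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("pretreatment volume must be finite and > 0", call. = FALSE)
  if (any(!is.finite(post)) || any(post < 0))
    stop("post-treatment volume must be finite and >= 0", call. = FALSE)
  100 * (post - pre) / pre
}

#' Read a drug-activity table
#'
#' CSV with a \code{sample_id} column and either a precomputed
#' \code{activity_pct} column or \code{pre_volume} and \code{post_volume}
#' columns (converted via \code{\link{percentTumorVolumeChange}}).
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{sample_id} and \code{activity}
#'   (percent tumor-volume change).
#' @export
readDrugActivity <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("activity CSV needs a sample_id column: ", path, call. = FALSE)
  if ("activity_pct" %in% names(df)) {
    act <- as.numeric(df$activity_pct)
  } else if (all(c("pre_volume", "post_volume") %in% names(df))) {
    act <- percentTumorVolumeChange(df$pre_volume, df$post_volume)
  } else {
    stop("activity CSV needs either activity_pct or pre_volume+post_volume ",
         "columns: ", path, call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$sample_id), activity = act,
                    stringsAsFactors = FALSE)
  .activityVector(out)  # validates
  out
}

#' Write a drug-activity table
#'
#' @param activity data.frame(sample_id, activity) or named numeric vector.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDrugActivity <- function(activity, path) {
  v <- .activityVector(activity)
  df <- data.frame(sample_id = names(v), activity_pct = .fullPrecision(v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical-outcome table
#'
#' CSV with a \code{sample_id} column and either a binary \code{response}
#' column (1 = responder/pCR, 0 = non-responder/RD) or survival columns
#' \code{time} (nonnegative, months) and \code{event} (0/1).
#'
#' @param path CSV file path.
#' @return data.frame with an \code{outcome_kind} attribute
#'   (\code{"binary_response"} or \code{"survival"}); see
#'   \code{\link{outcomeKind}}.
#' @export
readOutcome <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("outcome CSV needs a sample_id column: ", path, call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if ("response" %in% names(df)) {
    if (!all(df$response %in% c(0, 1)))
      stop("response must be 0/1: ", path, call. = FALSE)
    out <- df[, c("sample_id", "response")]
    attr(out, "outcome_kind") <- "binary_response"
  } else if (all(c("time", "event") %in% names(df))) {
    if (any(!is.finite(df$time)) || any(df$time < 0))
      stop("time must be finite and >= 0: ", path, call. = FALSE)
    if (!all(df$event %in% c(0, 1)))
      stop("event must be 0/1: ", path, call. = FALSE)
    out <- df[, c("sample_id", "time", "event")]
    attr(out, "outcome_kind") <- "survival"
  } else {
    stop("outcome CSV needs either a response column or time+event columns: ",
         path, call. = FALSE)
  }
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id in outcome table: ", path, call. = FALSE)
  out
}

#' Outcome kind of an outcome table
#'
#' @param outcome an outcome data.frame (from \code{\link{readOutcome}} or
#'   built in code with the same columns).
#' @return \code{"binary_response"} or \code{"survival"}.
#' @export
outcomeKind <- function(outcome) {
  k <- attr(outcome, "outcome_kind")
  if (!is.null(k)) return(k)
  if ("response" %in% names(outcome)) return("binary_response")
  if (all(c("time", "event") %in% names(outcome))) return("survival")
  stop("cannot infer outcome kind: need a response column or time+event",
       call. = FALSE)
}

#' Restrict two expression matrices to their shared feature space
#'
#' Both inputs are returned restricted to the intersection of their feature
#' identifiers, rows in identical order (the first matrix's order); sample
#' sets are untouched. Matching is by exact identifier string; cross-platform
#' probeset/gene mapping is the caller's responsibility.
#'
#' @param a,b matrices or SummarizedExperiments (features x samples).
#' @return list with elements \code{a} and \code{b} (same classes as the
#'   inputs' assays: plain matrices).
#' @export
alignFeatures <- function(a, b) {
  ma <- .asExprMatrix(a, "a")
  mb <- .asExprMatrix(b, "b")
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) == 0)
    stop("no shared features between the two matrices", call. = FALSE)
  list(a = ma[common, , drop = FALSE], b = mb[common, , drop = FALSE])
}
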