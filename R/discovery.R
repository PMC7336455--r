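#' Partition PDX models by the sign of drug activity
#'
#' PDXs whose tumors shrank under treatment (activity < 0) are the
#' "shrunken" (sensitive) group; activity at or above zero, including
#' exactly zero, is "grown" (resistant) -- shrinkage must be strict.
#'
#' @param activity data.frame(sample_id, activity) or named numeric vector
#'   of percent tumor-volume changes.
#' @return list with character vectors \code{shrunken} and \code{grown};
#'   together they cover every sample.
#' @export
splitByActivity <- function(activity) {
  v <- .activityVector(activity)
  if (length(v) == 0) stop("empty activity table", call. = FALSE)
  list(shrunken = names(v)[v < 0], grown = names(v)[v >= 0])
}

#' Choose the discovery test from group sizes
#'
#' A two-sample t-test contrasts expression between shrunken- and
#' grown-tumor PDXs when both groups are large enough; with fewer than
#' \code{minGroupSize} models in a group the screen switches to correlating
#' expression with the continuous percent tumor-volume change. The default
#' \code{minGroupSize = 2} admits the t-test for groups as small as two.
#'
#' @param nShrunken,nGrown group sizes.
#' @param minGroupSize minimum per-group size for the t-test branch.
#' @return \code{"t_test"} or \code{"correlation"}.
#' @export
chooseTestMethod <- function(nShrunken, nGrown, minGroupSize = 2) {
  if (nShrunken < 0 || nGrown < 0) stop("negative group size", call. = FALSE)
  if (nShrunken + nGrown < 4)
    stop("need at least 4 PDX models for biomarker discovery",
         call. = FALSE)
  if (min(nShrunken, nGrown) < minGroupSize) "correlation" else "t_test"
}

#' Per-feature two-sample t-test
#'
#' Vectorized unpaired two-sample t-test of every feature between the two
#' sample groups, two-sided. The statistic is oriented as
#' (mean grown - mean shrunken), so a positive statistic means higher
#' expression in growing (resistant) tumors. Pooled-variance Student's t by
#' default; set \code{varEqual = FALSE} for Welch.
#'
#' Features with zero variance in both groups are flagged \code{degenerate}:
#' equal means give statistic 0 / p 1, separated means give an infinite
#' statistic / p 0.
#'
#' @param expr matrix or SummarizedExperiment (features x samples).
#' @param shrunken,grown character vectors of sample ids (each of length
#'   >= 2).
#' @param varEqual pooled variance (TRUE, default) or Welch.
#' @return data.frame(feature_id, statistic, p_value, degenerate).
#' @export
tTestPerFeature <- function(expr, shrunken, grown, varEqual = TRUE) {
  mat <- .asExprMatrix(expr)
  if (!all(c(shrunken, grown) %in% colnames(mat)))
    stop("group sample ids missing from expression matrix", call. = FALSE)
  n1 <- length(shrunken); n2 <- length(grown)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples for a t-test", call. = FALSE)
  x1 <- mat[, shrunken, drop = FALSE]; x2 <- mat[, grown, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- .rowSds(x1)^2; v2 <- .rowSds(x2)^2
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(mat))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m2 - m1) / se
  degenerate <- se == 0
  stat[degenerate & m1 == m2] <- 0
  stat[degenerate & m1 != m2] <- sign(m2 - m1)[degenerate & m1 != m2] * Inf
  p <- 2 * pt(-abs(stat), df)
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  data.frame(feature_id = rownames(mat), statistic = stat, p_value = p,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-feature correlation with drug activity
#'
#' Correlates every feature's expression with the continuous percent
#' tumor-volume change across the PDX panel; Spearman (average ranks for
#' ties) by default, Pearson optional. Two-sided p-values use the standard
#' t approximation \eqn{t = r \sqrt{(n-2)/(1-r^2)}}. Constant features are
#' flagged \code{degenerate} with statistic 0 and p 1.
#'
#' @param expr matrix or SummarizedExperiment (features x samples).
#' @param activity data.frame(sample_id, activity) or named numeric vector.
#' @param flavor \code{"spearman"} (default) or \code{"pearson"}.
#' @return data.frame(feature_id, statistic, p_value, degenerate); the
#'   statistic is the correlation coefficient, positive when higher
#'   expression accompanies tumor growth.
#' @export
correlationPerFeature <- function(expr, activity,
                                  flavor = c("spearman", "pearson")) {
  flavor <- match.arg(flavor)
  mat <- .asExprMatrix(expr)
  v <- .activityVector(activity)
  al <- .alignSamples(mat, v)
  mat <- al$mat; v <- al$activity
  n <- length(v)
  if (n < 4) stop("need at least 4 samples for the correlation screen",
                  call. = FALSE)
  if (sd(v) == 0) stop("activity has zero variance", call. = FALSE)
  if (flavor == "spearman") {
    mat <- t(apply(mat, 1, rank))
    v <- rank(v)
  }
  xc <- mat - rowMeans(mat)
  vc <- v - mean(v)
  denom <- sqrt(rowSums(xc * xc)) * sqrt(sum(vc * vc))
  r <- as.vector(xc %*% vc) / denom
  degenerate <- denom == 0 | !is.finite(r)
  r[degenerate] <- 0
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[abs(r) == 1] <- 0
  p[degenerate] <- 1
  data.frame(feature_id = rownames(mat), statistic = r, p_value = p,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Screen initial drug-sensitivity biomarkers
#'
#' The discovery stage: choose the test (t-test vs correlation) from the
#' shrunken/grown group sizes, run it per feature, adjust p-values by
#' Benjamini-Hochberg, and select features at q < \code{fdr}. When no
#' feature clears the FDR threshold (typical for very small PDX panels) and
#' \code{nominalFallback} is TRUE, selection falls back to the nominal
#' p < \code{nominalAlpha} rule and the result is marked
#' \code{alpha_mode = "nominal"}.
#'
#' @param expr PDX expression (matrix or SummarizedExperiment).
#' @param activity percent tumor-volume changes
#'   (data.frame(sample_id, activity) or named numeric vector).
#' @param method \code{"auto"} (size rule via \code{\link{chooseTestMethod}}),
#'   \code{"t_test"}, \code{"pearson"} or \code{"spearman"}.
#' @param minGroupSize size-rule threshold for \code{method = "auto"}.
#' @param fdr FDR level for selection (default 0.05).
#' @param nominalAlpha nominal type-I level for the fallback (default 0.05).
#' @param nominalFallback enable the fallback (default TRUE).
#' @param corFlavor correlation flavor used when the correlation branch is
#'   chosen automatically (default \code{"spearman"}).
#' @param varEqual pooled-variance t (TRUE, default) or Welch.
#' @return a \linkS4class{BiomarkerResults} object, all screened features
#'   retained in input row order.
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(50 * 12), 50, 12,
#'                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
#' act <- setNames(rnorm(12, 0, 30), colnames(expr))
#' expr["g01", ] <- act / 20 + rnorm(12, 0, 0.1)  # planted signal
#' res <- discoverBiomarkers(expr, act)
#' selectedFeatures(res)
#' @export
discoverBiomarkers <- function(expr, activity, method = "auto",
                               minGroupSize = 2, fdr = 0.05,
                               nominalAlpha = 0.05, nominalFallback = TRUE,
                               corFlavor = c("spearman", "pearson"),
                               varEqual = TRUE) {
  corFlavor <- match.arg(corFlavor)
  mat <- .asExprMatrix(expr)
  v <- .activityVector(activity)
  al <- .alignSamples(mat, v)
  mat <- al$mat; v <- al$activity
  groups <- splitByActivity(v)
  if (method == "auto") {
    method <- chooseTestMethod(length(groups$shrunken),
                               length(groups$grown), minGroupSize)
    if (method == "correlation") method <- corFlavor
  }
  method <- match.arg(method, c("t_test", "pearson", "spearman"))
  res <- if (method == "t_test") {
    tTestPerFeature(mat, groups$shrunken, groups$grown, varEqual = varEqual)
  } else {
    correlationPerFeature(mat, v, flavor = method)
  }
  q <- p.adjust(res$p_value, method = "BH")
  selected <- q < fdr & !res$degenerate
  mode <- "fdr"
  if (!any(selected) && nominalFallback) {
    selected <- res$p_value < nominalAlpha & !res$degenerate
    mode <- "nominal"
  }
  d <- DataFrame(feature_id = res$feature_id, method = method,
                 statistic = res$statistic, p_value = res$p_value,
                 q_value = q, direction = sign(res$statistic),
                 degenerate = res$degenerate, selected = selected)
  metadata(d) <- list(alpha_mode = mode, method = method, fdr = fdr,
                      nominal_alpha = nominalAlpha,
                      n_shrunken = length(groups$shrunken),
                      n_grown = length(groups$grown))
  new("BiomarkerResults", d)
}

#' Write / read a biomarker table as CSV
#'
#' @param x a \linkS4class{BiomarkerResults} object.
#' @param path CSV path.
#' @return \code{path} (write) or a \linkS4class{BiomarkerResults} (read),
#'   with \code{alpha_mode} restored from the CSV column.
#' @export
writeBiomarkerTable <- function(x, path) {
  stopifnot(is(x, "BiomarkerResults"))
  df <- as.data.frame(x)
  df$alpha_mode <- alphaMode(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBiomarkerTable
#' @export
readBiomarkerTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mode <- unique(df$alpha_mode)
  d <- DataFrame(df[setdiff(names(df), "alpha_mode")])
  d$selected <- as.logical(d$selected)
  d$degenerate <- as.logical(d$degenerate)
  metadata(d) <- list(alpha_mode = mode, method = unique(df$method))
  new("BiomarkerResults", d)
}
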