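#' Pairwise feature-feature correlation matrix
#'
#' Correlations between all pairs of the given features across the samples of
#' one cohort; the building block of concordant co-expression analysis.
#' Constant (zero-variance) features produce zero rows/columns and are
#' flagged in the \code{"degenerate"} attribute so downstream selection can
#' exclude them; the diagonal is exactly 1.
#'
#' @param expr matrix or SummarizedExperiment (features x samples).
#' @param features optional character vector restricting (and ordering) the
#'   features; default all rows.
#' @param flavor \code{"pearson"} (default) or \code{"spearman"}.
#' @return symmetric numeric matrix with unit diagonal and a
#'   \code{"degenerate"} character attribute naming constant features.
#' @export
pairwiseCorrelations <- function(expr, features = NULL,
                                 flavor = c("pearson", "spearman")) {
  flavor <- match.arg(flavor)
  mat <- .asExprMatrix(expr)
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(mat))
    if (length(miss))
      stop("features absent from expression matrix: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    mat <- mat[features, , drop = FALSE]
  }
  if (ncol(mat) < 3)
    stop("need at least 3 samples to estimate pairwise correlations",
         call. = FALSE)
  if (nrow(mat) < 2)
    stop("need at least 2 features", call. = FALSE)
  C <- suppressWarnings(cor(t(mat), method = flavor))
  degenerate <- rownames(mat)[.rowSds(mat) == 0]
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  attr(C, "degenerate") <- degenerate
  C
}

# Lin's concordance correlation between two paired vectors, with n-1
# divisors throughout: 2*s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2).
# Degenerate case (both vectors constant with equal means) returns 0.
.linCCC <- function(u, v) {
  mu <- mean(u); mv <- mean(v)
  num <- 2 * sum((u - mu) * (v - mv))
  den <- sum((u - mu)^2) + sum((v - mv)^2) + length(u) * (mu - mv)^2
  if (den == 0) 0 else num / den
}

#' Concordance co-expression coefficient of one feature
#'
#' For candidate feature \code{g}, take its vector of correlations with the
#' other n-1 candidates in the PDX panel (column \code{g} of \code{U}, off
#' diagonal) and the matching vector in the patient cohort (column of
#' \code{V}), and return Lin's concordance correlation coefficient between
#' the two vectors:
#' \deqn{c(g) = \frac{2\sum_{k\neq g}(U_{kg}-\bar U_{.g})(V_{kg}-\bar V_{.g})}
#'   {\sum_{k\neq g}(U_{kg}-\bar U_{.g})^2 + \sum_{k\neq g}(V_{kg}-\bar V_{.g})^2
#'    + (n-1)(\bar U_{.g}-\bar V_{.g})^2}}
#' A value of 1 means the feature's co-expression neighborhood is perfectly
#' preserved between the two systems; values near 0 mean the wiring is
#' unrelated. When both correlation vectors are constant with equal means the
#' coefficient is undefined and 0 is returned (callers flag such features as
#' degenerate and never select them).
#'
#' @param U,V symmetric n x n correlation matrices over the same features in
#'   identical order (PDX and patient cohorts).
#' @param g feature index or name.
#' @return numeric scalar in [-1, 1].
#' @seealso \code{\link{runCCEA}}, \code{\link{ccecPvalue}}
#' @export
ccec <- function(U, V, g) {
  if (!is.matrix(U) || !is.matrix(V) || !all(dim(U) == dim(V)))
    stop("U and V must be correlation matrices of identical dimension",
         call. = FALSE)
  n <- nrow(U)
  if (n < 3)
    stop("need at least 3 features (2 off-diagonal partners) for the CCEC",
         call. = FALSE)
  if (is.character(g)) g <- match(g, rownames(U))
  if (is.na(g) || g < 1 || g > n) stop("feature index out of range",
                                       call. = FALSE)
  .linCCC(U[-g, g], V[-g, g])
}

#' Two-sided p-value for a concordance coefficient
#'
#' Tests H0: CCC = 0 with the Fisher-type inverse-hyperbolic-tangent
#' transform: \eqn{Z = \mathrm{atanh}(c)} with standard error
#' \eqn{1/\sqrt{m-2}} against a normal reference, where \code{m} is the
#' number of paired off-diagonal entries (n - 1 candidates). At |c| = 1 the
#' p-value is 0.
#'
#' @param c concordance coefficient(s) in [-1, 1].
#' @param m number of paired entries per coefficient (>= 3; scalar or
#'   vector).
#' @return two-sided p-value(s).
#' @export
ccecPvalue <- function(c, m) {
  if (any(m < 3)) stop("need m >= 3 paired entries for the CCEC p-value",
                       call. = FALSE)
  if (any(abs(c) > 1 + 1e-12)) stop("|ccec| must be <= 1", call. = FALSE)
  c <- pmin(1, pmax(-1, c))
  p <- 2 * pnorm(-abs(atanh(c)) * sqrt(m - 2))
  p[abs(c) == 1] <- 0
  p
}

#' Concordant co-expression analysis
#'
#' Builds the two candidate-by-candidate correlation matrices (U on the PDX
#' panel, V on the patient reference cohort), computes each candidate's
#' concordance co-expression coefficient, tests it (atanh z-test by default,
#' or a feature-label permutation null), adjusts by Benjamini-Hochberg, and
#' selects candidates with q < \code{fdr} and CCEC > \code{minCcec}. The
#' default \code{minCcec = 0} selects on significance alone; a stricter
#' absolute threshold (e.g. 0.3) yields a sparser, more concordant signature.
#'
#' @param pdxExpr,patientExpr expression (matrix or SummarizedExperiment);
#'   features are matched by exact identifier.
#' @param biomarkers a \linkS4class{BiomarkerResults} (its selected features
#'   are the candidates) or a character vector of candidate feature ids.
#' @param minCcec minimum CCEC for selection (default 0; must be >= 0 so
#'   selected features are positively concordant).
#' @param fdr FDR level (default 0.05).
#' @param flavor correlation flavor for U and V (default \code{"pearson"}).
#' @param pMethod \code{"ztransform"} (default) or \code{"permutation"}
#'   (permutes the other features' labels within V).
#' @param nPerm permutations when \code{pMethod = "permutation"}.
#' @param seed seed for the permutation null.
#' @return a \linkS4class{CceaResults} object.
#' @export
runCCEA <- function(pdxExpr, patientExpr, biomarkers, minCcec = 0,
                    fdr = 0.05, flavor = c("pearson", "spearman"),
                    pMethod = c("ztransform", "permutation"),
                    nPerm = 1000, seed = NULL) {
  flavor <- match.arg(flavor)
  pMethod <- match.arg(pMethod)
  if (minCcec < 0) stop("minCcec must be >= 0", call. = FALSE)
  cand <- if (is(biomarkers, "BiomarkerResults"))
    selectedFeatures(biomarkers) else as.character(biomarkers)
  al <- alignFeatures(pdxExpr, patientExpr)
  cand <- cand[cand %in% rownames(al$a)]
  n <- length(cand)
  if (n < 4)
    stop("need at least 4 candidate biomarkers shared by both cohorts ",
         "(got ", n, "): the correlation vectors are too short",
         call. = FALSE)
  U <- pairwiseCorrelations(al$a, cand, flavor = flavor)
  V <- pairwiseCorrelations(al$b, cand, flavor = flavor)
  degenerate <- cand %in% c(attr(U, "degenerate"), attr(V, "degenerate"))
  cc <- vapply(seq_len(n), function(g) ccec(U, V, g), numeric(1))
  m <- n - 1
  if (pMethod == "ztransform") {
    p <- ccecPvalue(cc, m)
  } else {
    if (!is.null(seed)) set.seed(seed)
    p <- vapply(seq_len(n), function(g) {
      u <- U[-g, g]; v <- V[-g, g]
      null <- vapply(seq_len(nPerm),
                     function(b) .linCCC(u, v[sample.int(m)]), numeric(1))
      (1 + sum(abs(null) >= abs(cc[g]))) / (1 + nPerm)
    }, numeric(1))
  }
  cc[degenerate] <- 0
  p[degenerate] <- 1
  q <- p.adjust(p, method = "BH")
  selected <- q < fdr & cc > minCcec & cc > 0 & !degenerate
  d <- DataFrame(feature_id = cand, ccec = cc, p_value = p, q_value = q,
                 degenerate = degenerate, selected = selected)
  metadata(d) <- list(n_features = n, pdx_n = ncol(al$a),
                      patient_n = ncol(al$b), flavor = flavor,
                      min_ccec = minCcec, fdr = fdr, p_method = pMethod,
                      n_selected = sum(selected),
                      ccec_range = range(cc), ccec_median = median(cc))
  new("CceaResults", d)
}

#' Write / read a CCEA table as CSV
#'
#' @param x a \linkS4class{CceaResults} object.
#' @param path CSV path.
#' @return \code{path} (write) or a \linkS4class{CceaResults} (read).
#' @export
writeCceaTable <- function(x, path) {
  stopifnot(is(x, "CceaResults"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCceaTable
#' @export
readCceaTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  d <- DataFrame(df)
  d$selected <- as.logical(d$selected)
  d$degenerate <- as.logical(d$degenerate)
  new("CceaResults", d)
}
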