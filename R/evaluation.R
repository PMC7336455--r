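# Merge a score vector with an outcome table by sample id.
.mergeScoresOutcome <- function(scores, outcome) {
  if (!is.numeric(scores) || is.null(names(scores)))
    stop("scores must be a named numeric vector", call. = FALSE)
  common <- intersect(names(scores), outcome$sample_id)
  if (length(common) == 0)
    stop("no shared samples between scores and outcome", call. = FALSE)
  out <- outcome[match(common, outcome$sample_id), , drop = FALSE]
  out$score <- scores[common]
  attr(out, "outcome_kind") <- outcomeKind(outcome)
  out
}

#' Compare prediction scores between response groups
#'
#' Two-sided two-sample t-test of PDXGEM scores between responders
#' (response = 1) and non-responders (response = 0).
#'
#' @param scores named numeric vector of prediction scores.
#' @param outcome binary outcome table (columns sample_id, response).
#' @param varEqual pooled variance (TRUE, default) or Welch.
#' @return list with \code{statistic}, \code{p_value} and
#'   \code{group_means} (named: responder, nonresponder).
#' @export
compareScoreGroups <- function(scores, outcome, varEqual = TRUE) {
  df <- .mergeScoresOutcome(scores, outcome)
  if (outcomeKind(df) != "binary_response")
    stop("compareScoreGroups needs a binary response outcome", call. = FALSE)
  resp <- df$score[df$response == 1]
  non <- df$score[df$response == 0]
  if (length(resp) < 2 || length(non) < 2)
    stop("each response group needs at least 2 samples", call. = FALSE)
  tt <- t.test(resp, non, var.equal = varEqual)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       group_means = c(responder = mean(resp), nonresponder = mean(non)))
}

#' ROC AUC of prediction scores
#'
#' Rank-based (Mann-Whitney) area under the ROC curve for discriminating
#' responders from non-responders, with half credit for ties. With
#' \code{responderLow = TRUE} (the pipeline's convention: scores live on
#' the tumor-volume-change scale, so lower scores predict response) the
#' AUC is the probability that a responder scores \emph{lower} than a
#' non-responder. An optional stratified bootstrap confidence interval
#' resamples within each response class.
#'
#' @param scores named numeric vector.
#' @param outcome binary outcome table (columns sample_id, response).
#' @param responderLow orientation; default TRUE.
#' @param ci compute a bootstrap CI (default FALSE).
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap (required when \code{ci = TRUE}).
#' @param conf confidence level (default 0.95).
#' @return list with \code{auc}, \code{n_responder}, \code{n_nonresponder},
#'   and (when requested) \code{ci_lower}, \code{ci_upper}.
#' @export
aucScore <- function(scores, outcome, responderLow = TRUE, ci = FALSE,
                     nBoot = 2000, seed = NULL, conf = 0.95) {
  df <- .mergeScoresOutcome(scores, outcome)
  if (outcomeKind(df) != "binary_response")
    stop("aucScore needs a binary response outcome", call. = FALSE)
  s <- if (responderLow) -df$score else df$score
  y <- df$response
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both response classes must be present", call. = FALSE)
  rankAuc <- function(s, y) {
    r <- rank(s)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out <- list(auc = rankAuc(s, y), n_responder = n1, n_nonresponder = n0)
  if (ci) {
    if (is.null(seed)) stop("the bootstrap CI requires a seed", call. = FALSE)
    set.seed(as.integer(seed))
    iPos <- which(y == 1); iNeg <- which(y == 0)
    boots <- vapply(seq_len(nBoot), function(b) {
      idx <- c(sample(iPos, n1, replace = TRUE),
               sample(iNeg, n0, replace = TRUE))
      rankAuc(s[idx], y[idx])
    }, numeric(1))
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    out$ci_lower <- qs[1]; out$ci_upper <- qs[2]
  }
  out
}

#' Stratify samples by prediction score
#'
#' \code{median_split}: samples at or below the median score are "low"
#' (ties at the median go to "low"); the rest are "high".
#' \code{tertiles}: empirical 1/3 and 2/3 quantiles split samples into
#' "low" / "intermediate" / "high", balanced within one sample where ties
#' permit.
#'
#' @param scores named numeric vector.
#' @param mode \code{"median_split"} (default) or \code{"tertiles"}.
#' @return named ordered factor of stratum labels, monotone in score.
#' @export
stratifyScores <- function(scores, mode = c("median_split", "tertiles")) {
  mode <- match.arg(mode)
  if (!is.numeric(scores) || is.null(names(scores)))
    stop("scores must be a named numeric vector", call. = FALSE)
  if (length(unique(scores)) < 2)
    stop("all scores identical: no stratification possible", call. = FALSE)
  if (mode == "median_split") {
    if (length(scores) < 2) stop("need at least 2 samples", call. = FALSE)
    lab <- ifelse(scores <= median(scores), "low", "high")
    f <- factor(lab, levels = c("low", "high"), ordered = TRUE)
  } else {
    if (length(scores) < 3) stop("need at least 3 samples for tertiles",
                                 call. = FALSE)
    qs <- quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
    lab <- ifelse(scores <= qs[1], "low",
                  ifelse(scores <= qs[2], "intermediate", "high"))
    if (length(unique(lab)) < 2)
      stop("score ties are too heavy for tertile stratification",
           call. = FALSE)
    f <- factor(lab, levels = c("low", "intermediate", "high"),
                ordered = TRUE)
    f <- droplevels(f)
  }
  setNames(f, names(scores))
}

#' Compare survival between score strata
#'
#' Kaplan-Meier analysis of the strata: per-stratum median survival and
#' curve coordinates, the log-rank test across strata, and a trend test for
#' ordered strata (the log-rank linear-trend construction: the stratum
#' (O - E) vector contrasted with ordered scores 1, 2, ... against its
#' log-rank covariance; for two strata it reduces to the ordinary log-rank
#' test).
#'
#' @param strata named factor of stratum labels (from
#'   \code{\link{stratifyScores}}).
#' @param outcome survival outcome table (columns sample_id, time, event).
#' @return list with \code{logrank_p}, \code{trend_p}, \code{logrank_chisq},
#'   \code{median_survival} (named per stratum), \code{n}, \code{events},
#'   and \code{curves} (data.frame stratum/time/surv for plotting).
#' @export
survivalCompare <- function(strata, outcome) {
  if (outcomeKind(outcome) != "survival")
    stop("survivalCompare needs a survival outcome", call. = FALSE)
  common <- intersect(names(strata), outcome$sample_id)
  if (length(common) == 0)
    stop("no shared samples between strata and outcome", call. = FALSE)
  df <- outcome[match(common, outcome$sample_id), ]
  df$stratum <- droplevels(factor(strata[common],
                                  levels = levels(strata), ordered = TRUE))
  if (nlevels(df$stratum) < 2)
    stop("need at least 2 strata", call. = FALSE)
  if (sum(df$event) == 0)
    stop("no events observed: survival comparison impossible", call. = FALSE)
  sdiff <- survdiff(Surv(time, event) ~ stratum, data = df)
  k <- length(sdiff$n)
  logrank_p <- pchisq(sdiff$chisq, df = k - 1, lower.tail = FALSE)
  # trend: linear contrast of the (O - E) vector with ordered scores
  w <- seq_len(k)
  oe <- sdiff$obs - sdiff$exp
  Vw <- as.numeric(t(w) %*% sdiff$var %*% w)
  trend_chisq <- if (Vw > 0) as.numeric(sum(w * oe))^2 / Vw else 0
  trend_p <- pchisq(trend_chisq, df = 1, lower.tail = FALSE)

  fit <- survfit(Surv(time, event) ~ stratum, data = df)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))  # defensive; k >= 2 here
  med <- setNames(tab[, "median"],
                  sub("^stratum=", "", rownames(tab)))
  curves <- data.frame(
    stratum = rep(sub("^stratum=", "", names(fit$strata)), fit$strata),
    time = fit$time, surv = fit$surv, stringsAsFactors = FALSE)
  list(logrank_p = logrank_p, trend_p = trend_p,
       logrank_chisq = unname(sdiff$chisq),
       median_survival = med,
       n = setNames(as.numeric(sdiff$n), names(med)),
       events = setNames(as.numeric(sdiff$obs), names(med)),
       curves = curves)
}

#' Association of continuous scores with survival (Cox pass-through)
#'
#' Thin wrapper around \code{survival::coxph} relating the raw continuous
#' prediction score (per unit) to survival, optionally adjusted for
#' covariates supplied as extra columns of the outcome table.
#'
#' @param scores named numeric vector.
#' @param outcome survival outcome table; extra columns named in
#'   \code{covariates} are used as adjusters.
#' @param covariates character vector of covariate column names.
#' @return list with \code{hr}, \code{ci_lower}, \code{ci_upper},
#'   \code{p_value}, and the fitted \code{coxph} object as \code{fit}.
#' @export
coxScoreAssociation <- function(scores, outcome, covariates = character()) {
  df <- .mergeScoresOutcome(scores, outcome)
  if (outcomeKind(df) != "survival")
    stop("coxScoreAssociation needs a survival outcome", call. = FALSE)
  rhs <- paste(c("score", covariates), collapse = " + ")
  fit <- coxph(stats::as.formula(paste("Surv(time, event) ~", rhs)),
               data = df)
  s <- summary(fit)
  list(hr = unname(s$conf.int["score", "exp(coef)"]),
       ci_lower = unname(s$conf.int["score", "lower .95"]),
       ci_upper = unname(s$conf.int["score", "upper .95"]),
       p_value = unname(s$coefficients["score", "Pr(>|z|)"]),
       fit = fit)
}

#' Validate prediction scores against one cohort's outcomes
#'
#' Dispatches on the outcome kind. Binary response: two-sample t-test of
#' scores between groups plus rank AUC (with a seeded stratified bootstrap
#' CI when a seed is given). Survival: score stratification (median split or
#' tertiles), Kaplan-Meier medians and curves, log-rank and trend tests.
#'
#' @param scores named numeric vector of prediction scores.
#' @param outcome outcome table from \code{\link{readOutcome}} or built in
#'   code.
#' @param responderLow orientation of the AUC (default TRUE: lower score
#'   predicts response).
#' @param strata stratification for survival outcomes
#'   (\code{"median_split"} or \code{"tertiles"}).
#' @param label cohort label carried into the report.
#' @param seed seed for the AUC bootstrap CI (NULL skips the CI).
#' @param nBoot bootstrap resamples for the CI.
#' @return a \linkS4class{ValidationReport}.
#' @export
validateCohort <- function(scores, outcome, responderLow = TRUE,
                           strata = c("median_split", "tertiles"),
                           label = "", seed = NULL, nBoot = 2000) {
  strata <- match.arg(strata)
  kind <- outcomeKind(outcome)
  if (kind == "binary_response") {
    tt <- compareScoreGroups(scores, outcome)
    a <- aucScore(scores, outcome, responderLow = responderLow,
                  ci = !is.null(seed), nBoot = nBoot, seed = seed)
    new("ValidationReport", cohortLabel = label,
        outcomeKind = kind, auc = a$auc,
        aucCI = if (is.null(seed)) c(NA_real_, NA_real_)
                else c(a$ci_lower, a$ci_upper),
        tTestP = tt$p_value, groupMeans = tt$group_means,
        strata = NA_character_, survivalTests = list())
  } else {
    st <- stratifyScores(scores, mode = strata)
    sv <- survivalCompare(st, outcome)
    new("ValidationReport", cohortLabel = label, outcomeKind = kind,
        auc = NA_real_, aucCI = c(NA_real_, NA_real_), tTestP = NA_real_,
        groupMeans = numeric(), strata = strata, survivalTests = sv)
  }
}

#' Serialize a validation report to JSON
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  stopifnot(is(report, "ValidationReport"))
  x <- list(cohort_label = report@cohortLabel,
            outcome_kind = report@outcomeKind)
  if (report@outcomeKind == "binary_response") {
    x$auc <- report@auc
    if (!all(is.na(report@aucCI))) x$auc_ci <- report@aucCI
    x$t_test_p <- report@tTestP
    x$group_means <- as.list(report@groupMeans)
  } else {
    x$strata_definition <- report@strata
    st <- report@survivalTests
    x$survival_tests <- list(logrank_p = st$logrank_p,
                             trend_p = st$trend_p,
                             median_survival = as.list(st$median_survival))
    x$km_curves <- st$curves
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}
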