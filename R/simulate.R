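#' Configuration for a synthetic PDX/patient study
#'
#' Defines the generative conditions of a simulated drug study: a PDX panel
#' with measured drug activity, a patient co-expression reference cohort,
#' and a validation cohort with clinical outcomes. Sensitivity features are
#' organized into co-expression modules (aligned loadings, within-module
#' correlation \code{blockCorrelation}): the first \code{nConcordant}
#' features form modules shared by the PDX and patient systems, while the
#' remaining sensitivity features form PDX-only modules whose patient-side
#' wiring is destroyed (they are iid in patient cohorts) -- the
#' engraftment-rewiring phenomenon the concordance filter is designed to
#' detect. Null features are iid everywhere. Activity is a linear
#' combination of the sensitivity features' expression scaled by
#' \code{effectSize} plus Gaussian noise, in percent tumor-volume-change
#' units.
#'
#' @param nFeatures total number of features (default 1000).
#' @param nSensitivity features truly associated with activity (default 50).
#' @param nConcordant sensitivity features whose co-expression is shared
#'   with patients (default 30; must be <= nSensitivity).
#' @param nPdx PDX panel size (default 13, a typical small panel).
#' @param nPatientsRef patient reference cohort size (default 100).
#' @param nPatientsVal validation cohort size (default 100).
#' @param effectSize activity-model coefficient scale (default 1).
#' @param noiseSd sd of the activity noise (default 0.5).
#' @param blockCorrelation within-module correlation (default 0.7, in
#'   (0, 1)).
#' @param moduleSize maximum features per co-expression module (default 50:
#'   the default sensitivity set is one module).
#' @param seed integer seed; all randomness derives from it (Mersenne
#'   Twister).
#' @return validated config list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nFeatures = 1000, nSensitivity = 50, nConcordant = 30,
                      nPdx = 13, nPatientsRef = 100, nPatientsVal = 100,
                      effectSize = 1, noiseSd = 0.5, blockCorrelation = 0.7,
                      moduleSize = 50, seed = 1) {
  cfg <- list(nFeatures = nFeatures, nSensitivity = nSensitivity,
              nConcordant = nConcordant, nPdx = nPdx,
              nPatientsRef = nPatientsRef, nPatientsVal = nPatientsVal,
              effectSize = effectSize, noiseSd = noiseSd,
              blockCorrelation = blockCorrelation, moduleSize = moduleSize,
              seed = as.integer(seed), generator = "Mersenne-Twister")
  counts <- unlist(cfg[c("nFeatures", "nSensitivity", "nConcordant", "nPdx",
                         "nPatientsRef", "nPatientsVal")])
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (nConcordant > nSensitivity || nSensitivity > nFeatures)
    stop("need nConcordant <= nSensitivity <= nFeatures", call. = FALSE)
  if (blockCorrelation < 0 || blockCorrelation >= 1)
    stop("blockCorrelation must lie in [0, 1)", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (moduleSize < 1) stop("moduleSize must be >= 1", call. = FALSE)
  class(cfg) <- "SimConfig"
  cfg
}

# One cohort draw under the factor model. modules: list of integer feature
# index vectors; preserve: features that keep their module loading in this
# cohort (others in a module are drawn iid). Returns the signal matrix
# (features x samples, unit-variance entries, no baseline).
.drawCohort <- function(n, nFeatures, modules, preserve, rho) {
  x <- matrix(rnorm(nFeatures * n), nFeatures, n)
  if (rho > 0) {
    for (m in modules) {
      keep <- intersect(m, preserve)
      if (length(keep) >= 1) {
        z <- rnorm(n)
        x[keep, ] <- sqrt(rho) * matrix(z, length(keep), n, byrow = TRUE) +
          sqrt(1 - rho) * x[keep, , drop = FALSE]
      }
    }
  }
  x
}

#' Simulate a full PDX-to-patient drug study
#'
#' Generates, reproducibly from the config seed: a PDX expression panel with
#' percent tumor-volume changes, a patient reference cohort sharing the
#' concordant features' co-expression modules, and a validation cohort with
#' a latent drug response (same linear rule restricted to the concordant
#' features), a binary endpoint (responder = latent response at or below
#' the cohort median, i.e. predicted shrinkage), and an exponential survival
#' endpoint whose hazard increases with the latent response, censored
#' administratively at 60 months. Expression values carry per-feature
#' baselines drawn once and shared across cohorts, mimicking log-scale
#' array intensities.
#'
#' @param config a \code{\link{simConfig}} object (or arguments for one).
#' @return list with elements \code{pdx} (SummarizedExperiment),
#'   \code{activity} (data.frame sample_id/activity), \code{patientRef},
#'   \code{patientVal} (SummarizedExperiments), \code{outcomeBinary},
#'   \code{outcomeSurvival} (outcome data.frames), and \code{truth}
#'   (sensitivity/concordant feature ids, coefficients, latent response,
#'   config).
#' @examples
#' sim <- simulateStudy(simConfig(nFeatures = 100, nSensitivity = 10,
#'                                nConcordant = 6, nPdx = 10, seed = 42))
#' dim(SummarizedExperiment::assay(sim$pdx))
#' @export
simulateStudy <- function(config = simConfig()) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  set.seed(config$seed)
  nF <- config$nFeatures
  featIds <- sprintf("g%05d", seq_len(nF))
  sensIdx <- seq_len(config$nSensitivity)
  concIdx <- seq_len(config$nConcordant)
  nonconcIdx <- setdiff(sensIdx, concIdx)
  # Concordant features form modules that exist in both systems;
  # non-concordant sensitivity features form separate PDX-only modules
  # (their patient-side co-expression is destroyed by engraftment-style
  # rewiring). Nulls are iid everywhere.
  chunk <- function(idx) if (length(idx))
    split(idx, ceiling(seq_along(idx) / config$moduleSize)) else list()
  modules <- c(chunk(concIdx), chunk(nonconcIdx))
  # aligned within-module signs; modules alternate sign
  beta <- numeric(nF)
  for (i in seq_along(modules))
    beta[modules[[i]]] <- config$effectSize * (-1)^(i - 1)
  baseline <- runif(nF, 5, 12)

  asSE <- function(x, prefix) {
    colnames(x) <- sprintf("%s%03d", prefix, seq_len(ncol(x)))
    rownames(x) <- featIds
    SummarizedExperiment(assays = list(exprs = x + baseline))
  }
  rho <- config$blockCorrelation

  # PDX panel: the full sensitivity module structure is present.
  xPdx <- .drawCohort(config$nPdx, nF, modules, sensIdx, rho)
  activity <- as.numeric(crossprod(xPdx, beta)) +
    rnorm(config$nPdx, 0, config$noiseSd)
  pdx <- asSE(xPdx, "PDX")

  # Patient cohorts: only the concordant subset keeps the module wiring.
  xRef <- .drawCohort(config$nPatientsRef, nF, modules, concIdx, rho)
  ref <- asSE(xRef, "REF")
  xVal <- .drawCohort(config$nPatientsVal, nF, modules, concIdx, rho)
  val <- asSE(xVal, "VAL")

  # Latent response of validation patients: same rule on concordant
  # features only; pure noise when nothing is concordant.
  latent <- if (config$nConcordant > 0)
    as.numeric(crossprod(xVal[concIdx, , drop = FALSE], beta[concIdx]))
  else rnorm(config$nPatientsVal)
  latent <- latent + rnorm(config$nPatientsVal, 0, config$noiseSd)
  valIds <- colnames(val)

  response <- as.integer(latent <= median(latent))
  outcomeBinary <- data.frame(sample_id = valIds, response = response,
                              stringsAsFactors = FALSE)
  attr(outcomeBinary, "outcome_kind") <- "binary_response"

  zl <- if (sd(latent) > 0) (latent - mean(latent)) / sd(latent) else latent
  rawTime <- rexp(length(latent), rate = 0.08 * exp(0.8 * zl))
  event <- as.integer(rawTime <= 60)
  outcomeSurvival <- data.frame(sample_id = valIds,
                                time = pmin(rawTime, 60), event = event,
                                stringsAsFactors = FALSE)
  attr(outcomeSurvival, "outcome_kind") <- "survival"

  truth <- list(sensitivity_feature_ids = featIds[sensIdx],
                concordant_feature_ids = featIds[concIdx],
                coefficients = setNames(beta[sensIdx], featIds[sensIdx]),
                latent_response = setNames(latent, valIds),
                modules = lapply(modules, function(m) featIds[m]),
                config = config)

  list(pdx = pdx,
       activity = data.frame(sample_id = colnames(pdx), activity = activity,
                             stringsAsFactors = FALSE),
       patientRef = ref, patientVal = val,
       outcomeBinary = outcomeBinary, outcomeSurvival = outcomeSurvival,
       truth = truth)
}

#' Check the realized co-expression of a simulated cohort
#'
#' Mean off-diagonal correlation among the concordant members of each
#' module, against the configured \code{blockCorrelation} target.
#'
#' @param expr a simulated cohort (SummarizedExperiment or matrix).
#' @param truth the \code{truth} element of \code{\link{simulateStudy}}.
#' @return list with \code{mean_within_block}, \code{per_module}, and
#'   \code{target}.
#' @export
empiricalCorrelationCheck <- function(expr, truth) {
  mat <- .asExprMatrix(expr)
  target <- truth$config$blockCorrelation
  conc <- truth$concordant_feature_ids
  per <- vapply(truth$modules, function(m) {
    m <- intersect(m, conc)
    if (length(m) < 2) return(NA_real_)
    C <- cor(t(mat[m, , drop = FALSE]))
    mean(C[upper.tri(C)])
  }, numeric(1))
  per <- per[!is.na(per)]
  list(mean_within_block = if (length(per)) mean(per) else NA_real_,
       per_module = per, target = target)
}

#' Write all simulated study files to a directory
#'
#' Writes the five pipeline inputs in the package's text formats plus the
#' ground truth as JSON: \code{pdx_expr.tsv}, \code{activity.csv},
#' \code{patient_ref.tsv}, \code{patient_val.tsv},
#' \code{outcome_binary.csv}, \code{outcome_survival.csv},
#' \code{truth.json}.
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(sim$pdx, file.path(dir, "pdx_expr.tsv"))
  writeDrugActivity(sim$activity, file.path(dir, "activity.csv"))
  writeExpression(sim$patientRef, file.path(dir, "patient_ref.tsv"))
  writeExpression(sim$patientVal, file.path(dir, "patient_val.tsv"))
  write.csv(sim$outcomeBinary, file.path(dir, "outcome_binary.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(sim$outcomeSurvival, file.path(dir, "outcome_survival.csv"),
            row.names = FALSE, quote = FALSE)
  tr <- sim$truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
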