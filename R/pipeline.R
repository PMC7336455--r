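# Load an input that may be a file path or an in-memory object.
.loadExprInput <- function(x, dialect = "matrix_tsv") {
  if (is.character(x) && length(x) == 1) readExpression(x, dialect = dialect)
  else x
}
.loadActivityInput <- function(x) {
  if (is.character(x) && length(x) == 1) readDrugActivity(x) else x
}
.loadOutcomeInput <- function(x) {
  if (is.character(x) && length(x) == 1) readOutcome(x) else x
}
.digestInput <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    unname(tools::md5sum(x)) else NA_character_
}

#' Run the full drug-response modeling pipeline
#'
#' Orchestrates discovery, concordant co-expression analysis, model
#' training, cohort scoring, and validation from one configuration, and
#' returns (and optionally writes) every stage artifact plus a
#' machine-readable run manifest with the stage-by-stage feature counts
#' (screened, discovered, CCE-selected, final model -- monotone
#' non-increasing), seeds, input digests, and versions.
#'
#' All randomness derives from the single root \code{seed}: the forest uses
#' \code{seed + 101}, the validation bootstrap \code{seed + 303}.
#'
#' When FDR-level CCEA selects fewer than \code{minModelFeatures}
#' candidates, the stage relaxes to nominal p < 0.05 selection; if that is
#' still too sparse, CCEA is skipped entirely. The mode actually applied is
#' recorded in the manifest (\code{ccea_mode}: \code{"fdr"},
#' \code{"nominal"}, or \code{"skipped"}).
#'
#' @param config configuration: a named list or a path to a YAML file with
#'   keys \code{inputs} (pdx_expr, activity, patient_ref, and a
#'   \code{validation} list of \code{expr}/\code{outcome}/\code{label}
#'   entries -- file paths or in-memory objects), \code{seed}, and optional
#'   stage blocks \code{discovery} (method, fdr, min_group_size,
#'   nominal_fallback, cor_flavor), \code{ccea} (fdr, min_ccec, cor, skip),
#'   \code{gem} (trees), \code{evaluation} (responder_low, strata).
#' @param outdir optional output directory; when given, every stage
#'   artifact is written as it is produced (biomarkers.csv, ccea.csv,
#'   model.rds, scores_<label>.csv, report_<label>.json, manifest.json),
#'   so completed artifacts persist even if a later stage fails.
#' @param minModelFeatures minimum features required to train (default 4).
#' @return list with \code{manifest}, \code{biomarkers}, \code{ccea} (NULL
#'   when skipped), \code{discoveredFeatures} (the discovery-stage output,
#'   after any fallback), \code{cceFeatures} (the features handed to
#'   training after the CCEA stage and its fallbacks), \code{model},
#'   \code{scores}
#'   (named list per cohort), and \code{reports} (named list of
#'   \linkS4class{ValidationReport}).
#' @examples
#' sim <- simulateStudy(simConfig(nFeatures = 150, nSensitivity = 20,
#'                                nConcordant = 12, nPdx = 12,
#'                                moduleSize = 20, seed = 3))
#' run <- runPipeline(list(
#'   inputs = list(pdx_expr = sim$pdx, activity = sim$activity,
#'                 patient_ref = sim$patientRef,
#'                 validation = list(list(expr = sim$patientVal,
#'                                        outcome = sim$outcomeBinary,
#'                                        label = "val"))),
#'   seed = 3))
#' run$manifest$counts
#' @export
runPipeline <- function(config, outdir = NULL, minModelFeatures = 4) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  inp <- config$inputs
  if (is.null(inp$pdx_expr) || is.null(inp$activity))
    stop("config$inputs needs pdx_expr and activity", call. = FALSE)
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required", call. = FALSE)
  seed <- as.integer(seed)
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(fn, ..., file) {
    if (!is.null(outdir)) fn(..., file.path(outdir, file))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  opt <- function(block, key, default) {
    v <- config[[block]][[key]]
    if (is.null(v)) default else v
  }

  manifest <- list(
    config = rapply(config, function(x)
      if (is.character(x) || is.numeric(x) || is.logical(x)) x else
        paste0("<in-memory ", class(x)[1], ">"), how = "replace"),
    input_digests = list(pdx_expr = .digestInput(inp$pdx_expr),
                         activity = .digestInput(inp$activity),
                         patient_ref = .digestInput(inp$patient_ref)),
    seeds = list(root = seed, gem = seed + 101L, bootstrap = seed + 303L),
    versions = list(package = as.character(packageVersion("pdxgem")),
                    r = R.version.string),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  pdx <- stage("load", .loadExprInput(inp$pdx_expr))
  activity <- stage("load", .loadActivityInput(inp$activity))

  biomarkers <- stage("discovery", discoverBiomarkers(
    pdx, activity,
    method = opt("discovery", "method", "auto"),
    minGroupSize = opt("discovery", "min_group_size", 2),
    fdr = opt("discovery", "fdr", 0.05),
    nominalAlpha = opt("discovery", "nominal_alpha", 0.05),
    nominalFallback = opt("discovery", "nominal_fallback", TRUE),
    corFlavor = opt("discovery", "cor_flavor", "spearman")))
  emit(writeBiomarkerTable, biomarkers, file = "biomarkers.csv")
  discovered <- selectedFeatures(biomarkers)
  manifest$alpha_mode <- alphaMode(biomarkers)
  if (length(discovered) < minModelFeatures) {
    # A model needs a handful of features; when FDR selection is this
    # sparse, widen to the nominal level (the same relaxation the
    # discovery stage applies when FDR selects nothing).
    discovered <- featureIds(biomarkers)[
      biomarkers$p_value < opt("discovery", "nominal_alpha", 0.05) &
      !biomarkers$degenerate]
    manifest$alpha_mode <- "nominal"
    manifest$discovery_fallback <- "min_model_features"
  }

  skipCcea <- isTRUE(opt("ccea", "skip", FALSE))
  cceaRes <- NULL
  cceaMode <- "skipped"
  trainFeatures <- discovered
  if (!skipCcea) {
    if (is.null(inp$patient_ref))
      stop("config$inputs$patient_ref is required unless ccea$skip is TRUE",
           call. = FALSE)
    ref <- stage("load", .loadExprInput(inp$patient_ref))
    cceaFdr <- opt("ccea", "fdr", 0.05)
    cceaRes <- stage("ccea", runCCEA(
      pdx, ref, discovered, minCcec = opt("ccea", "min_ccec", 0),
      fdr = cceaFdr, flavor = opt("ccea", "cor", "pearson")))
    cceaMode <- "fdr"
    sel <- selectedFeatures(cceaRes)
    if (length(sel) < minModelFeatures) {
      # Sparse-panel fallback, mirroring the discovery stage: relax to the
      # nominal level, then give up on the filter rather than abort.
      nominal <- with(as.data.frame(cceaRes),
                      feature_id[p_value < 0.05 &
                                 ccec > opt("ccea", "min_ccec", 0) &
                                 !degenerate])
      if (length(nominal) >= minModelFeatures) {
        sel <- as.character(nominal)
        cceaMode <- "nominal"
      } else {
        sel <- discovered
        cceaMode <- "skipped"
      }
    }
    emit(writeCceaTable, cceaRes, file = "ccea.csv")
    trainFeatures <- sel
  }
  manifest$ccea_mode <- cceaMode

  model <- stage("gem", trainGem(
    pdx, activity, features = trainFeatures,
    nTrees = opt("gem", "trees", 500), seed = seed + 101L,
    drugLabel = opt("gem", "drug_label", "")))
  if (!is.null(outdir)) saveGemModel(model, file.path(outdir, "model.rds"))
  manifest$training_cor <- trainingCor(model)
  manifest$training_cor_oob <- trainingCor(model, oob = TRUE)

  manifest$counts <- list(
    n_features = nrow(biomarkers),
    n_discovered = length(discovered),
    n_cce = length(trainFeatures),
    n_model = length(featureIds(model)))

  scores <- list(); reports <- list()
  vals <- inp$validation
  if (!is.null(vals)) {
    for (i in seq_along(vals)) {
      vc <- vals[[i]]
      label <- if (!is.null(vc$label)) vc$label else paste0("cohort", i)
      expr <- stage(paste0("predict:", label), .loadExprInput(vc$expr))
      sc <- stage(paste0("predict:", label), predictScores(model, expr))
      scores[[label]] <- sc
      emit(writeScores, sc, file = paste0("scores_", label, ".csv"))
      if (!is.null(vc$outcome)) {
        outc <- stage(paste0("validate:", label),
                      .loadOutcomeInput(vc$outcome))
        rep <- stage(paste0("validate:", label), validateCohort(
          sc, outc,
          responderLow = opt("evaluation", "responder_low", TRUE),
          strata = opt("evaluation", "strata", "median_split"),
          label = label, seed = seed + 303L,
          nBoot = opt("evaluation", "n_boot", 2000)))
        reports[[label]] <- rep
        emit(writeValidationReport, rep, file = paste0("report_", label,
                                                       ".json"))
      }
    }
  }

  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  list(manifest = manifest, biomarkers = biomarkers,
       discoveredFeatures = discovered, ccea = cceaRes,
       cceFeatures = trainFeatures, model = model, scores = scores,
       reports = reports)
}
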