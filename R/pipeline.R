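#' Configure an end-to-end pipeline run
#'
#' Bundles the cohort definition, normalization settings, the feature-set
#' configurations to evaluate, the per-fold feature count (or a sweep
#' range), the SVM settings and one global seed. The global seed fans out
#' to per-stage seeds by fixed small offsets, so each stage is
#' independently reproducible.
#'
#' @param cohort a [CohortConfig-class]; its seed is overridden by
#'   \code{seed}.
#' @param alpha reference-cluster significance level.
#' @param perTimepoint recompute the reference cluster per timepoint.
#' @param blocks character vector naming feature configurations to
#'   evaluate; must come from \code{names(standardFeatureCombinations())}.
#' @param k per-fold selected-feature count (used when \code{kRange} is
#'   NULL).
#' @param kRange optional integer vector: sweep the feature count and
#'   report each configuration at its argmax-k.
#' @param svm an [SvmConfig-class].
#' @param seed global integer seed.
#' @return a list of class \code{"petmciRunConfig"}.
#' @export
runConfig <- function(cohort = cohortConfig(), alpha = 0.05,
                      perTimepoint = TRUE,
                      blocks = c("Static_mbl", "Static_m6", "Dynamic_1",
                                 "Cognitive"),
                      k = 46L, kRange = NULL, svm = svmConfig(),
                      seed = 1L) {
  known <- names(standardFeatureCombinations())
  bad <- setdiff(blocks, known)
  if (length(bad) > 0L)
    stop("unknown feature configuration(s): ", paste(bad, collapse = ", "),
         "; choose from: ", paste(known, collapse = ", "), call. = FALSE)
  cohort@seed <- as.integer(seed)
  structure(list(cohort = cohort, alpha = alpha,
                 perTimepoint = perTimepoint, blocks = blocks,
                 k = as.integer(k), kRange = kRange, svm = svm,
                 seed = as.integer(seed)),
            class = "petmciRunConfig")
}

#' Run the full pipeline: simulate, normalize, extract, select, classify
#'
#' Executes every stage in order on a synthetic cohort: generation,
#' two-step reference-cluster normalization (per timepoint), regional
#' feature extraction with age/gender residualization, then per requested
#' feature configuration an F-score-selected leave-one-out RBF-SVM
#' evaluation. The report has one row per requested feature set with
#' ACC/SEN/SPE (percent) and AUC, the layout used for published
#' feature-set comparison tables.
#' Identical config and seed give byte-identical metric tables.
#'
#' @param config a [runConfig()] object.
#' @param outDir optional directory; when given, writes the cohort, the
#'   reference clusters, the feature TSV (+ block sidecar), the per-block
#'   metrics TSV, ROC points, F-score rankings and a provenance JSON.
#' @return list with \code{report} (data.frame), \code{results} (named
#'   list of [CVResult-class]), \code{featureSet}, \code{clusters},
#'   \code{cohort}, \code{rankings} and \code{config}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "petmciRunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("simulate", generateCohort(config$cohort))
  norm <- stage("normalize",
                normalizeCohort(cohort, alpha = config$alpha,
                                perTimepoint = config$perTimepoint))
  fs <- stage("extract",
              extractFeatures(norm$images, cohort@atlas, cohort@subjects))
  combos <- standardFeatureCombinations()
  results <- list()
  rankings <- list()
  for (b in config$blocks) {
    sub <- selectBlocks(fs, combos[[b]])
    rankings[[b]] <- stage(paste0("select[", b, "]"), fScore(sub))
    results[[b]] <- stage(paste0("classify[", b, "]"), {
      if (is.null(config$kRange)) {
        looEvaluate(sub, k = min(config$k, nrow(sub)), svm = config$svm)
      } else {
        kr <- config$kRange[config$kRange <= nrow(sub)]
        sweepFeatureCount(sub, kRange = kr, svm = config$svm)$best
      }
    })
  }
  report <- data.frame(
    feature_set = config$blocks,
    k = vapply(results, slot, 0L, "kUsed"),
    acc = vapply(results, slot, 0, "acc"),
    sen = vapply(results, slot, 0, "sen"),
    spe = vapply(results, slot, 0, "spe"),
    auc = vapply(results, slot, 0, "auc"),
    row.names = NULL)
  out <- list(report = report, results = results, featureSet = fs,
              clusters = norm$clusters, cohort = cohort,
              rankings = rankings, config = config)
  if (!is.null(outDir)) writeRunReport(out, outDir)
  out
}

# serialize every artifact of a pipeline run
writeRunReport <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCohort(run$cohort, file.path(outDir, "cohort"))
  for (tp in names(run$clusters))
    writeReferenceCluster(run$clusters[[tp]],
                          file.path(outDir, "clusters"), prefix = tp)
  writeFeatureSet(run$featureSet, file.path(outDir, "features.tsv"))
  rep <- run$report
  rep[c("acc", "sen", "spe")] <- round(rep[c("acc", "sen", "spe")], 2)
  rep$auc <- round(rep$auc, 4)
  utils::write.table(rep, file.path(outDir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (b in names(run$results)) {
    safe <- gsub("[^A-Za-z0-9_]", "_", b)
    utils::write.table(run$results[[b]]@roc,
                       file.path(outDir, sprintf("roc_%s.tsv", safe)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rk <- run$rankings[[b]]
    utils::write.table(
      data.frame(feature = names(rk@F)[rk@ranking],
                 F = rk@F[rk@ranking]),
      file.path(outDir, sprintf("fscore_%s.tsv", safe)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prov <- list(seed = run$config$seed, alpha = run$config$alpha,
               blocks = run$config$blocks, k = run$config$k,
               svm = list(cost = run$config$svm@cost,
                          gamma = run$config$svm@gamma,
                          scale = run$config$svm@scale),
               package_version = as.character(
                 utils::packageVersion("petmci")))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
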