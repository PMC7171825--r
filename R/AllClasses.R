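#' @import methods
#' @importFrom stats pt pf rnorm runif rbinom sd var qr.resid lm.fit chisq.test
#' @importFrom utils head tail
NULL

#' VoxelImage: a single subject/timepoint 3-D PET intensity volume
#'
#' Holds one 3-D grid of metabolic intensity values together with a brain
#' mask restricting analysis to in-brain voxels, plus subject and timepoint
#' identifiers. Intensities are in arbitrary units; normalization functions
#' rescale them relative to the cerebral global mean or a reference cluster.
#'
#' @slot values numeric 3-D array of voxel intensities.
#' @slot mask logical 3-D array of the same dimensions; \code{TRUE} marks
#'   brain voxels.
#' @slot subject character scalar subject identifier.
#' @slot timepoint character scalar timepoint identifier (e.g. \code{"bl"},
#'   \code{"m6"}).
#'
#' @seealso [voxelImage()], [globalMeanNormalize()],
#'   [referenceClusterNormalize()]
#' @export
setClass("VoxelImage",
         slots = c(values = "array", mask = "array",
                   subject = "character", timepoint = "character"))

setValidity("VoxelImage", function(object) {
  if (length(dim(object@values)) != 3L)
    return("'values' must be a 3-D array")
  if (!identical(dim(object@values), dim(object@mask)))
    return("'values' and 'mask' must share dimensions")
  if (!is.logical(object@mask))
    return("'mask' must be logical")
  if (sum(object@mask) < 1L)
    return("mask selects no voxels")
  if (!all(is.finite(object@values[object@mask])))
    return("in-mask intensities must be finite")
  TRUE
})

#' AtlasLabelMap: integer region labels on a voxel grid
#'
#' An integer-labelled parcellation volume on the same grid as the intensity
#' images. Label 0 denotes background; labels 1..K are regions. Every region
#' label present must be non-empty.
#'
#' @slot labels integer 3-D array of region labels (0 = background).
#'
#' @seealso [makeAtlas()], [parcellate()]
#' @export
setClass("AtlasLabelMap", slots = c(labels = "array"))

setValidity("AtlasLabelMap", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("'labels' must be a 3-D array")
  if (!is.integer(object@labels))
    return("'labels' must be integer")
  labs <- object@labels[object@labels > 0L]
  if (length(labs) == 0L)
    return("atlas contains no labelled voxels")
  ids <- sort(unique(labs))
  if (!identical(ids, seq_len(max(ids))))
    return("region labels must be the consecutive integers 1..K, all non-empty")
  TRUE
})

#' ReferenceCluster: the data-driven normalization reference mask
#'
#' The set of voxels that appear relatively hypermetabolic in the patient
#' group after global-mean scaling, selected by a voxel-wise two-sample
#' t-test against healthy controls. Per-voxel t and one-sided p maps are
#' retained for inspection.
#'
#' @slot selected logical 3-D array of selected voxels.
#' @slot tMap numeric 3-D array of voxel t statistics (NA outside the mask).
#' @slot pMap numeric 3-D array of one-sided p-values (NA outside the mask).
#' @slot alpha numeric significance level used for selection.
#'
#' @seealso [findReferenceCluster()], [referenceClusterNormalize()]
#' @export
setClass("ReferenceCluster",
         slots = c(selected = "array", tMap = "array", pMap = "array",
                   alpha = "numeric"))

setValidity("ReferenceCluster", function(object) {
  if (!is.logical(object@selected))
    return("'selected' must be logical")
  if (!identical(dim(object@selected), dim(object@tMap)) ||
      !identical(dim(object@selected), dim(object@pMap)))
    return("'selected', 'tMap' and 'pMap' must share dimensions")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must be a single value in (0, 1)")
  TRUE
})

#' CohortConfig: parameters of the synthetic-cohort generator
#'
#' Describes the statistical structure of a simulated longitudinal MCI
#' cohort: group sizes, image grid, parcellation, planted regional decline,
#' preserved (reference) regions, covariate effects, noise, and cognitive
#' trajectory parameters. Defaults mirror the study conditions the pipeline
#' is designed for (46 sMCI, 33 pMCI, 4 timepoints, 246 regions); see
#' [cohortConfig()] for the meaning and units of each field.
#'
#' @slot nSmci,nPmci,nHc integer group sizes (HC scanned at baseline only).
#' @slot gridDims integer(3) voxel grid dimensions.
#' @slot nRegions integer number of atlas regions.
#' @slot nTimepoints integer number of scan timepoints (>= 2).
#' @slot baselineMean numeric baseline regional intensity (arbitrary units).
#' @slot declinePerTpPmci,declinePerTpSmci numeric fractional intensity loss
#'   per timepoint in affected regions for each patient group.
#' @slot backgroundDecline numeric fractional loss per timepoint applied to
#'   every non-reference region in patients (reference regions are
#'   preserved, hence relatively hypermetabolic after global scaling).
#' @slot baselineOffsetPmci numeric fractional baseline reduction in
#'   affected regions for pMCI (plants a cross-sectional group difference).
#' @slot nAffectedRegions,nReferenceRegions integer planted region counts.
#' @slot ageEffect numeric intensity change per year of age.
#' @slot genderEffect numeric additive intensity offset for male subjects.
#' @slot noiseSd numeric i.i.d. Gaussian voxel noise SD.
#' @slot ageRange numeric(2) uniform age range (years).
#' @slot pMale numeric probability of male gender.
#' @slot cognitiveParams list of MMSE/ADAS-cog trajectory parameters.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("CohortConfig",
         slots = c(nSmci = "integer", nPmci = "integer", nHc = "integer",
                   gridDims = "integer", nRegions = "integer",
                   nTimepoints = "integer", baselineMean = "numeric",
                   declinePerTpPmci = "numeric", declinePerTpSmci = "numeric",
                   backgroundDecline = "numeric",
                   baselineOffsetPmci = "numeric",
                   nAffectedRegions = "integer",
                   nReferenceRegions = "integer",
                   ageEffect = "numeric", genderEffect = "numeric",
                   noiseSd = "numeric", ageRange = "numeric",
                   pMale = "numeric", cognitiveParams = "list",
                   seed = "integer"))

setValidity("CohortConfig", function(object) {
  cnt <- c(object@nSmci, object@nPmci, object@nHc, object@nRegions,
           object@nAffectedRegions, object@nReferenceRegions)
  if (any(cnt < 1L)) return("all counts must be >= 1")
  if (length(object@gridDims) != 3L || any(object@gridDims < 1L))
    return("'gridDims' must be 3 positive integers")
  if (object@nTimepoints < 2L) return("'nTimepoints' must be >= 2")
  if (object@nAffectedRegions + object@nReferenceRegions > object@nRegions)
    return("nAffectedRegions + nReferenceRegions must be <= nRegions")
  if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
  if (prod(object@gridDims) < object@nRegions)
    return("grid has fewer voxels than regions")
  if (object@ageRange[2] < object@ageRange[1])
    return("'ageRange' must be increasing")
  if (object@pMale < 0 || object@pMale > 1) return("'pMale' must be in [0,1]")
  TRUE
})

#' SyntheticCohort: a generated longitudinal study population
#'
#' The full output of [generateCohort()]: per-subject per-timepoint images
#' for the MCI groups, baseline-only healthy-control images, the atlas, the
#' subject table (group, age, gender, cognitive scores per timepoint), and a
#' ground-truth record of the planted effects.
#'
#' @slot images named list (by subject id) of named lists (by timepoint) of
#'   [VoxelImage-class] objects for the MCI subjects.
#' @slot controlImages list of baseline [VoxelImage-class] objects for
#'   healthy controls.
#' @slot atlas an [AtlasLabelMap-class].
#' @slot subjects data.frame, one row per MCI subject: subject_id, group,
#'   age, gender, and mmse/adas columns per timepoint.
#' @slot truth list recording planted affected-region ids, reference-region
#'   ids and effect sizes.
#' @slot config the generating [CohortConfig-class].
#'
#' @export
setClass("SyntheticCohort",
         slots = c(images = "list", controlImages = "list",
                   atlas = "AtlasLabelMap", subjects = "data.frame",
                   truth = "list", config = "CohortConfig"))

setValidity("SyntheticCohort", function(object) {
  nT <- object@config@nTimepoints
  if (!all(vapply(object@images, length, 1L) == nT))
    return("every MCI subject must have exactly nTimepoints images")
  ids <- regionIds(object@atlas)
  tr <- object@truth
  if (!all(c(tr$affectedRegions, tr$referenceRegions) %in% ids))
    return("truth region ids must be valid atlas labels")
  if (nrow(object@subjects) != length(object@images))
    return("subject table rows must match image map")
  TRUE
})

#' FeatureSet: subjects-by-features matrix with named blocks
#'
#' A \linkS4class{SummarizedExperiment} specialisation holding the assembled
#' feature matrix: rows are features annotated with their block (Static_mbl,
#' Static_m6, Static_m12, Static_m18, Dynamic_1..3, R1..3, Cognitive),
#' columns are subjects annotated with group label (pMCI is the positive
#' class), age and gender. Construct with [FeatureSet()]; subset by block
#' with [selectBlocks()].
#'
#' @seealso [featureMatrix()], [featureBlocks()], [subjectGroups()],
#'   [fScore()], [looEvaluate()]
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"block" %in% colnames(rd)) return("rowData must contain 'block'")
  if (!"group" %in% colnames(cd)) return("colData must contain 'group'")
  a <- SummarizedExperiment::assay(object, "features")
  if (anyNA(a)) return("feature matrix must have no missing cells")
  if (length(unique(as.character(cd$group))) != 2L)
    return("'group' must take exactly two values")
  TRUE
})

#' SvmConfig: RBF-SVM hyperparameters
#'
#' Regularisation weight C, kernel width (as sigma or equivalently
#' gamma = 1/(2 sigma^2); if neither is given gamma defaults to 1/p, the
#' libsvm convention), and whether features are z-scored per training fold.
#'
#' @slot cost numeric C > 0.
#' @slot gamma numeric RBF gamma, or NA to use 1/p at fit time.
#' @slot scale logical; z-score features using training-fold statistics.
#' @slot seed integer seed for any stochastic solver path.
#'
#' @seealso [svmConfig()], [looEvaluate()]
#' @export
setClass("SvmConfig",
         slots = c(cost = "numeric", gamma = "numeric", scale = "logical",
                   seed = "integer"))

setValidity("SvmConfig", function(object) {
  if (object@cost <= 0) return("'cost' must be > 0")
  if (!is.na(object@gamma) && object@gamma <= 0)
    return("'gamma' must be > 0")
  TRUE
})

#' FScoreRanking: per-feature F values and the induced ranking
#'
#' Result of [fScore()]: non-negative (possibly infinite, when both
#' within-class variances vanish with unequal means) F values per feature,
#' the feature indices sorted by decreasing F with ties broken by ascending
#' original index, and the class sizes.
#'
#' @slot F numeric per-feature F value.
#' @slot ranking integer permutation of feature indices, decreasing F.
#' @slot nPos,nNeg integer class sizes.
#' @slot flagged integer indices of features with degenerate (infinite) F.
#'
#' @seealso [fScore()], [selectTopK()]
#' @export
setClass("FScoreRanking",
         slots = c(F = "numeric", ranking = "integer",
                   nPos = "integer", nNeg = "integer", flagged = "integer"))

setValidity("FScoreRanking", function(object) {
  if (any(object@F < 0, na.rm = TRUE)) return("F values must be >= 0")
  if (!identical(sort(object@ranking), seq_along(object@F)))
    return("'ranking' must be a permutation of the feature indices")
  TRUE
})

#' CVResult: leave-one-out cross-validation outcome
#'
#' Per-subject held-out decision scores, predicted and true labels, plus the
#' pooled summary metrics: accuracy, sensitivity and specificity in percent
#' (pMCI positive), AUC in [0,1], and the ROC point list.
#'
#' @slot perSubject data.frame with columns subject, fold, score, predicted,
#'   truth.
#' @slot acc,sen,spe numeric summary metrics in percent (unrounded).
#' @slot auc numeric area under the ROC curve.
#' @slot roc data.frame of (fpr, tpr) points.
#' @slot kUsed integer number of features selected per fold.
#'
#' @seealso [looEvaluate()], [confusionMetrics()], [rocAuc()]
#' @export
setClass("CVResult",
         slots = c(perSubject = "data.frame", acc = "numeric",
                   sen = "numeric", spe = "numeric", auc = "numeric",
                   roc = "data.frame", kUsed = "integer"))

setValidity("CVResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("AUC must lie in [0,1]")
  tab <- table(object@perSubject$predicted == object@perSubject$truth)
  acc <- 100 * sum(object@perSubject$predicted == object@perSubject$truth) /
    nrow(object@perSubject)
  if (abs(acc - object@acc) > 1e-8)
    return("ACC inconsistent with the per-subject confusion counts")
  TRUE
})
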