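#' Default cognitive trajectory parameters
#'
#' Group-wise baseline means/SDs for MMSE and ADAS-cog with per-timepoint
#' drifts (MMSE falls and ADAS-cog rises faster in pMCI), a per-subject
#' random slope SD (making the four scores of one subject correlated), and
#' an occasion noise SD.
#'
#' @return a list with components \code{mmse} and \code{adas}.
#' @export
defaultCognitiveParams <- function() {
  list(
    mmse = list(mean = c(sMCI = 27.8, pMCI = 27.1),
                sd = c(sMCI = 1.4, pMCI = 1.6),
                driftPerTp = c(sMCI = -0.2, pMCI = -1.0),
                driftSd = 0.3, noiseSd = 0.5),
    adas = list(mean = c(sMCI = 13.9, pMCI = 18.1),
                sd = c(sMCI = 5.5, pMCI = 4.0),
                driftPerTp = c(sMCI = 0.3, pMCI = 1.5),
                driftSd = 0.5, noiseSd = 1.0)
  )
}

#' Configure a synthetic longitudinal MCI cohort
#'
#' Defaults define the study conditions the pipeline targets: 46 stable and
#' 33 progressive MCI patients plus 40 baseline-only healthy controls,
#' scanned at 4 timepoints (bl, m6, m12, m18) on a 12x12x12 grid parcellated
#' into 246 contiguous regions. Progressive patients lose 5% of regional
#' intensity per timepoint in 25 affected regions (stable patients 1%), all
#' patients lose 2% per timepoint everywhere outside 20 preserved reference
#' regions — which therefore appear relatively hypermetabolic after
#' global-mean scaling — and images carry additive age and gender effects
#' plus i.i.d. Gaussian voxel noise.
#'
#' @param nSmci,nPmci,nHc group sizes.
#' @param gridDims integer(3) voxel grid.
#' @param nRegions atlas region count.
#' @param nTimepoints number of timepoints (>= 2).
#' @param baselineMean baseline regional intensity (arbitrary units).
#' @param declinePerTpPmci,declinePerTpSmci fractional loss per timepoint in
#'   affected regions by group.
#' @param backgroundDecline fractional loss per timepoint in all
#'   non-reference regions of patients.
#' @param baselineOffsetPmci fractional baseline reduction of affected
#'   regions in pMCI (0 = groups share baseline level).
#' @param nAffectedRegions,nReferenceRegions planted region counts.
#' @param ageEffect intensity change per year of age.
#' @param genderEffect additive intensity offset for males (gender code 1).
#' @param noiseSd voxel noise SD (intensity units).
#' @param ageRange numeric(2) uniform age range in years.
#' @param pMale probability of male gender.
#' @param cognitiveParams see [defaultCognitiveParams()].
#' @param seed integer RNG seed.
#' @return a [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nSmci = 6, nPmci = 5, nHc = 4,
#'                     gridDims = c(6, 6, 6), nRegions = 20,
#'                     nAffectedRegions = 4, nReferenceRegions = 3)
#' @export
cohortConfig <- function(nSmci = 46L, nPmci = 33L, nHc = 40L,
                         gridDims = c(12L, 12L, 12L), nRegions = 246L,
                         nTimepoints = 4L, baselineMean = 100,
                         declinePerTpPmci = 0.05, declinePerTpSmci = 0.01,
                         backgroundDecline = 0.02, baselineOffsetPmci = 0,
                         nAffectedRegions = 25L, nReferenceRegions = 20L,
                         ageEffect = -0.2, genderEffect = 2,
                         noiseSd = 5, ageRange = c(55, 85), pMale = 0.7,
                         cognitiveParams = defaultCognitiveParams(),
                         seed = 1L) {
  new("CohortConfig",
      nSmci = as.integer(nSmci), nPmci = as.integer(nPmci),
      nHc = as.integer(nHc), gridDims = as.integer(gridDims),
      nRegions = as.integer(nRegions), nTimepoints = as.integer(nTimepoints),
      baselineMean = baselineMean,
      declinePerTpPmci = declinePerTpPmci,
      declinePerTpSmci = declinePerTpSmci,
      backgroundDecline = backgroundDecline,
      baselineOffsetPmci = baselineOffsetPmci,
      nAffectedRegions = as.integer(nAffectedRegions),
      nReferenceRegions = as.integer(nReferenceRegions),
      ageEffect = ageEffect, genderEffect = genderEffect,
      noiseSd = noiseSd, ageRange = ageRange, pMale = pMale,
      cognitiveParams = cognitiveParams, seed = as.integer(seed))
}

#' Timepoint names for a given number of scans
#'
#' Baseline plus 6-monthly follow-ups: \code{"bl", "m6", "m12", ...}.
#' Follow-up index i = 1, 2, 3 maps to m6, m12, m18.
#'
#' @param nTimepoints number of timepoints.
#' @return character vector of timepoint names.
#' @export
timepointNames <- function(nTimepoints) {
  c("bl", paste0("m", 6L * seq_len(nTimepoints - 1L)))
}

# serpentine (boustrophedon) linearisation of a 3-D grid: consecutive
# positions are always 6-adjacent, so consecutive chunks are contiguous
serpentineOrder <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ord <- integer(nx * ny * nz)
  k <- 0L; xdir <- 1L; ydir <- 1L
  for (z in seq_len(nz)) {
    yseq <- if (ydir == 1L) seq_len(ny) else rev(seq_len(ny))
    for (y in yseq) {
      xseq <- if (xdir == 1L) seq_len(nx) else rev(seq_len(nx))
      ord[k + seq_len(nx)] <- xseq + (y - 1L) * nx + (z - 1L) * nx * ny
      k <- k + nx
      xdir <- -xdir
    }
    ydir <- -ydir
  }
  ord
}

#' Build a synthetic contiguous-parcel atlas
#'
#' Partitions the whole grid into \code{nRegions} non-empty, spatially
#' contiguous parcels of near-equal size by chunking a serpentine scan of
#' the grid; the assignment of label ids to chunks is a seeded permutation,
#' so the same seed always yields the identical label volume. A synthetic
#' stand-in for an anatomical parcellation such as the 246-region
#' Brainnetome atlas.
#'
#' @param gridDims integer(3) grid dimensions.
#' @param nRegions number of regions; must not exceed the voxel count.
#' @param seed integer seed for the label permutation.
#' @return an [AtlasLabelMap-class].
#' @examples
#' atl <- makeAtlas(c(10, 10, 10), 246, seed = 1)
#' nRegions(atl)
#' @export
makeAtlas <- function(gridDims, nRegions, seed = 1L) {
  gridDims <- as.integer(gridDims)
  nRegions <- as.integer(nRegions)
  nvox <- prod(gridDims)
  if (nvox < nRegions)
    stop("cannot partition ", nvox, " voxels into ", nRegions,
         " non-empty regions", call. = FALSE)
  ord <- serpentineOrder(gridDims)
  base <- nvox %/% nRegions
  sizes <- rep(base, nRegions)
  extra <- nvox %% nRegions
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  set.seed(as.integer(seed) %% .Machine$integer.max)
  perm <- sample.int(nRegions)
  labs <- integer(nvox)
  labs[ord] <- rep(perm, times = sizes)
  new("AtlasLabelMap", labels = array(labs, gridDims))
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d sMCI + %d pMCI + %d HC, %s grid, %d regions, %d timepoints\n",
    object@nSmci, object@nPmci, object@nHc,
    paste(object@gridDims, collapse = "x"),
    object@nRegions, object@nTimepoints))
  cat(sprintf(
    "  decline/tp: pMCI %.3f, sMCI %.3f, background %.3f; %d affected, %d reference regions\n",
    object@declinePerTpPmci, object@declinePerTpSmci,
    object@backgroundDecline, object@nAffectedRegions,
    object@nReferenceRegions))
  cat(sprintf("  noise SD %.3g, seed %d\n", object@noiseSd, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@subjects$group)
  cat(sprintf(
    "SyntheticCohort: %d MCI subjects (%s), %d HC baseline images, %d regions\n",
    nrow(object@subjects),
    paste(names(tab), tab, sep = "=", collapse = ", "),
    length(object@controlImages), nRegions(object@atlas)))
})

#' Generate a synthetic longitudinal MCI cohort
#'
#' Simulates per-subject per-timepoint PET-like volumes with planted group
#' structure (see [cohortConfig()]), a baseline-only healthy-control image
#' set, the atlas, and a subject table with group, age, gender and
#' MMSE/ADAS-cog trajectories. Regional mean intensity for a patient at
#' timepoint t (0 = baseline) is
#' \code{baselineMean * (1 - backgroundDecline)^t} outside the reference
#' regions, additionally multiplied by \code{(1 - decline_group)^t} in
#' affected regions (and by \code{1 - baselineOffsetPmci} at all timepoints
#' for pMCI), plus additive age/gender terms and i.i.d. voxel noise.
#' Identical seed yields a bit-identical cohort.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' cht <- generateCohort(cohortConfig(nSmci = 5, nPmci = 4, nHc = 3,
#'                                    gridDims = c(6, 6, 4), nRegions = 12,
#'                                    nAffectedRegions = 3,
#'                                    nReferenceRegions = 2, seed = 7))
#' cht
#' @export
generateCohort <- function(config) {
  validObject(config)
  atlas <- makeAtlas(config@gridDims, config@nRegions, seed = config@seed)
  labVec <- as.integer(regionLabels(atlas))
  nvox <- length(labVec)
  tps <- timepointNames(config@nTimepoints)
  ageMid <- mean(config@ageRange)

  set.seed((config@seed + 1L) %% .Machine$integer.max)
  rids <- sample.int(config@nRegions)
  affected <- sort(rids[seq_len(config@nAffectedRegions)])
  reference <- sort(rids[config@nAffectedRegions +
                           seq_len(config@nReferenceRegions)])

  n <- config@nSmci + config@nPmci
  group <- c(rep("sMCI", config@nSmci), rep("pMCI", config@nPmci))
  age <- runif(n, config@ageRange[1], config@ageRange[2])
  gender <- rbinom(n, 1L, config@pMale)
  subjectId <- sprintf("S%03d", seq_len(n))

  cg <- config@cognitiveParams
  cogScores <- function(par) {
    bl <- rnorm(n, par$mean[group], par$sd[group])
    slope <- rnorm(n, par$driftPerTp[group], par$driftSd)
    out <- sapply(seq_along(tps) - 1L, function(t)
      bl + slope * t + rnorm(n, 0, par$noiseSd))
    colnames(out) <- tps
    out
  }
  mmse <- cogScores(cg$mmse)
  adas <- cogScores(cg$adas)

  regionMeans <- function(grp, t) {
    fac <- rep(1, config@nRegions)
    nonref <- setdiff(seq_len(config@nRegions), reference)
    fac[nonref] <- (1 - config@backgroundDecline)^t
    d <- if (grp == "pMCI") config@declinePerTpPmci else config@declinePerTpSmci
    fac[affected] <- fac[affected] * (1 - d)^t
    if (grp == "pMCI")
      fac[affected] <- fac[affected] * (1 - config@baselineOffsetPmci)
    config@baselineMean * fac
  }

  images <- vector("list", n)
  names(images) <- subjectId
  for (i in seq_len(n)) {
    covTerm <- config@ageEffect * (age[i] - ageMid) +
      config@genderEffect * gender[i]
    subjImgs <- vector("list", length(tps))
    names(subjImgs) <- tps
    for (t in seq_along(tps) - 1L) {
      mu <- regionMeans(group[i], t)
      vals <- mu[labVec] + covTerm + rnorm(nvox, 0, config@noiseSd)
      subjImgs[[t + 1L]] <- voxelImage(array(vals, config@gridDims),
                                       subject = subjectId[i],
                                       timepoint = tps[t + 1L])
    }
    images[[i]] <- subjImgs
  }

  hcAge <- runif(config@nHc, config@ageRange[1], config@ageRange[2])
  hcGender <- rbinom(config@nHc, 1L, config@pMale)
  controlImages <- lapply(seq_len(config@nHc), function(i) {
    covTerm <- config@ageEffect * (hcAge[i] - ageMid) +
      config@genderEffect * hcGender[i]
    vals <- config@baselineMean + covTerm + rnorm(nvox, 0, config@noiseSd)
    voxelImage(array(vals, config@gridDims),
               subject = sprintf("HC%03d", i), timepoint = "bl")
  })

  subjects <- data.frame(subject_id = subjectId, group = group,
                         age = age, gender = gender,
                         stringsAsFactors = FALSE)
  for (j in seq_along(tps)) subjects[[paste0("mmse_", tps[j])]] <- mmse[, j]
  for (j in seq_along(tps)) subjects[[paste0("adas_", tps[j])]] <- adas[, j]

  truth <- list(affectedRegions = affected, referenceRegions = reference,
                declinePerTpPmci = config@declinePerTpPmci,
                declinePerTpSmci = config@declinePerTpSmci,
                backgroundDecline = config@backgroundDecline,
                baselineOffsetPmci = config@baselineOffsetPmci)

  new("SyntheticCohort", images = images, controlImages = controlImages,
      atlas = atlas, subjects = subjects, truth = truth, config = config)
}
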