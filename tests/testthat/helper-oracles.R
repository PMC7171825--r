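# Independent oracles kept deliberately naive: scalar loops and direct
# formula evaluation, never the code paths they check.

# F-score by direct evaluation of the class-separation formula, one
# feature at a time
bruteForceFscore <- function(x, labels, positive) {
  vapply(seq_len(ncol(x)), function(i) {
    v <- x[, i]
    vp <- v[labels == positive]
    vn <- v[labels != positive]
    num <- (mean(vp) - mean(v))^2 + (mean(vn) - mean(v))^2
    den <- sum((vp - mean(vp))^2) / (length(vp) - 1) +
      sum((vn - mean(vn))^2) / (length(vn) - 1)
    num / den
  }, 0)
}

# AUC as the Mann-Whitney pairwise concordance count (ties = 1/2)
concordanceAuc <- function(scores, labels, positive = "pMCI") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# region means by explicit per-label summation over voxels
bruteForceRegionMeans <- function(img, atlas) {
  labs <- regionLabels(atlas)
  vals <- voxelValues(img)
  mask <- brainMask(img)
  ids <- regionIds(atlas)
  out <- numeric(length(ids))
  for (j in seq_along(ids)) {
    s <- 0; n <- 0
    for (i in seq_along(labs)) {
      if (mask[i] && labs[i] == ids[j]) { s <- s + vals[i]; n <- n + 1 }
    }
    out[j] <- s / n
  }
  out
}

# a small fast cohort configuration shared across tests
smallCohortConfig <- function(...) {
  cohortConfig(nSmci = 8L, nPmci = 6L, nHc = 6L, gridDims = c(6L, 6L, 4L),
               nRegions = 18L, nAffectedRegions = 4L,
               nReferenceRegions = 3L, seed = 42L, ...)
}

# cache the default small cohort; several test files reuse it
.cohortCache <- new.env(parent = emptyenv())
smallCohort <- function() {
  if (is.null(.cohortCache$c1))
    .cohortCache$c1 <- generateCohort(smallCohortConfig())
  .cohortCache$c1
}

# voxel mask of the planted reference regions of a cohort
referenceVoxelMask <- function(cohort) {
  labs <- regionLabels(cohort@atlas)
  array(labs %in% cohort@truth$referenceRegions, dim(labs))
}
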