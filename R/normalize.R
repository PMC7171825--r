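#' Cerebral global-mean intensity normalization
#'
#' Divides every in-mask voxel by the mean in-mask intensity, the first step
#' of the two-step reference-cluster normalization. The returned image has
#' in-mask mean exactly 1; out-of-mask voxels are zeroed. The input is
#' unchanged.
#'
#' @param img a [VoxelImage-class] with positive mean in-mask intensity.
#' @return a [VoxelImage-class] on the same grid.
#' @examples
#' img <- voxelImage(array(5, c(2, 2, 2)))
#' range(voxelValues(globalMeanNormalize(img)))
#' @rdname globalMeanNormalize
#' @export
setMethod("globalMeanNormalize", "VoxelImage", function(img) {
  m <- mean(img@values[img@mask])
  if (!is.finite(m) || m <= 0)
    stop("degenerate image: global in-mask mean is ", format(m),
         " (must be > 0)", call. = FALSE)
  vals <- array(0, dim(img@values))
  vals[img@mask] <- img@values[img@mask] / m
  new("VoxelImage", values = vals, mask = img@mask,
      subject = img@subject, timepoint = img@timepoint)
})

# stack in-mask voxel values of a list of grid-compatible images
# into an nvox x nimg matrix
stackInMask <- function(imgs, mask) {
  vapply(imgs, function(im) {
    checkGridCompatible(voxelValues(im), mask)
    voxelValues(im)[mask]
  }, numeric(sum(mask)))
}

#' Find the hypermetabolic reference cluster
#'
#' Second step of the reference-cluster normalization: a voxel-wise
#' two-sample t-test of (globally normalized) patient images against
#' healthy-control images. Voxels where the patient mean exceeds the
#' control mean with one-sided p < \code{alpha} form the reference cluster
#' — the relatively preserved regions that appear hypermetabolic after
#' global-mean scaling. Per-voxel t and p maps are retained for inspection.
#'
#' The test is pooled-variance by default (classical voxel-wise mapping
#' practice); set \code{varEqual = FALSE} for the Welch variant. No
#' multiple-comparison correction or cluster-extent threshold is applied
#' unless \code{minClusterSize} is set, matching the plain p < 0.05 voxel
#' selection rule; \code{minClusterSize} simply requires at least that many
#' selected voxels in total and errors otherwise.
#'
#' @param patientImgs,controlImgs non-empty lists of grid-compatible,
#'   globally normalized [VoxelImage-class] objects; each group needs >= 2
#'   images. All images must share the brain mask of the first patient
#'   image.
#' @param alpha one-sided significance level (default 0.05).
#' @param varEqual pooled (TRUE, default) or Welch (FALSE) variance.
#' @param minClusterSize optional minimum selected-voxel count (default 0 =
#'   off).
#' @return a [ReferenceCluster-class].
#' @examples
#' set.seed(1)
#' pat <- replicate(4, globalMeanNormalize(
#'   voxelImage(array(rnorm(64, 100, 5), c(4, 4, 4)))))
#' ctl <- replicate(4, globalMeanNormalize(
#'   voxelImage(array(rnorm(64, 100, 5), c(4, 4, 4)))))
#' ref <- findReferenceCluster(pat, ctl, alpha = 0.2)
#' nSelected(ref)
#' @export
findReferenceCluster <- function(patientImgs, controlImgs, alpha = 0.05,
                                 varEqual = TRUE, minClusterSize = 0L) {
  if (length(patientImgs) < 2L || length(controlImgs) < 2L)
    stop("each group needs at least 2 images", call. = FALSE)
  mask <- brainMask(patientImgs[[1L]])
  X <- stackInMask(patientImgs, mask)
  Y <- stackInMask(controlImgs, mask)
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  tstat[se == 0] <- 0
  p <- pt(tstat, df, lower.tail = FALSE)  # one-sided: patient > control
  sel <- is.finite(tstat) & tstat > 0 & p < alpha

  dims <- dim(mask)
  selArr <- array(FALSE, dims); selArr[mask] <- sel
  tArr <- array(NA_real_, dims); tArr[mask] <- tstat
  pArr <- array(NA_real_, dims); pArr[mask] <- p
  nsel <- sum(sel)
  if (nsel == 0L)
    stop("reference cluster is empty at alpha = ", alpha,
         "; fall back to global-mean normalization explicitly",
         call. = FALSE)
  if (nsel < minClusterSize)
    stop("reference cluster has ", nsel, " voxels, below minClusterSize = ",
         minClusterSize, call. = FALSE)
  new("ReferenceCluster", selected = selArr, tMap = tArr, pMap = pArr,
      alpha = alpha)
}

#' Normalize an image by its reference-cluster mean
#'
#' Divides in-mask intensities by the mean intensity within the reference
#' cluster, so the mean over the cluster is exactly 1 afterwards. With the
#' whole brain mask as the cluster this reduces to
#' [globalMeanNormalize()].
#'
#' @param img a [VoxelImage-class].
#' @param ref a [ReferenceCluster-class] on the same grid.
#' @return a [VoxelImage-class].
#' @examples
#' img <- voxelImage(array(c(2, 4), c(2, 1, 1)))
#' ref <- new("ReferenceCluster",
#'            selected = array(c(TRUE, FALSE), c(2, 1, 1)),
#'            tMap = array(NA_real_, c(2, 1, 1)),
#'            pMap = array(NA_real_, c(2, 1, 1)), alpha = 0.05)
#' voxelValues(referenceClusterNormalize(img, ref))
#' @rdname referenceClusterNormalize
#' @export
setMethod("referenceClusterNormalize",
          signature("VoxelImage", "ReferenceCluster"),
          function(img, ref) {
  checkGridCompatible(img@values, ref@selected)
  if (nSelected(ref) == 0L)
    stop("reference cluster is empty", call. = FALSE)
  m <- mean(img@values[ref@selected])
  if (!is.finite(m) || m <= 0)
    stop("degenerate reference mean ", format(m), " (must be > 0)",
         call. = FALSE)
  vals <- array(0, dim(img@values))
  vals[img@mask] <- img@values[img@mask] / m
  new("VoxelImage", values = vals, mask = img@mask,
      subject = img@subject, timepoint = img@timepoint)
})

#' Two-step reference-cluster normalization of a cohort
#'
#' Convenience wrapper applying the full procedure per timepoint: globally
#' normalize all patient and control images, find the reference cluster for
#' each timepoint by contrasting that timepoint's patient images against
#' the healthy-control baseline set, then rescale each patient image by its
#' timepoint's cluster mean. Set \code{perTimepoint = FALSE} to compute a
#' single shared cluster from the baseline contrast.
#'
#' @param cohort a [SyntheticCohort-class] (or any object with the same
#'   slots read here: \code{images}, \code{controlImages}).
#' @param alpha one-sided significance level.
#' @param perTimepoint recompute the cluster per timepoint (default TRUE).
#' @param varEqual pooled (default) or Welch voxel t-test.
#' @return list with \code{images} (normalized patient images, same nesting
#'   as the input) and \code{clusters} (named list of
#'   [ReferenceCluster-class] per timepoint).
#' @export
normalizeCohort <- function(cohort, alpha = 0.05, perTimepoint = TRUE,
                            varEqual = TRUE) {
  ctl <- lapply(cohort@controlImages, globalMeanNormalize)
  imgs <- lapply(cohort@images, function(s) lapply(s, globalMeanNormalize))
  tps <- names(imgs[[1L]])
  clusterFor <- function(tp) {
    pat <- lapply(imgs, `[[`, tp)
    findReferenceCluster(pat, ctl, alpha = alpha, varEqual = varEqual)
  }
  clusters <- if (perTimepoint) {
    cl <- lapply(tps, clusterFor)
    names(cl) <- tps
    cl
  } else {
    cl <- rep(list(clusterFor(tps[1L])), length(tps))
    names(cl) <- tps
    cl
  }
  norm <- lapply(imgs, function(s) {
    out <- lapply(tps, function(tp)
      referenceClusterNormalize(s[[tp]], clusters[[tp]]))
    names(out) <- tps
    out
  })
  list(images = norm, clusters = clusters)
}
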