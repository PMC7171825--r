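#' Regional mean intensities (static features)
#'
#' Maps in-mask voxels onto atlas regions and returns, per region, the
#' arithmetic mean intensity: the static feature of one subject/timepoint.
#'
#' @param img a [VoxelImage-class].
#' @param atlas an [AtlasLabelMap-class] on the same grid; every region
#'   must contain at least one in-mask voxel.
#' @return named numeric vector of length \code{nRegions(atlas)} with
#'   attributes \code{subject} and \code{timepoint}.
#' @examples
#' atl <- makeAtlas(c(4, 4, 2), 8)
#' img <- voxelImage(array(1, c(4, 4, 2)))
#' parcellate(img, atl)
#' @rdname parcellate
#' @export
setMethod("parcellate", signature("VoxelImage", "AtlasLabelMap"),
          function(img, atlas) {
  checkGridCompatible(img@values, atlas@labels)
  keep <- img@mask & atlas@labels > 0L
  labs <- atlas@labels[keep]
  ids <- regionIds(atlas)
  missing <- setdiff(ids, unique(labs))
  if (length(missing) > 0L)
    stop("region(s) empty under the brain mask: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sums <- rowsum(img@values[keep], labs)
  cnts <- rowsum(rep(1, length(labs)), labs)
  out <- as.numeric(sums / cnts)[match(ids, as.integer(rownames(sums)))]
  names(out) <- sprintf("R%03d", ids)
  attr(out, "subject") <- img@subject
  attr(out, "timepoint") <- img@timepoint
  out
})

#' Remove age and gender effects by linear regression
#'
#' Replaces each variable (voxel or regional intensity) by its least-squares
#' residual against the design (intercept, age, gender), fitted across
#' subjects. Residuals are exactly orthogonal to the age and gender columns.
#' Because least-squares residuals are linear in the response with a shared
#' design, residualizing voxels and then averaging within regions equals
#' averaging first and residualizing the regional means.
#'
#' @param x numeric matrix, subjects x variables.
#' @param covariates data.frame with one row per subject and columns
#'   \code{age} (years) and \code{gender} (0/1), no missing values.
#' @return matrix of residuals, same shape and dimnames as \code{x}.
#' @examples
#' cov <- data.frame(age = c(60, 65, 70, 75), gender = c(0, 1, 0, 1))
#' x <- cbind(a = 2 * cov$age, b = rnorm(4))
#' residualizeConfounds(x, cov)[, "a"]  # exactly linear in age -> ~0
#' @export
residualizeConfounds <- function(x, covariates) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (nrow(x) != nrow(covariates))
    stop("covariate rows must match subjects", call. = FALSE)
  if (anyNA(covariates$age) || anyNA(covariates$gender))
    stop("covariates must have no missing values", call. = FALSE)
  design <- cbind(intercept = 1, age = covariates$age,
                  gender = as.numeric(covariates$gender))
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("rank-deficient confound design (constant age or single gender?)",
         call. = FALSE)
  res <- qr.resid(qrd, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Longitudinal dynamic features: differences D and change rates R
#'
#' From static regional intensities at baseline and follow-up timepoints,
#' computes per region the intensity difference from baseline,
#' \code{D_i = T_baseline - T_i}, and the change rate relative to baseline,
#' \code{R_i = D_i / T_baseline}, for follow-up i = 1, 2, 3 (m6, m12, m18).
#' The identity \code{R_i * T_baseline = D_i} holds element-wise.
#'
#' @param statics named list of static feature vectors or subjects x regions
#'   matrices, one per timepoint, baseline first; all must share the region
#'   set. Names default to \code{"bl", "m6", ...} order.
#' @param eps guard against undefined ratios: any \code{|T_baseline| < eps}
#'   is an error (default 1e-12; normalized intensities sit near 1, so this
#'   never triggers on sane input).
#' @return list with components \code{D} and \code{R}, each a named list
#'   (\code{"1"}, \code{"2"}, ...) of objects shaped like the inputs.
#' @examples
#' dynamicFeatures(list(bl = c(a = 2), m6 = c(a = 1.5)))
#' @export
dynamicFeatures <- function(statics, eps = 1e-12) {
  if (length(statics) < 2L)
    stop("need baseline plus at least one follow-up", call. = FALSE)
  asMat <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1,
                                                       dimnames = list(NULL, names(v)))
  bl <- asMat(statics[[1L]])
  if (any(abs(bl) < eps))
    stop("baseline intensity below eps guard (", format(eps),
         ") in some region: change rate undefined", call. = FALSE)
  D <- list(); R <- list()
  for (i in seq_len(length(statics) - 1L)) {
    Ti <- asMat(statics[[i + 1L]])
    if (!identical(dim(Ti), dim(bl)))
      stop("timepoint ", i, " does not share the baseline region set",
           call. = FALSE)
    Di <- bl - Ti
    D[[as.character(i)]] <- if (is.matrix(statics[[1L]])) Di else drop(Di)
    Ri <- Di / bl
    R[[as.character(i)]] <- if (is.matrix(statics[[1L]])) Ri else drop(Ri)
  }
  list(D = D, R = R)
}

#' Assemble the cognitive feature block
#'
#' Per subject, the MMSE scores of all timepoints followed by the ADAS-cog
#' scores of all timepoints (8 columns at 4 timepoints), taken verbatim
#' from the subject table. Column order is fixed:
#' \code{mmse_bl, mmse_m6, ..., adas_bl, adas_m6, ...}.
#'
#' @param subjects data.frame with per-timepoint \code{mmse_*} and
#'   \code{adas_*} columns; any missing score is an error naming the
#'   subject.
#' @param timepoints character timepoint names (default from the columns
#'   present, in \code{mmse_*} order).
#' @return numeric matrix, subjects x (2 * timepoints).
#' @export
assembleCognitive <- function(subjects, timepoints = NULL) {
  if (is.null(timepoints)) {
    mm <- grep("^mmse_", colnames(subjects), value = TRUE)
    timepoints <- sub("^mmse_", "", mm)
  }
  cols <- c(paste0("mmse_", timepoints), paste0("adas_", timepoints))
  miss <- setdiff(cols, colnames(subjects))
  if (length(miss) > 0L)
    stop("missing cognitive columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- as.matrix(subjects[, cols])
  if (anyNA(out)) {
    bad <- subjects$subject_id[rowSums(is.na(out)) > 0][1L]
    stop("missing cognitive score for subject ", bad, call. = FALSE)
  }
  rownames(out) <- subjects$subject_id
  out
}

#' Construct a FeatureSet from named blocks
#'
#' Column-binds the named feature blocks (each a subjects x p matrix in
#' identical subject order) into a [FeatureSet-class], recording block
#' membership in \code{rowData} and the subject table (group label, age,
#' gender) in \code{colData}. Column names are prefixed with the block name
#' and must be unique after prefixing; duplicated blocks are rejected.
#'
#' @param blocks named list of numeric matrices, subjects x features.
#' @param subjects data.frame with columns \code{subject_id}, \code{group}
#'   (two values; pMCI positive), and optionally \code{age}, \code{gender}.
#' @return a [FeatureSet-class].
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @export
FeatureSet <- function(blocks, subjects) {
  if (is.null(names(blocks)) || any(names(blocks) == "") ||
      anyDuplicated(names(blocks)))
    stop("blocks must be uniquely named", call. = FALSE)
  blocks <- lapply(blocks, as.matrix)
  ns <- vapply(blocks, nrow, 1L)
  if (length(unique(ns)) != 1L || ns[1L] != nrow(subjects))
    stop("all blocks must share the subject ordering of the subject table",
         call. = FALSE)
  for (b in names(blocks)) {
    cn <- colnames(blocks[[b]])
    if (is.null(cn)) cn <- sprintf("f%03d", seq_len(ncol(blocks[[b]])))
    colnames(blocks[[b]]) <- paste(b, cn, sep = ".")
  }
  mat <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(mat)))
    stop("duplicated feature names after block prefixing", call. = FALSE)
  block <- factor(rep(names(blocks), vapply(blocks, ncol, 1L)),
                  levels = names(blocks))
  cd <- S4Vectors::DataFrame(group = subjects$group,
                             row.names = subjects$subject_id)
  for (cc in intersect(c("age", "gender"), colnames(subjects)))
    cd[[cc]] <- subjects[[cc]]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat)),
    rowData = S4Vectors::DataFrame(block = block, row.names = colnames(mat)),
    colData = cd)
  new("FeatureSet", se)
}

#' Subjects-by-features matrix of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return numeric matrix, subjects in rows, features in columns.
#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureSet", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' Block membership of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return named list mapping block name to feature (row) indices.
#' @rdname featureBlocks
#' @export
setMethod("featureBlocks", "FeatureSet", function(x) {
  bl <- SummarizedExperiment::rowData(x)$block
  split(seq_along(bl), bl)
})

#' Group labels of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return factor of subject group labels with pMCI last (positive class).
#' @rdname subjectGroups
#' @export
setMethod("subjectGroups", "FeatureSet", function(x) {
  g <- as.character(SummarizedExperiment::colData(x)$group)
  lev <- unique(g)
  if ("pMCI" %in% lev) lev <- c(setdiff(lev, "pMCI"), "pMCI")
  factor(g, levels = lev)
})

#' Select feature blocks
#'
#' Returns the sub-FeatureSet containing the named blocks, in the order
#' given — the column-wise concatenation used for the combined feature
#' configurations (e.g. Static_all, Dynamic_all, Dynamic & Cognitive).
#'
#' @param x a [FeatureSet-class].
#' @param blocks character vector of block names.
#' @return a [FeatureSet-class].
#' @rdname selectBlocks
#' @export
setMethod("selectBlocks", "FeatureSet", function(x, blocks) {
  have <- levels(SummarizedExperiment::rowData(x)$block)
  miss <- setdiff(blocks, have)
  if (length(miss) > 0L)
    stop("unknown block(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(blocks))
    stop("duplicated block selection", call. = FALSE)
  fb <- featureBlocks(x)
  idx <- unlist(fb[blocks], use.names = FALSE)
  out <- x[idx, ]
  rd <- SummarizedExperiment::rowData(out)
  rd$block <- droplevels(rd$block)
  SummarizedExperiment::rowData(out) <- rd
  out
})

#' The standard feature-set configurations
#'
#' Named list mapping each reported feature configuration to its block
#' composition: the four per-timepoint static sets, Static_all, the three
#' difference sets Dynamic_1..3 and rate sets R1..3, Dynamic_all (the three
#' D blocks; set \code{includeRates = TRUE} to add R1..3), Cognitive, and
#' the pairwise/all combinations (Static & Dynamic, Static & Cognitive,
#' Dynamic & Cognitive, All).
#'
#' @param includeRates include R1..3 in Dynamic_all and downstream
#'   combinations (default FALSE).
#' @return named list of character vectors of block names.
#' @export
standardFeatureCombinations <- function(includeRates = FALSE) {
  statics <- c("Static_mbl", "Static_m6", "Static_m12", "Static_m18")
  dyn <- c("Dynamic_1", "Dynamic_2", "Dynamic_3")
  if (includeRates) dyn <- c(dyn, c("R1", "R2", "R3"))
  out <- list()
  for (s in statics) out[[s]] <- s
  out$Static_all <- statics
  for (d in c("Dynamic_1", "Dynamic_2", "Dynamic_3")) out[[d]] <- d
  for (r in c("R1", "R2", "R3")) out[[r]] <- r
  out$Dynamic_all <- dyn
  out$Cognitive <- "Cognitive"
  out$`Static & Dynamic` <- c(statics, dyn)
  out$`Static & Cognitive` <- c(statics, "Cognitive")
  out$`Dynamic & Cognitive` <- c(dyn, "Cognitive")
  out$All <- c(statics, dyn, "Cognitive")
  out
}

#' Build the full FeatureSet of a normalized cohort
#'
#' Parcellates every normalized patient image, computes the dynamic D and R
#' features from the per-timepoint statics, assembles the cognitive block,
#' and (by default) residualizes age and gender out of every imaging block.
#' T and D are linear in the voxel data, so region-level residualization
#' equals the voxel-level order; R is residualized as a derived variable.
#' Cognitive scores are not residualized.
#'
#' @param normImages normalized patient images as returned in
#'   \code{normalizeCohort()$images}.
#' @param atlas an [AtlasLabelMap-class].
#' @param subjects the subject table (must align with \code{normImages}).
#' @param residualize remove age/gender from imaging blocks (default TRUE).
#' @param includeCognitive add the cognitive block (default TRUE).
#' @return a [FeatureSet-class] with blocks Static_mbl..Static_m18,
#'   Dynamic_1..3, R1..3 and Cognitive.
#' @export
extractFeatures <- function(normImages, atlas, subjects,
                            residualize = TRUE, includeCognitive = TRUE) {
  if (length(normImages) != nrow(subjects))
    stop("images and subject table do not align", call. = FALSE)
  tps <- names(normImages[[1L]])
  statics <- lapply(tps, function(tp)
    t(vapply(normImages, function(s) parcellate(s[[tp]], atlas),
             numeric(nRegions(atlas)))))
  names(statics) <- tps
  dyn <- dynamicFeatures(statics)
  staticNames <- paste0("Static_", tps)
  staticNames[tps == "bl"] <- "Static_mbl"
  blocks <- list()
  for (j in seq_along(tps)) blocks[[staticNames[j]]] <- statics[[j]]
  for (i in names(dyn$D)) blocks[[paste0("Dynamic_", i)]] <- dyn$D[[i]]
  for (i in names(dyn$R)) blocks[[paste0("R", i)]] <- dyn$R[[i]]
  if (residualize)
    blocks <- lapply(blocks, residualizeConfounds, covariates = subjects)
  if (includeCognitive)
    blocks$Cognitive <- assembleCognitive(subjects)
  FeatureSet(blocks, subjects)
}
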