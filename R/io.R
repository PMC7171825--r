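#' Read and write voxel volumes as NIfTI-1
#'
#' Images are written with double-precision storage so that a write/read
#' round trip is exact. The brain mask travels as a companion volume when
#' given. Atlas label maps are written as integer volumes.
#'
#' @param img a [VoxelImage-class].
#' @param path output \code{.nii} or \code{.nii.gz} path.
#' @param maskPath optional path for the mask volume.
#' @return \code{writeVoxelImage} returns \code{path} invisibly;
#'   \code{readVoxelImage} returns a [VoxelImage-class].
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
writeVoxelImage <- function(img, path, maskPath = NULL) {
  RNifti::writeNifti(voxelValues(img), path, datatype = "double")
  if (!is.null(maskPath))
    RNifti::writeNifti(array(as.integer(brainMask(img)),
                             dim(brainMask(img))),
                       maskPath, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti-io
#' @param subject,timepoint identifiers attached on read.
#' @export
readVoxelImage <- function(path, maskPath = NULL, subject = "s1",
                           timepoint = "bl") {
  v <- RNifti::readNifti(path)
  vals <- array(as.numeric(v), dim(v))
  mask <- if (is.null(maskPath)) NULL else {
    m <- RNifti::readNifti(maskPath)
    array(as.numeric(m) > 0, dim(m))
  }
  voxelImage(vals, mask = mask, subject = subject, timepoint = timepoint)
}

#' @rdname nifti-io
#' @param atlas an [AtlasLabelMap-class].
#' @export
writeAtlas <- function(atlas, path) {
  RNifti::writeNifti(regionLabels(atlas), path, datatype = "int32")
  invisible(path)
}

#' @rdname nifti-io
#' @export
readAtlas <- function(path) {
  v <- RNifti::readNifti(path)
  labs <- array(as.integer(round(as.numeric(v))), dim(v))
  new("AtlasLabelMap", labels = labs)
}

#' Write a reference cluster and its statistic maps as NIfTI
#'
#' @param ref a [ReferenceCluster-class].
#' @param dir output directory; writes \code{mask.nii.gz},
#'   \code{tmap.nii.gz}, \code{pmap.nii.gz}.
#' @param prefix filename prefix (e.g. the timepoint).
#' @return the directory, invisibly.
#' @export
writeReferenceCluster <- function(ref, dir, prefix = "cluster") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(array(as.integer(selectedVoxels(ref)),
                           dim(selectedVoxels(ref))),
                     file.path(dir, paste0(prefix, "_mask.nii.gz")),
                     datatype = "uint8")
  RNifti::writeNifti(tMap(ref),
                     file.path(dir, paste0(prefix, "_tmap.nii.gz")),
                     datatype = "double")
  RNifti::writeNifti(pMap(ref),
                     file.path(dir, paste0(prefix, "_pmap.nii.gz")),
                     datatype = "double")
  invisible(dir)
}

#' Read and write the subject table as TSV
#'
#' @param subjects data.frame subject table.
#' @param path TSV path with header.
#' @return the path (write) or the data.frame (read).
#' @name subjects-io
NULL

#' @rdname subjects-io
#' @export
writeSubjectTable <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname subjects-io
#' @export
readSubjectTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write and read a FeatureSet as TSV plus a block-index sidecar
#'
#' The feature matrix is written subjects x features as TSV (subject ids in
#' the first column); block membership and subject metadata go to a JSON
#' sidecar so the object reconstructs exactly.
#'
#' @param fs a [FeatureSet-class].
#' @param path TSV path; the sidecar is \code{<path>.blocks.json}.
#' @return the path (write) or a [FeatureSet-class] (read).
#' @name featureset-io
NULL

#' @rdname featureset-io
#' @export
writeFeatureSet <- function(fs, path) {
  mat <- featureMatrix(fs)
  df <- data.frame(subject_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  side <- list(
    blocks = lapply(featureBlocks(fs), function(i)
      rownames(SummarizedExperiment::rowData(fs))[i]),
    subjects = cbind(subject_id = rownames(mat), cd))
  jsonlite::write_json(side, paste0(path, ".blocks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname featureset-io
#' @export
readFeatureSet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".blocks.json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$subject_id
  blocks <- lapply(side$blocks, function(cols) {
    b <- mat[, cols, drop = FALSE]
    # strip the block prefix; FeatureSet() re-adds it
    colnames(b) <- sub("^[^.]+\\.", "", cols)
    b
  })
  FeatureSet(blocks, side$subjects)
}

#' Write a synthetic cohort to disk
#'
#' Images and atlas as NIfTI-1, the subject table as TSV, and the planted
#' ground truth as JSON, so every downstream stage can be run standalone
#' from files.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAtlas(cohort@atlas, file.path(dir, "atlas.nii.gz"))
  writeSubjectTable(cohort@subjects, file.path(dir, "subjects.tsv"))
  jsonlite::write_json(cohort@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  imgDir <- file.path(dir, "images")
  dir.create(imgDir, showWarnings = FALSE)
  for (sid in names(cohort@images))
    for (tp in names(cohort@images[[sid]]))
      writeVoxelImage(cohort@images[[sid]][[tp]],
                      file.path(imgDir, sprintf("%s_%s.nii.gz", sid, tp)))
  hcDir <- file.path(dir, "controls")
  dir.create(hcDir, showWarnings = FALSE)
  for (i in seq_along(cohort@controlImages))
    writeVoxelImage(cohort@controlImages[[i]],
                    file.path(hcDir, sprintf("HC%03d_bl.nii.gz", i)))
  invisible(dir)
}
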