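#' @rdname globalMeanNormalize
#' @export
setGeneric("globalMeanNormalize",
           function(img) standardGeneric("globalMeanNormalize"))

#' @rdname referenceClusterNormalize
#' @export
setGeneric("referenceClusterNormalize",
           function(img, ref) standardGeneric("referenceClusterNormalize"))

#' @rdname parcellate
#' @export
setGeneric("parcellate",
           function(img, atlas) standardGeneric("parcellate"))

#' @rdname fScore
#' @export
setGeneric("fScore",
           function(x, labels, positive = "pMCI")
             standardGeneric("fScore"))

#' Accessors for image and atlas classes
#'
#' \code{voxelValues} and \code{brainMask} return the intensity and mask
#' arrays of a [VoxelImage-class]; \code{regionLabels} the label array of an
#' [AtlasLabelMap-class]; \code{regionIds} its sorted non-background label
#' ids; \code{nRegions} their count; \code{selectedVoxels}, \code{tMap},
#' \code{pMap} and \code{nSelected} the components of a
#' [ReferenceCluster-class].
#'
#' @param x the object.
#' @return the corresponding slot (or derived count).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("selectedVoxels", function(x) standardGeneric("selectedVoxels"))

#' @rdname accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' @rdname accessors
#' @export
setGeneric("pMap", function(x) standardGeneric("pMap"))

#' @rdname accessors
#' @export
setGeneric("nSelected", function(x) standardGeneric("nSelected"))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureBlocks
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname subjectGroups
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' @rdname selectBlocks
#' @export
setGeneric("selectBlocks",
           function(x, blocks) standardGeneric("selectBlocks"))
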