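#' Construct a VoxelImage
#'
#' @param values numeric 3-D array of intensities.
#' @param mask logical 3-D array; defaults to all voxels in-mask.
#' @param subject,timepoint identifier strings.
#' @return a [VoxelImage-class].
#' @examples
#' img <- voxelImage(array(rnorm(8, 100, 5), c(2, 2, 2)))
#' mean(voxelValues(img)[brainMask(img)])
#' @export
voxelImage <- function(values, mask = NULL, subject = "s1", timepoint = "bl") {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  new("VoxelImage", values = values, mask = mask,
      subject = as.character(subject), timepoint = as.character(timepoint))
}

#' @rdname accessors
#' @export
setMethod("voxelValues", "VoxelImage", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("brainMask", "VoxelImage", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("regionLabels", "AtlasLabelMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("regionIds", "AtlasLabelMap",
          function(x) sort(unique(x@labels[x@labels > 0L])))

#' @rdname accessors
#' @export
setMethod("nRegions", "AtlasLabelMap", function(x) length(regionIds(x)))

#' @rdname accessors
#' @export
setMethod("selectedVoxels", "ReferenceCluster", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("tMap", "ReferenceCluster", function(x) x@tMap)

#' @rdname accessors
#' @export
setMethod("pMap", "ReferenceCluster", function(x) x@pMap)

#' @rdname accessors
#' @export
setMethod("nSelected", "ReferenceCluster", function(x) sum(x@selected))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelImage %s/%s: %d x %d x %d grid, %d in-mask voxels\n",
              object@subject, object@timepoint, d[1], d[2], d[3],
              sum(object@mask)))
  v <- object@values[object@mask]
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
})

setMethod("show", "AtlasLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("AtlasLabelMap: %d x %d x %d grid, %d regions, %d labelled voxels\n",
              d[1], d[2], d[3], nRegions(object),
              sum(object@labels > 0L)))
})

setMethod("show", "ReferenceCluster", function(object) {
  cat(sprintf("ReferenceCluster: %d voxels selected at alpha = %g\n",
              nSelected(object), object@alpha))
})

# grids must agree before any voxelwise operation
checkGridCompatible <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("incompatible grids: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
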