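#' @describeIn VoxelGrid voxel values as a plain 3D array
#' @param x a \linkS4class{VoxelGrid}
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @describeIn VoxelGrid voxel spacing in mm
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @describeIn VoxelGrid anatomical orientation code of the storage axes
#' @export
setGeneric("gridOrientation", function(x) standardGeneric("gridOrientation"))

#' @describeIn VoxelGrid world coordinate (mm, RAS) of the volume's minimal corner
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @describeIn LabelMap label vocabulary (named character, code -> name)
#' @export
setGeneric("labelVocabulary", function(x) standardGeneric("labelVocabulary"))

setMethod("gridValues", "VoxelGrid", function(x) x@values)
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
setMethod("gridOrientation", "VoxelGrid", function(x) x@orientation)
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
setMethod("labelVocabulary", "LabelMap", function(x) x@vocabulary)

#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@values))

setMethod("show", "VoxelGrid", function(object) {
  cat(class(object), ": ", paste(dim(object@values), collapse = " x "),
      " voxels, spacing ", paste(signif(object@spacing, 4), collapse = " x "),
      " mm, orientation ", object@orientation, "\n", sep = "")
})

setMethod("show", "LabelMap", function(object) {
  callNextMethod()
  present <- setdiff(unique(as.vector(object@values)), 0)
  nm <- object@vocabulary[as.character(present)]
  cat("  labels present: ",
      if (length(present)) paste(sprintf("%s=%s", present, nm), collapse = ", ")
      else "(none)", "\n", sep = "")
})

setMethod("show", "CenterlineSet", function(object) {
  cat("CenterlineSet: ", length(object@points), " labels on a ",
      paste(object@dim, collapse = " x "), " grid\n", sep = "")
  n <- vapply(object@points, nrow, 0L)
  if (length(n)) cat("  voxels per label: ",
                     paste(sprintf("%s:%d", names(n), n), collapse = ", "),
                     "\n", sep = "")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: ", length(object@tubes), " tubes, voxel ",
      object@voxel, " mm, FOV ",
      paste(signif(object@fov[2, ] - object@fov[1, ], 4), collapse = " x "),
      " mm\n", sep = "")
})

#' @describeIn CenterlineSet per-label index matrices
#' @param x a \code{CenterlineSet}
#' @export
setGeneric("centerlinePoints", function(x) standardGeneric("centerlinePoints"))
setMethod("centerlinePoints", "CenterlineSet", function(x) x@points)
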