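#' Accessors for image-like objects
#'
#' `imgData()` returns the raw array, `voxelSpacing()` the voxel edge
#' lengths in mm, and `imgOrigin()` the world coordinate (mm) of the first
#' voxel center.
#'
#' @param x an [ImageVolume-class], [DwiSeries-class] or
#'   [TensorField-class].
#' @return `imgData()`: the array; `voxelSpacing()`, `imgOrigin()`:
#'   numeric length 3.
#' @aliases imgData voxelSpacing imgOrigin
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname imgData
#' @export
setGeneric("imgOrigin", function(x) standardGeneric("imgOrigin"))

#' Validity mask of a fitted or simulated tensor field
#'
#' @param x a [TensorField-class].
#' @return logical 3D array, TRUE where a tensor is defined.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Streamline accessors
#'
#' `streamlines()` returns the list of point matrices; `trackLengths()`
#' the polyline lengths (mm); `pennationAngles()` the per-track angles
#' (degrees) to the reference axis.
#'
#' @param x a [StreamlineSet-class].
#' @aliases streamlines trackLengths pennationAngles
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname streamlines
#' @export
setGeneric("trackLengths", function(x) standardGeneric("trackLengths"))

#' @rdname streamlines
#' @export
setGeneric("pennationAngles", function(x) standardGeneric("pennationAngles"))

#' Effect table and post hoc comparisons of an ANOVA result
#'
#' @param x an [AnovaResult-class].
#' @return data.frame.
#' @aliases effects posthoc
#' @export
setGeneric("anovaEffects", function(x) standardGeneric("anovaEffects"))

#' @rdname anovaEffects
#' @export
setGeneric("anovaPosthoc", function(x) standardGeneric("anovaPosthoc"))
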