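#' @import methods
NULL

#' Reflect a volume-like object across its midsagittal plane
#'
#' Reverses the array along the object's mirror axis, mapping index \eqn{i}
#' to \eqn{N - 1 - i} (0-based) and leaving all other axes unchanged. This is
#' the left/right correspondence used throughout the package: inputs are
#' assumed resampled so that the midsagittal plane is the centre of the
#' mirror axis.
#'
#' @param x a [BrainVolume], [BrainMask], [BrainAtlas] or [AsymmetryMap]
#' @return an object of the same class with the grid reflected
#' @examples
#' v <- BrainVolume(array(1:8, c(2, 2, 2)), voxelSize = c(2, 2, 2))
#' identical(volumeData(mirror(mirror(v))), volumeData(v))
#' @export
setGeneric("mirror", function(x) standardGeneric("mirror"))

#' Volume of a single voxel in millilitres
#'
#' @param x any gridded object carrying voxel dimensions in mm
#' @return scalar, \eqn{dx \cdot dy \cdot dz / 1000} mL
#' @examples
#' v <- BrainVolume(array(0, c(4, 4, 4)), voxelSize = c(2, 2, 2))
#' voxelVolumeMl(v) # 0.008
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' @rdname gridAccessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname gridAccessors
#' @export
setGeneric("mirrorAxis", function(x) standardGeneric("mirrorAxis"))

#' @rdname BrainVolume
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname BrainVolume
#' @export
setGeneric("volumeUnits", function(x) standardGeneric("volumeUnits"))

#' @rdname BrainMask
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname BrainAtlas
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' @rdname BrainAtlas
#' @export
setGeneric("atlasLut", function(x) standardGeneric("atlasLut"))

#' @rdname AsymmetryMap
#' @export
setGeneric("aiValues", function(x) standardGeneric("aiValues"))

#' @rdname AsymmetryMap
#' @export
setGeneric("aiValid", function(x) standardGeneric("aiValid"))

#' @rdname AsymmetryMap
#' @export
setGeneric("aiMethod", function(x) standardGeneric("aiMethod"))

#' @rdname AsymmetryMap
#' @export
setGeneric("affectedSide", function(x) standardGeneric("affectedSide"))
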