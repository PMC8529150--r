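#' @rdname voxelCount
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname lungVoxels
#' @export
setGeneric("lungVoxels", function(x) standardGeneric("lungVoxels"))

#' @rdname interstitialVoxels
#' @export
setGeneric("interstitialVoxels", function(x) standardGeneric("interstitialVoxels"))

#' @rdname elvar
#' @export
setGeneric("elvar", function(x) standardGeneric("elvar"))
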