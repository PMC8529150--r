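#' Raw array of a volume or mask
#'
#' @param x a CTVolume or BinaryMask.
#' @return the underlying array, dim = (slice, row, col).
#' @export
imageArray <- function(x) {
  stopifnot(is(x, "CTVolume") || is(x, "BinaryMask"))
  x@data
}

#' Voxel count (popcount) of a mask
#'
#' @param x a BinaryMask.
#' @return number of TRUE voxels.
#' @rdname voxelCount
#' @export
setMethod("voxelCount", "BinaryMask", function(x) sum(x@data))

#' Voxel spacing in mm
#'
#' @param x a CTVolume.
#' @return numeric(3): (slice, row, col) spacing in mm.
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' Total lung voxel count L
#'
#' @param x a LungSegmentation or ElvarResult.
#' @rdname lungVoxels
#' @export
setMethod("lungVoxels", "LungSegmentation", function(x) x@L)

#' @rdname lungVoxels
#' @export
setMethod("lungVoxels", "ElvarResult", function(x) x@L)

#' Interstitial voxel count I
#'
#' @param x an InterstitialMap or ElvarResult.
#' @rdname interstitialVoxels
#' @export
setMethod("interstitialVoxels", "InterstitialMap", function(x) x@I)

#' @rdname interstitialVoxels
#' @export
setMethod("interstitialVoxels", "ElvarResult", function(x) x@I)

#' ELVAR value of a result
#'
#' @param x an ElvarResult.
#' @return (L - I)/L, or NA when undefined (L = 0).
#' @rdname elvar
#' @export
setMethod("elvar", "ElvarResult", function(x) x@elvar)

#' Is the ELVAR value defined?
#'
#' ELVAR is undefined when the lung mask is empty (L = 0); the result then
#' carries an explicit marker rather than propagating NaN.
#'
#' @param x an ElvarResult.
#' @export
isElvarDefined <- function(x) {
  stopifnot(is(x, "ElvarResult"))
  x@defined
}

#' Final lung mask of a segmentation
#'
#' @param x a LungSegmentation.
#' @export
lungMask <- function(x) {
  stopifnot(is(x, "LungSegmentation"))
  x@lungMask
}

#' Named intermediate masks of the segmentation stages
#'
#' @param x a LungSegmentation.
#' @return list with elements coarse_air, contour_filled, hole, pre_shrink.
#' @export
segmentationStages <- function(x) {
  stopifnot(is(x, "LungSegmentation"))
  x@stages
}

#' Interstitium mask of an enhancement result
#'
#' @param x an InterstitialMap.
#' @export
interstitiumMask <- function(x) {
  stopifnot(is(x, "InterstitialMap"))
  x@interstitiumMask
}

#' Per-voxel enhancement score field
#'
#' @param x an InterstitialMap.
#' @return 3-D array of scores in [0,1].
#' @export
scoreField <- function(x) {
  stopifnot(is(x, "InterstitialMap"))
  x@scoreField
}

#' Per-slice lung/interstitium counts and ratios
#'
#' @param x an ElvarResult.
#' @return data.frame with columns slice, L_s, I_s, elvar_s.
#' @export
perSliceElvar <- function(x) {
  stopifnot(is(x, "ElvarResult"))
  x@perSlice
}

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat("CTVolume:", paste(d, collapse = " x "), "voxels (slice x row x col)\n")
  cat("  spacing (mm):", paste(format(object@spacing), collapse = " x "), "\n")
  cat("  HU range:", paste(round(range(object@data), 1), collapse = " .. "), "\n")
  if (length(object@sourceMeta))
    cat("  source:", paste(names(object@sourceMeta), collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat("BinaryMask (role:", object@role, "):",
      paste(d, collapse = " x "), "-", sum(object@data), "voxels set\n")
})

setMethod("show", "LungSegmentation", function(object) {
  cat("LungSegmentation: L =", object@L, "lung voxels\n")
  cat("  stages:", paste(names(object@stages), collapse = ", "), "\n")
  if (length(object@diagnostics))
    cat("  diagnostics:", paste(object@diagnostics, collapse = "; "), "\n")
})

setMethod("show", "InterstitialMap", function(object) {
  cat("InterstitialMap: I =", object@I, "interstitial voxels\n")
})

setMethod("show", "ElvarResult", function(object) {
  cat("ElvarResult: L =", object@L, ", I =", object@I, "\n")
  if (object@defined)
    cat("  ELVAR = (L - I)/L =", sprintf("%.4f", object@elvar), "\n")
  else
    cat("  ELVAR undefined (empty lung mask)\n")
})

setMethod("show", "RocResult", function(object) {
  cat("RocResult: AUC =", sprintf("%.3f", object@auc),
      "; best cutoff =", sprintf("%.4g", object@bestCutoff),
      "(Youden J =", sprintf("%.3f", object@youdenJ), ")\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth: true ELVAR =", sprintf("%.4f", object@trueElvar), "\n")
  cat("  lung voxels:", sum(object@lungMaskTrue@data),
      "; interstitial:", sum(object@interstitiumMaskTrue@data), "\n")
})
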