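#' Construct segmentation parameters
#'
#' @param airThresholdHU HU threshold separating aerated lung from soft
#'   tissue; voxels below it are coarse lung-air candidates. Default -500.
#' @param gaussianSigmaMM sigma (mm) of the per-slice Gaussian applied to
#'   the binary lung indicator before the Laplacian. Default 1.0.
#' @param holeMinVolumeMM3 minimum 3-D volume (mm^3) of an enclosed dense
#'   structure for it to be treated as a mask hole (organ indentation)
#'   rather than a blood vessel. Default 500.
#' @param shrinkMaxIters maximum contour-shrinkage iterations. Default 50.
#' @param shrinkToleranceVoxels allowed residual symmetric difference at
#'   convergence. Default 0.
#' @param connectivity2D in-plane pixel connectivity (4 or 8). Default 8.
#' @param minLungComponentMM3 minimum 3-D air-component volume kept in the
#'   coarse mask. Default 10000.
#' @param excludeAirways remove the tracheal air column (the air component
#'   whose in-plane centroid lies in the central third of the field of view
#'   on the topmost 10 percent of slices). Default TRUE.
#' @return a \linkS4class{SegmentationParams} object.
#' @export
segmentationParams <- function(airThresholdHU = -500, gaussianSigmaMM = 1.0,
                               holeMinVolumeMM3 = 500, shrinkMaxIters = 50L,
                               shrinkToleranceVoxels = 0L,
                               connectivity2D = 8L,
                               minLungComponentMM3 = 10000,
                               excludeAirways = TRUE) {
  new("SegmentationParams",
      airThresholdHU = airThresholdHU, gaussianSigmaMM = gaussianSigmaMM,
      holeMinVolumeMM3 = holeMinVolumeMM3,
      shrinkMaxIters = as.integer(shrinkMaxIters),
      shrinkToleranceVoxels = as.integer(shrinkToleranceVoxels),
      connectivity2D = as.integer(connectivity2D),
      minLungComponentMM3 = minLungComponentMM3,
      excludeAirways = excludeAirways)
}

#' Construct interstitial-enhancement parameters
#'
#' @param scalesMM Gaussian scales (mm) for the multi-scale Hessian
#'   analysis; strictly increasing. Default c(0.7, 1.4, 2.8).
#' @param densityFloorHU voxels at least this dense enter the interstitium
#'   regardless of curvature (consolidation and ground-glass interiors are
#'   curvature-free). Default -700.
#' @param sheetnessThreshold threshold on the normalized geometry score in
#'   [0,1]. Default 0.35.
#' @param includeVesselsInI enable the tubular branch of the geometry score
#'   so vessels are counted in I. Default TRUE.
#' @param minComponentVoxels minimum component size kept in the
#'   interstitium mask. Default 3.
#' @return an \linkS4class{EnhancementParams} object.
#' @export
enhancementParams <- function(scalesMM = c(0.7, 1.4, 2.8),
                              densityFloorHU = -700,
                              sheetnessThreshold = 0.35,
                              includeVesselsInI = TRUE,
                              minComponentVoxels = 3L) {
  new("EnhancementParams",
      scalesMM = scalesMM, densityFloorHU = densityFloorHU,
      sheetnessThreshold = sheetnessThreshold,
      includeVesselsInI = includeVesselsInI,
      minComponentVoxels = as.integer(minComponentVoxels))
}

#' Canonical fingerprint of a parameter object
#'
#' Serializes all slots to a canonical string and hashes it (64-bit FNV-1a),
#' so that results carry a compact, reproducible record of the parameters
#' that produced them.
#'
#' @param ... parameter objects (or plain lists) to fingerprint together.
#' @return a 16-character hexadecimal string.
#' @export
paramsFingerprint <- function(...) {
  objs <- list(...)
  canon <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) {
      if (is.list(x)) {
        nm <- names(x)
        if (is.null(nm)) nm <- rep("", length(x))
        o <- order(nm)
        return(paste0("{", paste(vapply(o, function(i)
          paste0(nm[i], ":", canon(x[[i]])), ""), collapse = ","), "}"))
      }
      return(paste(format(x, digits = 17), collapse = ","))
    }
    sl <- sort(slotNames(class(x)))
    paste0(class(x), "{", paste(vapply(sl, function(s)
      paste0(s, ":", canon(slot(x, s))), ""), collapse = ","), "}")
  }
  .fnv1a64(paste(vapply(objs, canon, ""), collapse = "|"))
}

# 64-bit FNV-1a over the UTF-8 bytes of a string, implemented on split
# 32-bit halves to stay exact in double arithmetic.
.fnv1a64 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  # state as four 16-bit limbs, little-endian
  h <- c(0x2325L, 0x8422L, 0xE1C9L, 0xCBF2L)  # 0xCBF29CE484222325
  p <- c(0x01B3L, 0x0100L, 0x0000L, 0x0100L)  # 0x100000001B3
  for (b in bytes) {
    h[1] <- bitwXor(h[1], b)
    # multiply two 64-bit numbers held as 16-bit limbs, keep low 64 bits
    r <- integer(4)
    carry <- 0
    for (i in 1:4) {
      acc <- carry
      for (j in 1:i) acc <- acc + h[j] * p[i - j + 1]
      r[i] <- acc %% 65536
      carry <- acc %/% 65536
    }
    h <- as.integer(r)
  }
  paste0(sprintf("%04x", h[4]), sprintf("%04x", h[3]),
         sprintf("%04x", h[2]), sprintf("%04x", h[1]))
}
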