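# Four-stage ILD-robust lung segmentation:
#   1. coarse air thresholding + 3-D component analysis (body interior only)
#   2. per-slice Gaussian smoothing of the binary indicator, Laplacian
#      zero-crossing contour detection (inner/outer lung edges)
#   3. contour interior filling and mask-hole elimination (organ
#      indentations), preserving vessels and dense disease
#   4. contour shrinkage onto the accurate (zero-crossing) lung edge.

#' Stage 1: coarse lung-air segmentation
#'
#' Thresholds every slice at \code{airThresholdHU}, then removes air
#' connected to the in-plane image border (exterior air), optionally the
#' tracheal air column, and 3-D components smaller than
#' \code{minLungComponentMM3}.
#'
#' @param vol a \linkS4class{CTVolume} in HU.
#' @param p a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{BinaryMask} with role \code{coarse_air}; possible
#'   warning-level diagnostics are in \code{@metadata$diagnostics}.
#' @export
coarseSegment <- function(vol, p = segmentationParams()) {
  stopifnot(is(vol, "CTVolume"), is(p, "SegmentationParams"))
  d <- dim(vol@data)
  air <- vol@data < p@airThresholdHU
  lab <- labelComponents(air, 6L)

  # exterior air: any component touching the in-plane borders
  borderIds <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  borderIds <- borderIds[borderIds > 0L]
  keep <- air & !(lab %in% borderIds)
  keep <- array(keep, d)

  diagnostics <- character()

  if (p@excludeAirways) {
    topSlices <- seq.int(from = max(1L, ceiling(0.9 * d[1])), to = d[1])
    ids <- sort(unique(lab[keep]))
    midR <- d[2] * c(1, 2) / 3
    midC <- d[3] * c(1, 2) / 3
    for (id in ids) {
      inTop <- lab[topSlices, , , drop = FALSE] == id
      if (!any(inTop)) next
      w <- which(inTop, arr.ind = TRUE)
      if (mean(w[, 2]) >= midR[1] && mean(w[, 2]) <= midR[2] &&
          mean(w[, 3]) >= midC[1] && mean(w[, 3]) <= midC[2])
        keep[lab == id] <- FALSE
    }
  }

  # drop small components (noise specks, bowel gas)
  voxVol <- prod(vol@spacing)
  lab2 <- labelComponents(keep, 6L)
  sizes <- componentSizes(lab2)
  small <- as.integer(names(sizes))[sizes * voxVol < p@minLungComponentMM3]
  if (length(small)) keep[lab2 %in% small] <- FALSE

  if (!any(keep) && any(vol@data >= p@airThresholdHU))
    diagnostics <- c(diagnostics,
                     "body present but no interior air below threshold")

  binaryMask(keep, role = "coarse_air",
             gridRef = vol@sourceMeta$gridRef %||% "",
             metadata = list(diagnostics = diagnostics))
}

# In-plane face-neighbor stacks with replicate (clamped) boundary, so the
# image edge never generates spurious sign changes.
.inPlaneNeighborsReplicate <- function(a) {
  d <- dim(a)
  up <- a[, c(1, seq_len(d[2] - 1)), , drop = FALSE]
  dn <- a[, c(seq_len(d[2] - 1) + 1, d[2]), , drop = FALSE]
  lf <- a[, , c(1, seq_len(d[3] - 1)), drop = FALSE]
  rt <- a[, , c(seq_len(d[3] - 1) + 1, d[3]), drop = FALSE]
  list(up, dn, lf, rt)
}

#' Stage 2: Laplacian zero-crossing contour detection
#'
#' Per slice, the binary mask indicator is smoothed with a Gaussian of
#' \code{gaussianSigmaMM} (converted to voxels through \code{spacing},
#' truncated at 4 sigma), its Laplacian is computed, and zero-crossing
#' voxels are identified as sign changes between in-plane face neighbors.
#' A voxel is marked when its Laplacian differs in sign from at least one
#' neighbor and its magnitude does not exceed that neighbor's (the side
#' closest to zero wins; equal magnitudes mark both sides); an exactly zero
#' Laplacian flanked by both signs is also marked. The outer boundary (the
#' candidate lung edge) is the zero crossings on the dense side of the
#' smoothed transition (indicator < 0.5); the inner boundary lies on the
#' aerated side.
#'
#' @param coarse stage-1 \linkS4class{BinaryMask}.
#' @param p a \linkS4class{SegmentationParams}.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return a \linkS4class{ContourField}.
#' @export
detectContours <- function(coarse, p = segmentationParams(),
                           spacing = c(1, 1, 1)) {
  stopifnot(is(coarse, "BinaryMask"))
  d <- dim(coarse@data)
  ind <- array(as.numeric(coarse@data), d)
  sm <- gaussianSmooth3d(ind, p@gaussianSigmaMM, spacing, axes = 2:3)
  nb <- .inPlaneNeighborsReplicate(sm)
  lap <- (nb[[1]] + nb[[2]] - 2 * sm) / spacing[2]^2 +
         (nb[[3]] + nb[[4]] - 2 * sm) / spacing[3]^2

  ln <- .inPlaneNeighborsReplicate(lap)
  zc <- array(FALSE, d)
  anyPos <- array(FALSE, d)
  anyNeg <- array(FALSE, d)
  for (k in 1:4) {
    zc <- zc | (lap * ln[[k]] < 0 & abs(lap) <= abs(ln[[k]]))
    anyPos <- anyPos | ln[[k]] > 0
    anyNeg <- anyNeg | ln[[k]] < 0
  }
  zc <- zc | (lap == 0 & anyPos & anyNeg)

  outer <- zc & sm < 0.5
  inner <- zc & !outer
  gr <- coarse@gridRef
  new("ContourField", smoothed = sm, laplacian = lap,
      zeroCrossings = binaryMask(zc, "generic", gr),
      innerBoundary = binaryMask(inner, "generic", gr),
      outerBoundary = binaryMask(outer, "generic", gr))
}

#' Stage 2b: fill the interior of the candidate lung edge
#'
#' Per slice, the exterior is flood-filled from the slice border with
#' 4-connectivity, the zero-crossing contour acting as the barrier; every
#' pixel not reachable from the border is interior and gets filled; the
#' contour voxels themselves are retained, so the candidate edge keeps all
#' irregular fragments near the boundary. Unclosed contour fragments
#' enclose nothing and are not filled beyond their own voxels. The source
#' air region, when supplied, is superimposed onto the result, so the
#' filled contour always covers the binary lung region it was derived
#' from, even where heavy dense disease thins the aerated web below the
#' contour's resolution.
#'
#' @param cf a \linkS4class{ContourField} from \code{detectContours}.
#' @param p a \linkS4class{SegmentationParams}.
#' @param coarse optional stage-1 coarse air mask to superimpose.
#' @return a \linkS4class{BinaryMask} with role \code{filled_contour}.
#' @export
fillContours <- function(cf, p = segmentationParams(), coarse = NULL) {
  stopifnot(is(cf, "ContourField"))
  barrier <- cf@zeroCrossings@data
  d <- dim(barrier)
  lab <- labelComponents(!barrier, 4L)
  borderIds <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  borderIds <- borderIds[borderIds > 0L]
  # barrier voxels carry label 0, so they are retained automatically
  filled <- array(!(lab %in% borderIds), d)
  if (!is.null(coarse)) filled <- filled | coarse@data
  binaryMask(filled, role = "filled_contour",
             gridRef = cf@zeroCrossings@gridRef)
}

#' Stage 3: mask-hole elimination
#'
#' Candidate interior structures are the dense voxels inside the filled
#' contour (\code{filled \\ coarse}). Region growing over non-air voxels
#' from the lateral background (everything outside the filled contour)
#' identifies dense structure connected to the body: an organ indentation
#' ("mask hole") is such a background-connected candidate component with
#' volume at least \code{holeMinVolumeMM3}. Blood vessels are small and
#' dense disease is enclosed by aerated lung rather than connected to the
#' body, so both are preserved.
#'
#' @param filled stage-2 filled-contour mask.
#' @param coarse stage-1 coarse air mask.
#' @param p a \linkS4class{SegmentationParams}.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return list with \code{quasiLung} (filled minus hole) and \code{hole}
#'   (role \code{hole}).
#' @export
eliminateHoles <- function(filled, coarse, p = segmentationParams(),
                           spacing = c(1, 1, 1)) {
  stopifnot(is(filled, "BinaryMask"), is(coarse, "BinaryMask"))
  f <- filled@data
  cand <- f & !coarse@data
  d <- dim(f)
  hole <- array(FALSE, d)
  if (any(cand)) {
    dense <- !coarse@data
    lab <- labelComponents(dense, 6L)
    # region-grow the background from the volume border over non-lung
    # voxels; dense components it reaches are body-connected
    labF <- labelComponents(!f, 6L)
    reachIds <- unique(c(labF[, 1, ], labF[, d[2], ], labF[, , 1],
                         labF[, , d[3]]))
    reach <- array(labF %in% reachIds[reachIds > 0L], d)
    bgIds <- unique(lab[dense & reach])
    bgIds <- bgIds[bgIds > 0L]
    candLab <- labelComponents(cand, 6L)
    sizes <- componentSizes(candLab)
    voxVol <- prod(spacing)
    bgTouch <- unique(candLab[cand & (lab %in% bgIds)])
    holeIds <- intersect(
      as.integer(names(sizes))[sizes * voxVol >= p@holeMinVolumeMM3],
      bgTouch[bgTouch > 0L])
    if (length(holeIds)) hole <- array(candLab %in% holeIds, d)
  }
  gr <- filled@gridRef
  list(quasiLung = binaryMask(f & !hole, role = "generic", gridRef = gr),
       hole = binaryMask(hole, role = "hole", gridRef = gr))
}

#' Stage 4: contour shrinkage onto the accurate lung edge
#'
#' The quasi-lung mask is contracted one boundary layer at a time, per
#' slice; a boundary voxel stops contracting once it lies on the stopping
#' set. The stopping set is the zero crossing's aerated (inner) side
#' together with the smoothed indicator's interior (indicator >= 0.5): the
#' candidate (outer) edge is itself a zero crossing, so stopping on the
#' accurate inner side is what gives the stage its effect, and the interior
#' level set bounds the contraction where the discrete crossing set has
#' gaps. The mask never grows.
#'
#' @param quasi quasi-lung \linkS4class{BinaryMask} from
#'   \code{eliminateHoles}.
#' @param cf the \linkS4class{ContourField} the mask derives from.
#' @param p a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{BinaryMask} with role \code{lung_final};
#'   \code{@metadata$converged} and \code{@metadata$iterations} record the
#'   stopping behavior.
#' @export
shrinkContour <- function(quasi, cf, p = segmentationParams()) {
  stopifnot(is(quasi, "BinaryMask"), is(cf, "ContourField"))
  m <- quasi@data
  gr <- quasi@gridRef
  if (!any(cf@zeroCrossings@data)) {
    return(binaryMask(m, role = "lung_final", gridRef = gr,
                      metadata = list(converged = FALSE, iterations = 0L,
                                      diagnostics = "empty zero-crossing set; mask unchanged")))
  }
  stopSet <- cf@innerBoundary@data | cf@smoothed >= 0.5
  iter <- 0L
  converged <- FALSE
  while (iter < p@shrinkMaxIters) {
    boundary <- m & !erodeInPlane4(m)
    removable <- boundary & !stopSet
    if (sum(removable) <= p@shrinkToleranceVoxels) { converged <- TRUE; break }
    m <- m & !removable
    iter <- iter + 1L
  }
  if (!converged) {
    boundary <- m & !erodeInPlane4(m)
    converged <- !any(boundary & !stopSet)
  }
  md <- list(converged = converged, iterations = iter)
  if (!converged)
    md$diagnostics <- "contour shrinkage did not converge within shrinkMaxIters"
  binaryMask(m, role = "lung_final", gridRef = gr, metadata = md)
}

#' Run the full four-stage lung segmentation
#'
#' Executes coarse segmentation, contour detection, contour filling, hole
#' elimination and contour shrinkage in order, keeping every intermediate
#' mask for audit, and counts the total number of lung voxels L.
#' Deterministic for fixed input and parameters.
#'
#' @param vol a \linkS4class{CTVolume} in HU.
#' @param p a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{LungSegmentation}.
#' @export
segmentLungs <- function(vol, p = segmentationParams()) {
  stopifnot(is(vol, "CTVolume"))
  coarse <- coarseSegment(vol, p)
  cf <- detectContours(coarse, p, vol@spacing)
  filled <- fillContours(cf, p, coarse)
  eh <- eliminateHoles(filled, coarse, p, vol@spacing)
  final <- shrinkContour(eh$quasiLung, cf, p)

  diagnostics <- c(coarse@metadata$diagnostics %||% character(),
                   final@metadata$diagnostics %||% character())
  L <- sum(final@data)
  if (L == 0) diagnostics <- c(diagnostics, "empty final lung mask (L = 0)")
  pre <- eh$quasiLung
  pre@role <- "generic"
  new("LungSegmentation", lungMask = final, L = as.numeric(L),
      stages = list(coarse_air = coarse, contour_filled = filled,
                    hole = eh$hole, pre_shrink = pre),
      contours = cf, paramsUsed = p, diagnostics = diagnostics)
}
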