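# Curvature-based lung interstitial enhancement. Interstitial structures
# (septal thickening, reticulation) are locally sheet-like, vessels are
# tubular, and both differ from aerated parenchyma in the direction profile
# of the local second derivatives. The concrete operator is multi-scale
# Hessian eigenvalue analysis of the HU field; a density floor additionally
# captures ground-glass and consolidation interiors, which are dense but
# curvature-free.

# Hessian of a smoothed volume by central differences, in physical units
# (per mm^2), with the scale-normalization factor s^2 (gamma = 2) applied.
.hessianFields <- function(sm, spacing, scaleMM) {
  s1 <- spacing[1]; s2 <- spacing[2]; s3 <- spacing[3]
  g <- scaleMM^2
  sh <- function(ds, dr, dc) shift3d(sm, ds, dr, dc, fill = 0)
  list(
    hss = g * (sh(1, 0, 0) + sh(-1, 0, 0) - 2 * sm) / s1^2,
    hrr = g * (sh(0, 1, 0) + sh(0, -1, 0) - 2 * sm) / s2^2,
    hcc = g * (sh(0, 0, 1) + sh(0, 0, -1) - 2 * sm) / s3^2,
    hsr = g * (sh(1, 1, 0) - sh(1, -1, 0) - sh(-1, 1, 0) + sh(-1, -1, 0)) /
      (4 * s1 * s2),
    hsc = g * (sh(1, 0, 1) - sh(1, 0, -1) - sh(-1, 0, 1) + sh(-1, 0, -1)) /
      (4 * s1 * s3),
    hrc = g * (sh(0, 1, 1) - sh(0, 1, -1) - sh(0, -1, 1) + sh(0, -1, -1)) /
      (4 * s2 * s3))
}

#' Multi-scale curvature geometry score
#'
#' For every in-lung voxel and every scale, the eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|} of the Hessian of the
#' scale-smoothed HU field are computed. Bright sheet-like structures have
#' one dominant negative eigenvalue, bright tubes two; the geometry score
#' combines a sheetness response \eqn{|\lambda_3|
#' \exp(-(\lambda_2/\lambda_3)^2 / 2\alpha^2)} (for \eqn{\lambda_3 < 0})
#' with, when the tubular branch is enabled, a vesselness-style response
#' \eqn{\sqrt{|\lambda_2\lambda_3|}
#' \exp(-\lambda_1^2/(2\beta^2 |\lambda_2\lambda_3|))} for
#' \eqn{\lambda_2, \lambda_3 < 0}. The per-voxel score is the maximum over
#' scales, normalized by the volume maximum to [0, 1] so the threshold is
#' transferable across volumes.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param lung a \linkS4class{LungSegmentation} (or BinaryMask) defining
#'   the voxels scored.
#' @param p an \linkS4class{EnhancementParams}.
#' @return 3-D array of scores in [0, 1], zero outside the lung.
#' @export
curvatureFeatures <- function(vol, lung, p = enhancementParams()) {
  stopifnot(is(vol, "CTVolume"))
  m <- if (is(lung, "LungSegmentation")) lung@lungMask@data else lung@data
  d <- dim(vol@data)
  stopifnot(identical(dim(m), d))
  score <- array(0, d)
  if (!any(m)) return(score)
  alpha <- 0.25  # sheet/tube eigenvalue-ratio bandwidth
  beta <- 0.5    # blob-suppression bandwidth
  for (s in p@scalesMM) {
    sm <- gaussianSmooth3d(vol@data, s, vol@spacing)
    H <- .hessianFields(sm, vol@spacing, s)
    ev <- cpp_eigs_sym3(H$hss, H$hrr, H$hcc, H$hsr, H$hsc, H$hrc,
                        as.logical(m))
    l1 <- ev$e1; l2 <- ev$e2; l3 <- ev$e3
    bright <- l3 < 0
    ratio2 <- ifelse(bright, (l2 / l3)^2, 0)
    sheet <- ifelse(bright, abs(l3) * exp(-ratio2 / (2 * alpha^2)), 0)
    resp <- sheet
    if (p@includeVesselsInI) {
      tubular <- l3 < 0 & l2 < 0
      p23 <- abs(l2 * l3)
      tube <- ifelse(tubular,
                     sqrt(p23) * exp(-l1^2 / (2 * beta^2 * pmax(p23, 1e-12))) *
                       (1 - exp(-ratio2 / (2 * alpha^2))),
                     0)
      resp <- pmax(resp, tube)
    }
    score <- pmax(score, array(resp, d))
  }
  mx <- max(score)
  if (mx > 0) score <- score / mx
  score[!m] <- 0
  score
}

#' Generate the lung interstitial enhancement map and count I
#'
#' Marks in-lung voxels whose geometry score reaches
#' \code{sheetnessThreshold} or whose density reaches
#' \code{densityFloorHU} (the dense-disease fallback for consolidation and
#' ground glass, whose interiors have no edge curvature), removes
#' components below \code{minComponentVoxels}, and counts the interstitial
#' voxels I.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param lung a \linkS4class{LungSegmentation}.
#' @param p an \linkS4class{EnhancementParams}.
#' @return an \linkS4class{InterstitialMap}.
#' @export
enhanceInterstitium <- function(vol, lung, p = enhancementParams()) {
  stopifnot(is(vol, "CTVolume"), is(lung, "LungSegmentation"))
  m <- lung@lungMask@data
  score <- curvatureFeatures(vol, lung, p)
  sel <- m & (score >= p@sheetnessThreshold | vol@data >= p@densityFloorHU)
  if (any(sel) && p@minComponentVoxels > 1L) {
    lab <- labelComponents(sel, 26L)
    sizes <- componentSizes(lab)
    small <- as.integer(names(sizes))[sizes < p@minComponentVoxels]
    if (length(small)) sel <- sel & !array(lab %in% small, dim(sel))
  }
  new("InterstitialMap",
      interstitiumMask = binaryMask(sel, role = "interstitium",
                                    gridRef = lung@lungMask@gridRef),
      I = as.numeric(sum(sel)), scoreField = score, paramsUsed = p)
}

# Lung-window display mapping (display only; data stay in HU).
.windowGray <- function(hu, center = -600, width = 1500) {
  pmin(pmax((hu - (center - width / 2)) / width, 0), 1)
}

#' Render enhancement overlays and a score projection
#'
#' Writes one lung-window PNG per slice with interstitial voxels tinted
#' red, plus a maximum-intensity projection of the score field along the
#' chosen axis as a basic 3-D visualization.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param imap an \linkS4class{InterstitialMap}.
#' @param axis projection axis for the MIP (1 = slice, 2 = row, 3 = col).
#' @param outDir output directory (created if absent).
#' @return invisibly, the files written.
#' @export
renderEnhancement <- function(vol, imap, axis = 1L, outDir) {
  stopifnot(is(vol, "CTVolume"), is(imap, "InterstitialMap"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol@data)
  files <- character(0)
  for (s in seq_len(d[1])) {
    gray <- .windowGray(vol@data[s, , ])
    tint <- imap@interstitiumMask@data[s, , ]
    img <- array(gray, c(d[2], d[3], 3))
    img[, , 1][tint] <- pmax(gray[tint], 0.85)
    img[, , 2][tint] <- gray[tint] * 0.25
    img[, , 3][tint] <- gray[tint] * 0.25
    f <- file.path(outDir, sprintf("overlay_%04d.png", s))
    png::writePNG(img, f)
    files <- c(files, f)
  }
  mip <- apply(imap@scoreField, setdiff(1:3, axis), max)
  f <- file.path(outDir, "score_mip.png")
  png::writePNG(mip, f)
  invisible(c(files, f))
}
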