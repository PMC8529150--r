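# Digital thoracic phantom: an elliptical soft-tissue body in exterior air,
# two ellipsoidal air-filled lungs, a procedurally branching vessel tree,
# parameterized interstitial disease (septal sheets, ground-glass blobs,
# consolidation blobs), an optional diaphragm-level organ indentation and
# an optional tracheal air column, with paired ground-truth masks recorded
# before noise is added.

# Evaluate an expression under a local, fully specified RNG state and
# restore the caller's state afterwards. The generator contract is R's
# Mersenne-Twister with inversion normals and rejection sampling, which is
# platform-independent.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Construct a phantom specification
#'
#' Defaults describe a 40 x 128 x 128 voxel thorax at 1 mm isotropic
#' spacing: soft tissue +40 HU, aerated lung -850 HU, exterior air
#' -1000 HU, vessels +50 HU, Gaussian HU noise sigma 20. Disease patterns
#' use conventional radiological HU: septal sheets -300 (1 voxel thick),
#' ground glass -600, consolidation +20.
#'
#' @param shape integer(3) voxel dims (slice, row, col).
#' @param spacingMM numeric(3) spacing in mm.
#' @param bodyHU,lungHU,airHU tissue HU values.
#' @param vessel list(nBranches, radiusRangeMM, hu).
#' @param disease list(mix, targetFraction, peripheralBias, minRho): mix is
#'   a named weight vector over septal_sheet/ggo/consolidation;
#'   targetFraction is the target share of lung volume in [0, 0.5];
#'   peripheralBias biases lesion centers toward the outer lung; minRho
#'   (0..1) optionally confines lesions beyond that normalized lung radius.
#' @param organIndentation list(on, volumeMM3).
#' @param trachea list(on, radiusMM).
#' @param noiseSigmaHU Gaussian HU noise standard deviation.
#' @param countVesselsInTruth whether ground-truth I counts vessels.
#' @param seed integer RNG seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(40L, 128L, 128L), spacingMM = c(1, 1, 1),
                        bodyHU = 40, lungHU = -850, airHU = -1000,
                        vessel = list(), disease = list(),
                        organIndentation = list(), trachea = list(),
                        noiseSigmaHU = 20, countVesselsInTruth = TRUE,
                        seed = 1L) {
  vdef <- list(nBranches = 80L, radiusRangeMM = c(0.8, 2.2), hu = 50)
  ddef <- list(mix = c(septal_sheet = 1, ggo = 1, consolidation = 1) / 3,
               targetFraction = 0, peripheralBias = TRUE, minRho = 0)
  idef <- list(on = FALSE, volumeMM3 = 2000)
  tdef <- list(on = FALSE, radiusMM = 5)
  vessel <- utils::modifyList(vdef, vessel)
  disease <- utils::modifyList(ddef, disease)
  organIndentation <- utils::modifyList(idef, organIndentation)
  trachea <- utils::modifyList(tdef, trachea)
  new("PhantomSpec", shape = as.integer(shape),
      spacingMM = as.numeric(spacingMM), bodyHU = bodyHU, lungHU = lungHU,
      airHU = airHU, vessel = vessel, disease = disease,
      organIndentation = organIndentation, trachea = trachea,
      noiseSigmaHU = noiseSigmaHU, countVesselsInTruth = countVesselsInTruth,
      seed = as.integer(seed))
}

# 0-based voxel coordinate arrays for dims d = (ns, nr, nc).
.coordArrays <- function(d) {
  list(s = array(rep(0:(d[1] - 1), times = d[2] * d[3]), d),
       r = aperm(array(rep(0:(d[2] - 1), times = d[1] * d[3]),
                       c(d[2], d[1], d[3])), c(2, 1, 3)),
       c = aperm(array(rep(0:(d[3] - 1), times = d[1] * d[2]),
                       c(d[3], d[1], d[2])), c(2, 3, 1)))
}

# 3-D erosion by the 6-neighborhood, iterated k times.
erode3d6 <- function(m, k = 1L) !dilate3d6(!m, k)

# Paint voxels within `radius` (mm) of the segment p0-p1 (voxel coords,
# converted through spacing) into `mask`, restricted to a bounding box.
.paintCapsule <- function(mask, p0, p1, radius, spacing) {
  d <- dim(mask)
  rvox <- radius / spacing
  lo <- pmax(floor(pmin(p0, p1) - rvox) + 1, 1)
  hi <- pmin(ceiling(pmax(p0, p1) + rvox) + 1, d)
  if (any(lo > hi)) return(mask)
  is <- lo[1]:hi[1]; ir <- lo[2]:hi[2]; ic <- lo[3]:hi[3]
  # physical (mm) coordinates of the box
  xs <- (is - 1) * spacing[1]; xr <- (ir - 1) * spacing[2]
  xc <- (ic - 1) * spacing[3]
  q0 <- p0 * spacing; q1 <- p1 * spacing
  u <- q1 - q0; uu <- sum(u^2)
  bs <- array(xs, c(length(is), length(ir), length(ic)))
  br <- aperm(array(xr, c(length(ir), length(is), length(ic))), c(2, 1, 3))
  bc <- aperm(array(xc, c(length(ic), length(is), length(ir))), c(2, 3, 1))
  t <- if (uu > 0)
    pmin(pmax(((bs - q0[1]) * u[1] + (br - q0[2]) * u[2] +
                 (bc - q0[3]) * u[3]) / uu, 0), 1) else 0
  d2 <- (bs - q0[1] - t * u[1])^2 + (br - q0[2] - t * u[2])^2 +
    (bc - q0[3] - t * u[3])^2
  sub <- mask[is, ir, ic]
  sub[d2 <= radius^2] <- TRUE
  mask[is, ir, ic] <- sub
  mask
}

# Random unit vector (isotropic).
.runifDir <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Grow one lung's branching vessel tree; returns the painted mask. Branch
# directions are nudged back toward the lung center when an endpoint
# approaches the lung surface (normalized radius > 0.8), so the tree stays
# mostly intra-pulmonary like real vasculature.
.growVesselTree <- function(mask, start, spacing, nBranches, radiusRange,
                            center, semiAxes) {
  queue <- list(list(p = start, dir = .runifDir(), radius = radiusRange[2]))
  painted <- 0L
  d <- dim(mask)
  rhoOf <- function(p) sqrt(sum(((p - center) / semiAxes)^2))
  while (length(queue) && painted < nBranches) {
    node <- queue[[1]]; queue <- queue[-1]
    len <- stats::runif(1, 8, 16)
    dirn <- node$dir + 0.5 * .runifDir()
    dirn <- dirn / sqrt(sum(dirn^2))
    p1 <- node$p + dirn * len / spacing
    if (rhoOf(p1) > 0.8) {
      toCtr <- (center - node$p)
      toCtr <- toCtr / sqrt(sum(toCtr^2) + 1e-9)
      dirn <- dirn + 1.5 * toCtr
      dirn <- dirn / sqrt(sum(dirn^2))
      p1 <- node$p + dirn * len / spacing
    }
    mask <- .paintCapsule(mask, node$p, p1, node$radius, spacing)
    painted <- painted + 1L
    rnew <- max(node$radius * 0.72, radiusRange[1])
    queue <- c(queue, list(list(p = p1, dir = dirn, radius = rnew),
                           list(p = p1, dir = dirn, radius = rnew)))
  }
  mask
}

# One disease lesion as a local voxel-index set. Returns integer indices
# into the flat array, ordered by distance from the lesion center.
.lesionVoxels <- function(pattern, center, d, spacing) {
  if (pattern == "septal_sheet") {
    nrm <- .runifDir()
    R <- stats::runif(1, 5, 12)
    half <- 0.6  # half-thickness (mm): one-voxel sheets
    rv <- R / spacing
    lo <- pmax(floor(center - rv) + 1, 1); hi <- pmin(ceiling(center + rv) + 1, d)
  } else {
    rad <- if (pattern == "ggo") stats::runif(3, 4, 10) else stats::runif(3, 3, 8)
    rv <- rad / spacing
    lo <- pmax(floor(center - rv) + 1, 1); hi <- pmin(ceiling(center + rv) + 1, d)
  }
  is <- lo[1]:hi[1]; ir <- lo[2]:hi[2]; ic <- lo[3]:hi[3]
  nb <- c(length(is), length(ir), length(ic))
  bs <- (array(is, nb) - 1 - center[1]) * spacing[1]
  br <- (aperm(array(ir, nb[c(2, 1, 3)]), c(2, 1, 3)) - 1 - center[2]) * spacing[2]
  bc <- (aperm(array(ic, nb[c(3, 1, 2)]), c(2, 3, 1)) - 1 - center[3]) * spacing[3]
  if (pattern == "septal_sheet") {
    inl <- abs(bs * nrm[1] + br * nrm[2] + bc * nrm[3]) <= half &
      (bs^2 + br^2 + bc^2) <= R^2
  } else {
    inl <- (bs / rad[1])^2 + (br / rad[2])^2 + (bc / rad[3])^2 <= 1
  }
  w <- which(inl)
  if (!length(w)) return(integer(0))
  # map box indices to flat indices
  aw <- arrayInd(w, nb)
  flat <- (is[aw[, 1]]) + (ir[aw[, 2]] - 1) * d[1] + (ic[aw[, 3]] - 1) * d[1] * d[2]
  dist <- bs[w]^2 + br[w]^2 + bc[w]^2
  flat[order(dist, flat)]
}

#' Generate a synthetic thoracic CT phantom with ground truth
#'
#' Deterministic for a fixed specification (the seed lives in the spec);
#' truth masks are recorded before noise. Disease is painted lesion by
#' lesion until the achieved fraction of lung volume matches the target to
#' within one voxel (the last lesion is trimmed, nearest-to-center voxels
#' kept), so phantoms with the same seed and increasing targets have nested
#' disease masks.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list(volume = \linkS4class{CTVolume},
#'   truth = \linkS4class{PhantomTruth}).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@shape
  sp <- spec@spacingMM
  .withSeed(spec@seed, {
    co <- .coordArrays(d)
    ctrS <- (d[1] - 1) / 2; ctrR <- (d[2] - 1) / 2; ctrC <- (d[3] - 1) / 2
    body <- ((co$r - ctrR) / (0.44 * d[2]))^2 +
      ((co$c - ctrC) / (0.46 * d[3]))^2 <= 1

    aS <- 0.42 * d[1]; aR <- 0.30 * d[2]; aC <- 0.17 * d[3]
    off <- 0.235 * d[3]
    lungOf <- function(cc) ((co$s - ctrS) / aS)^2 + ((co$r - ctrR) / aR)^2 +
      ((co$c - cc) / aC)^2 <= 1
    lungL <- lungOf(ctrC - off)
    lungR <- lungOf(ctrC + off)
    lungRaw <- lungL | lungR

    trachea <- array(FALSE, d)
    if (isTRUE(spec@trachea$on)) {
      rad <- spec@trachea$radiusMM
      trachea <- co$s >= 0.7 * d[1] &
        ((co$r - ctrR) * sp[2])^2 + ((co$c - ctrC) * sp[3])^2 <= rad^2
      trachea <- trachea & body & !lungRaw
    }

    indent <- array(FALSE, d)
    sphere <- array(FALSE, d)
    if (isTRUE(spec@organIndentation$on)) {
      rs <- (3 * spec@organIndentation$volumeMM3 / (2 * pi))^(1 / 3)
      cen <- c(ctrS - aS, ctrR, ctrC + off)  # inferior pole of the right lung
      sphere <- ((co$s - cen[1]) * sp[1])^2 + ((co$r - cen[2]) * sp[2])^2 +
        ((co$c - cen[3]) * sp[3])^2 <= rs^2
      indent <- sphere & lungRaw
    }
    lungTrue <- lungRaw & !sphere

    hu <- array(spec@airHU, d)
    hu[body] <- spec@bodyHU
    hu[lungTrue] <- spec@lungHU
    hu[trachea] <- spec@airHU

    interior <- erode3d6(lungTrue, 2L) & !indent

    vessel <- array(FALSE, d)
    if (spec@vessel$nBranches > 0) {
      for (cc in c(ctrC - off, ctrC + off)) {
        vessel <- .growVesselTree(vessel, start = c(ctrS, ctrR, cc),
                                  spacing = sp,
                                  nBranches = spec@vessel$nBranches,
                                  radiusRange = spec@vessel$radiusRangeMM,
                                  center = c(ctrS, ctrR, cc),
                                  semiAxes = c(aS, aR, aC))
      }
      vessel <- vessel & interior
      hu[vessel] <- spec@vessel$hu
    }

    disease <- array(FALSE, d)
    tf <- spec@disease$targetFraction
    if (tf > 0) {
      Ltrue <- sum(lungTrue)
      targetVox <- round(tf * Ltrue)
      avail <- interior & !vessel
      if (spec@disease$minRho > 0) {
        rho <- pmin(
          sqrt(((co$s - ctrS) / aS)^2 + ((co$r - ctrR) / aR)^2 +
                 ((co$c - (ctrC - off)) / aC)^2),
          sqrt(((co$s - ctrS) / aS)^2 + ((co$r - ctrR) / aR)^2 +
                 ((co$c - (ctrC + off)) / aC)^2))
        avail <- avail & rho >= spec@disease$minRho
      }
      availIdx <- which(avail)
      if (length(availIdx) < targetVox)
        stop("infeasible disease target fraction ", tf,
             " for the available lung volume")
      wgt <- NULL
      if (isTRUE(spec@disease$peripheralBias)) {
        rhoA <- pmin(
          sqrt(((co$s - ctrS) / aS)^2 + ((co$r - ctrR) / aR)^2 +
                 ((co$c - (ctrC - off)) / aC)^2),
          sqrt(((co$s - ctrS) / aS)^2 + ((co$r - ctrR) / aR)^2 +
                 ((co$c - (ctrC + off)) / aC)^2))
        wgt <- 0.1 + rhoA[availIdx]^2
      }
      mix <- spec@disease$mix / sum(spec@disease$mix)
      huOf <- c(septal_sheet = -300, ggo = -600, consolidation = 20)
      achieved <- 0L
      guard <- 0L
      while (achieved < targetVox) {
        guard <- guard + 1L
        if (guard > 5000L)
          stop("infeasible disease target fraction ", tf,
               ": lesion placement did not converge")
        pattern <- sample(names(mix), 1L, prob = mix)
        ci <- if (is.null(wgt)) sample(length(availIdx), 1L)
              else sample(length(availIdx), 1L, prob = wgt)
        center <- arrayInd(availIdx[ci], d)[1, ] - 1  # 0-based
        vox <- .lesionVoxels(pattern, as.numeric(center), d, sp)
        vox <- vox[avail[vox] & !disease[vox]]
        if (!length(vox)) next
        room <- targetVox - achieved
        if (length(vox) > room) vox <- vox[seq_len(room)]
        disease[vox] <- TRUE
        hu[vox] <- huOf[[pattern]]
        achieved <- achieved + length(vox)
      }
    }

    if (spec@noiseSigmaHU > 0)
      hu <- hu + stats::rnorm(length(hu), 0, spec@noiseSigmaHU)
    hu <- array(pmin(pmax(round(hu), -1024), 3071), d)

    gr <- sprintf("phantom-seed%d", spec@seed)
    interTrue <- disease | (vessel & spec@countVesselsInTruth)
    Ltrue <- sum(lungTrue)
    Itrue <- sum(interTrue)
    vol <- ctVolume(hu, spacing = sp,
                    sourceMeta = list(gridRef = gr, phantom = TRUE,
                                      seed = spec@seed))
    truth <- new("PhantomTruth",
                 lungMaskTrue = binaryMask(lungTrue, "lung_final", gr),
                 interstitiumMaskTrue = binaryMask(interTrue, "interstitium", gr),
                 vesselMaskTrue = binaryMask(vessel, "generic", gr),
                 diseaseMaskTrue = binaryMask(disease, "generic", gr),
                 indentationMask = binaryMask(indent, "hole", gr),
                 tracheaMask = binaryMask(trachea, "generic", gr),
                 trueElvar = if (Ltrue > 0) (Ltrue - Itrue) / Ltrue else 1,
                 spec = spec)
    list(volume = vol, truth = truth)
  })
}
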