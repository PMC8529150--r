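#' @useDynLib elvarkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' CTVolume: a calibrated 3-D CT intensity grid
#'
#' Holds a chest CT volume in Hounsfield units (HU) on a regular lattice.
#' The axis convention everywhere in this package is \code{(slice, row, col)}
#' with the slice axis running caudo-cranially (slice 1 is the most caudal);
#' voxel indices are 0-based in all physical-coordinate computations.
#' Calibration (raw * slope + intercept) is applied exactly once, at load
#' time; all downstream modules assume HU.
#'
#' @slot data 3-D numeric array of HU values, dim = (slice, row, col).
#' @slot spacing numeric(3), voxel spacing in mm as (slice, row, col).
#' @slot origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @slot slicePositions numeric, strictly increasing physical positions (mm)
#'   of the slices along the scan axis.
#' @slot sourceMeta free-form provenance list (series UID, rescale slope and
#'   intercept as read, vendor string, file paths).
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 slicePositions = "numeric", sourceMeta = "list"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), sourceMeta = list())
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must have exactly 3 axes")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  sp <- object@slicePositions
  if (length(sp)) {
    if (length(sp) != dim(object@data)[1L])
      msg <- c(msg, "slicePositions length must equal the number of slices")
    if (any(diff(sp) <= 0))
      msg <- c(msg, "slice positions must be strictly increasing (duplicates are an error)")
  }
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a boolean grid bound to a CTVolume lattice
#'
#' @slot data 3-D logical array, same dim as the bound volume.
#' @slot gridRef character identifier of the lattice the mask lives on.
#' @slot role one of \code{"coarse_air"}, \code{"filled_contour"},
#'   \code{"hole"}, \code{"lung_final"}, \code{"interstitium"}, or
#'   \code{"generic"}.
#' @slot metadata free-form list (diagnostics, provenance).
#' @export
setClass("BinaryMask",
  representation(data = "array", gridRef = "character", role = "character",
                 metadata = "list"),
  prototype(gridRef = "", role = "generic", metadata = list())
)

.maskRoles <- c("coarse_air", "filled_contour", "hole", "lung_final",
                "interstitium", "generic")

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "mask data must have exactly 3 axes")
  if (!is.logical(object@data))
    msg <- c(msg, "mask data must be logical")
  if (any(is.na(object@data)))
    msg <- c(msg, "mask data must not contain NA")
  if (!object@role %in% .maskRoles)
    msg <- c(msg, paste("role must be one of:", paste(.maskRoles, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Parameters of the four-stage lung segmentation
#'
#' Houses every tunable constant of the segmentation pipeline. Thresholds are
#' in HU, geometric tolerances in mm or mm^3 so they are spacing-independent.
#'
#' @slot airThresholdHU HU below which a voxel counts as aerated (default
#'   -500, the conventional aerated/soft-tissue divide).
#' @slot gaussianSigmaMM sigma (mm) of the per-slice Gaussian used to smooth
#'   the binary lung indicator before the Laplacian (default 1.0).
#' @slot holeMinVolumeMM3 minimum volume (mm^3) for a dense enclosed
#'   structure to count as a mask hole rather than a vessel (default 500).
#' @slot shrinkMaxIters cap on contour-shrinkage iterations (default 50).
#' @slot shrinkToleranceVoxels allowed residual symmetric difference at
#'   convergence (default 0).
#' @slot connectivity2D in-plane connectivity for 2-D components, 4 or 8.
#' @slot minLungComponentMM3 minimum 3-D component volume kept in the coarse
#'   air mask (default 10000 mm^3).
#' @slot excludeAirways drop the tracheal air column (default TRUE).
#' @export
setClass("SegmentationParams",
  representation(airThresholdHU = "numeric", gaussianSigmaMM = "numeric",
                 holeMinVolumeMM3 = "numeric", shrinkMaxIters = "integer",
                 shrinkToleranceVoxels = "integer", connectivity2D = "integer",
                 minLungComponentMM3 = "numeric", excludeAirways = "logical")
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  num <- c(object@airThresholdHU, object@gaussianSigmaMM,
           object@holeMinVolumeMM3, object@minLungComponentMM3)
  if (any(!is.finite(num))) msg <- c(msg, "all scalar parameters must be finite")
  if (object@airThresholdHU < -1024 || object@airThresholdHU > 3071)
    msg <- c(msg, "airThresholdHU must lie in the physical HU range [-1024, 3071]")
  if (object@gaussianSigmaMM <= 0) msg <- c(msg, "gaussianSigmaMM must be > 0")
  if (object@shrinkMaxIters < 1L) msg <- c(msg, "shrinkMaxIters must be >= 1")
  if (!object@connectivity2D %in% c(4L, 8L))
    msg <- c(msg, "connectivity2D must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' Contour field produced by the lung contour detection stage
#'
#' @slot smoothed per-slice Gaussian-smoothed mask indicator.
#' @slot laplacian per-slice Laplacian of the smoothed indicator.
#' @slot zeroCrossings single-voxel-thick zero-crossing set (BinaryMask).
#' @slot innerBoundary zero crossings on the aerated (interior) side.
#' @slot outerBoundary zero crossings on the dense (exterior) side.
#' @export
setClass("ContourField",
  representation(smoothed = "array", laplacian = "array",
                 zeroCrossings = "BinaryMask", innerBoundary = "BinaryMask",
                 outerBoundary = "BinaryMask")
)

setValidity("ContourField", function(object) {
  msg <- character()
  zc <- object@zeroCrossings@data
  ib <- object@innerBoundary@data
  ob <- object@outerBoundary@data
  if (any(ib & ob)) msg <- c(msg, "inner and outer boundaries must be disjoint")
  if (any((ib | ob) & !zc))
    msg <- c(msg, "zero-crossing set must contain both boundary sets")
  if (length(msg)) msg else TRUE
})

#' Result of the four-stage lung segmentation
#'
#' @slot lungMask final lung mask (role \code{lung_final}).
#' @slot L total lung voxel count, \code{popcount(lungMask)}.
#' @slot stages named list of intermediate masks for audit:
#'   \code{coarse_air}, \code{contour_filled}, \code{hole}, \code{pre_shrink}.
#' @slot contours the ContourField of stage 2.
#' @slot paramsUsed the SegmentationParams that produced the result.
#' @slot diagnostics character vector of warning-level diagnostics.
#' @export
setClass("LungSegmentation",
  representation(lungMask = "BinaryMask", L = "numeric", stages = "list",
                 contours = "ContourField", paramsUsed = "SegmentationParams",
                 diagnostics = "character")
)

setValidity("LungSegmentation", function(object) {
  msg <- character()
  if (object@L != sum(object@lungMask@data))
    msg <- c(msg, "L must equal popcount(lungMask)")
  if (object@L < 0) msg <- c(msg, "L must be >= 0")
  st <- object@stages
  if (all(c("contour_filled", "hole") %in% names(st))) {
    allowed <- st$contour_filled@data & !st$hole@data
    if (any(object@lungMask@data & !allowed))
      msg <- c(msg, "lungMask must be contained in contour_filled \\ hole")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the curvature-based interstitial enhancement
#'
#' @slot scalesMM Gaussian scales (mm) of the multi-scale Hessian analysis
#'   (default 0.7, 1.4, 2.8; strictly increasing).
#' @slot densityFloorHU voxels at least this dense are interstitial
#'   candidates regardless of curvature (default -700); captures
#'   ground-glass and consolidation interiors, which are curvature-free.
#' @slot sheetnessThreshold normalized geometry-score threshold in [0,1]
#'   (default 0.35).
#' @slot includeVesselsInI enable the tubular (vessel) branch of the
#'   geometry score (default TRUE).
#' @slot minComponentVoxels components smaller than this are dropped from
#'   the interstitium mask (default 3).
#' @export
setClass("EnhancementParams",
  representation(scalesMM = "numeric", densityFloorHU = "numeric",
                 sheetnessThreshold = "numeric", includeVesselsInI = "logical",
                 minComponentVoxels = "integer")
)

setValidity("EnhancementParams", function(object) {
  msg <- character()
  s <- object@scalesMM
  if (!length(s) || any(s <= 0) || any(diff(s) <= 0))
    msg <- c(msg, "scalesMM must be positive and strictly increasing")
  if (object@sheetnessThreshold < 0 || object@sheetnessThreshold > 1)
    msg <- c(msg, "sheetnessThreshold must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Interstitial enhancement result
#'
#' @slot interstitiumMask in-lung interstitial voxels (role
#'   \code{interstitium}).
#' @slot I interstitial voxel count, \code{popcount(interstitiumMask)}.
#' @slot scoreField per-voxel enhancement score in [0,1].
#' @slot paramsUsed the EnhancementParams used.
#' @export
setClass("InterstitialMap",
  representation(interstitiumMask = "BinaryMask", I = "numeric",
                 scoreField = "array", paramsUsed = "EnhancementParams")
)

setValidity("InterstitialMap", function(object) {
  msg <- character()
  if (object@I != sum(object@interstitiumMask@data))
    msg <- c(msg, "I must equal popcount(interstitiumMask)")
  if (length(msg)) msg else TRUE
})

#' Effective Lung Ventilation Area Ratio result
#'
#' ELVAR = (L - I) / L, the fraction of lung voxels free of interstitial
#' structures; lower values mean more extensive interstitial involvement.
#'
#' @slot L total lung voxel count.
#' @slot I interstitial voxel count.
#' @slot elvar (L - I)/L, or NA when undefined (L = 0); check
#'   \code{isElvarDefined()}.
#' @slot defined logical, FALSE iff L = 0.
#' @slot perSlice data.frame with columns slice, L_s, I_s, elvar_s
#'   (elvar_s is NA where L_s = 0).
#' @slot paramsFingerprint hash of all parameters used.
#' @slot provenance input identifier.
#' @export
setClass("ElvarResult",
  representation(L = "numeric", I = "numeric", elvar = "numeric",
                 defined = "logical", perSlice = "data.frame",
                 paramsFingerprint = "character", provenance = "character")
)

setValidity("ElvarResult", function(object) {
  msg <- character()
  if (object@I > object@L) msg <- c(msg, "I must not exceed L")
  if (object@defined) {
    if (object@L <= 0) msg <- c(msg, "defined result requires L > 0")
    else if (abs(object@elvar - (object@L - object@I) / object@L) > 1e-12)
      msg <- c(msg, "elvar must equal (L - I)/L")
  }
  ps <- object@perSlice
  if (nrow(ps)) {
    if (sum(ps$L_s) != object@L) msg <- c(msg, "per-slice L_s must sum to L")
    if (sum(ps$I_s) != object@I) msg <- c(msg, "per-slice I_s must sum to I")
  }
  if (length(msg)) msg else TRUE
})

#' Digital thoracic phantom specification
#'
#' Describes a synthetic chest CT: an elliptical soft-tissue body in exterior
#' air, two ellipsoidal air-filled lungs, a procedurally grown vessel tree,
#' parameterized interstitial disease (septal sheets, ground-glass, blobs of
#' consolidation), an optional diaphragm-level organ indentation (the "mask
#' hole" geometry), an optional central tracheal air column, and Gaussian HU
#' noise.
#'
#' @slot shape integer(3) voxel dims (slice, row, col), default 40x128x128.
#' @slot spacingMM numeric(3) voxel spacing in mm, default (1,1,1).
#' @slot bodyHU,lungHU,airHU tissue HU values (defaults +40, -850, -1000).
#' @slot vessel list(nBranches, radiusRangeMM, hu) for the per-lung vessel
#'   tree.
#' @slot disease list(mix, targetFraction, peripheralBias): pattern mix over
#'   septal_sheet/ggo/consolidation, target fraction of lung volume in
#'   [0, 0.5], and peripheral placement bias.
#' @slot organIndentation list(on, volumeMM3).
#' @slot trachea list(on, radiusMM).
#' @slot noiseSigmaHU Gaussian HU noise sd, default 20.
#' @slot countVesselsInTruth whether the ground-truth interstitium counts
#'   vessels (default TRUE, matching the default analysis configuration).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacingMM = "numeric", bodyHU = "numeric",
                 lungHU = "numeric", airHU = "numeric", vessel = "list",
                 disease = "list", organIndentation = "list",
                 trachea = "list", noiseSigmaHU = "numeric",
                 countVesselsInTruth = "logical", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msg <- c(msg, "shape must be 3 dims, each >= 8")
  tf <- object@disease$targetFraction
  if (is.null(tf) || tf < 0 || tf > 0.5)
    msg <- c(msg, "disease targetFraction must lie in [0, 0.5]")
  hu <- c(object@bodyHU, object@lungHU, object@airHU)
  if (any(hu < -1024 | hu > 3071))
    msg <- c(msg, "tissue HU values must lie in [-1024, 3071]")
  if (length(msg)) msg else TRUE
})

#' Ground truth paired with a generated phantom
#'
#' @slot lungMaskTrue true lung mask (lung cavities minus any organ
#'   indentation).
#' @slot interstitiumMaskTrue true interstitial compartment: disease, plus
#'   vessels when the spec counts them.
#' @slot vesselMaskTrue true vessel voxels.
#' @slot diseaseMaskTrue true disease voxels (subset of interstitium).
#' @slot indentationMask voxels of the organ indentation carved out of the
#'   lung (empty when off).
#' @slot tracheaMask voxels of the tracheal air column (empty when off).
#' @slot trueElvar (L_true - I_true)/L_true.
#' @slot spec the generating PhantomSpec.
#' @export
setClass("PhantomTruth",
  representation(lungMaskTrue = "BinaryMask",
                 interstitiumMaskTrue = "BinaryMask",
                 vesselMaskTrue = "BinaryMask", diseaseMaskTrue = "BinaryMask",
                 indentationMask = "BinaryMask", tracheaMask = "BinaryMask",
                 trueElvar = "numeric", spec = "PhantomSpec")
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (any(object@interstitiumMaskTrue@data & !object@lungMaskTrue@data))
    msg <- c(msg, "true interstitium must be contained in the true lung")
  if (object@trueElvar < 0 || object@trueElvar > 1)
    msg <- c(msg, "trueElvar must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Emulates a two-group cohort (e.g. early-death vs early-survival) with
#' group-specific ELVAR distributions, stated as median and interquartile
#' range on [0,1] and realized as logit-normal draws, plus a
#' piecewise-constant hazard per group with administrative censoring.
#'
#' @slot nPerGroup integer, one value for both groups or one per group (A, B).
#' @slot elvarA,elvarB list(median, iqr = c(q25, q75)).
#' @slot hazardA,hazardB list(breaks, rates): piecewise-constant hazard in
#'   events per month; breaks are the upper ends of all but the last piece.
#' @slot followUpMonths administrative censoring horizon (default 12).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", elvarA = "list", elvarB = "list",
                 hazardA = "list", hazardB = "list",
                 followUpMonths = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (any(object@nPerGroup < 2L)) msg <- c(msg, "need n >= 2 per group")
  for (el in list(object@elvarA, object@elvarB)) {
    if (el$median <= 0 || el$median >= 1)
      msg <- c(msg, "group ELVAR medians must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' ROC analysis result
#'
#' @slot thresholds candidate cutoffs (midpoints between consecutive
#'   distinct scores, with outer sentinels).
#' @slot sensitivity,specificity operating characteristics per threshold.
#' @slot auc trapezoidal area under the empirical ROC curve.
#' @slot bestCutoff Youden-maximizing cutoff.
#' @slot youdenJ J = sensitivity + specificity - 1 at the best cutoff.
#' @slot direction "low-positive" or "high-positive".
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric",
                 bestCutoff = "numeric", youdenJ = "numeric",
                 direction = "character")
)

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
      any(object@specificity < 0 | object@specificity > 1))
    msg <- c(msg, "sensitivity and specificity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
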