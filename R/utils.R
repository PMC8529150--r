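#' Construct a BinaryMask
#'
#' @param data 3-D logical array (slice, row, col).
#' @param role mask role, see \linkS4class{BinaryMask}.
#' @param gridRef lattice identifier binding the mask to its source volume.
#' @param metadata optional free-form list.
#' @export
binaryMask <- function(data, role = "generic", gridRef = "", metadata = list()) {
  storage.mode(data) <- "logical"
  new("BinaryMask", data = data, role = role, gridRef = gridRef,
      metadata = metadata)
}

#' Construct a CTVolume
#'
#' @param data 3-D numeric array in HU, dim = (slice, row, col).
#' @param spacing numeric(3) voxel spacing (slice, row, col) in mm.
#' @param origin numeric(3) physical position of voxel (0,0,0) in mm.
#' @param slicePositions strictly increasing physical slice positions; by
#'   default derived from origin and slice spacing.
#' @param sourceMeta free-form provenance list.
#' @export
ctVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     slicePositions = NULL, sourceMeta = list()) {
  storage.mode(data) <- "double"
  if (is.null(slicePositions))
    slicePositions <- origin[1] + (seq_len(dim(data)[1]) - 1) * spacing[1]
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), slicePositions = as.numeric(slicePositions),
      sourceMeta = sourceMeta)
}

#' Dice overlap coefficient between two masks
#'
#' Dice = 2|A intersect B| / (|A| + |B|); 1 for identical non-empty masks.
#'
#' @param a,b BinaryMask objects or logical arrays on the same lattice.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "BinaryMask")) a <- a@data
  if (is(b, "BinaryMask")) b <- b@data
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Shift a 3-D array by (ds, dr, dc); vacated voxels take `fill`.
shift3d <- function(a, ds = 0L, dr = 0L, dc = 0L, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, k) {
    # target indices t receive a[t - k]
    t0 <- max(1L, 1L + k); t1 <- min(n, n + k)
    if (t0 > t1) return(NULL)
    list(t = t0:t1, s = (t0 - k):(t1 - k))
  }
  i1 <- src(d[1], ds); i2 <- src(d[2], dr); i3 <- src(d[3], dc)
  if (is.null(i1) || is.null(i2) || is.null(i3)) return(out)
  out[i1$t, i2$t, i3$t] <- a[i1$s, i2$s, i3$s]
  out
}

# In-plane (per-slice) erosion by the 4-neighborhood structuring element.
erodeInPlane4 <- function(m) {
  m & shift3d(m, 0L, 1L, 0L) & shift3d(m, 0L, -1L, 0L) &
    shift3d(m, 0L, 0L, 1L) & shift3d(m, 0L, 0L, -1L)
}

# In-plane dilation by the 4- or 8-neighborhood.
dilateInPlane <- function(m, connectivity = 8L) {
  out <- m | shift3d(m, 0L, 1L, 0L) | shift3d(m, 0L, -1L, 0L) |
    shift3d(m, 0L, 0L, 1L) | shift3d(m, 0L, 0L, -1L)
  if (connectivity == 8L)
    out <- out | shift3d(m, 0L, 1L, 1L) | shift3d(m, 0L, 1L, -1L) |
      shift3d(m, 0L, -1L, 1L) | shift3d(m, 0L, -1L, -1L)
  out
}

# Full 3-D (6-neighborhood) dilation, iterated `k` times.
dilate3d6 <- function(m, k = 1L) {
  for (i in seq_len(k)) {
    m <- m | shift3d(m, 1L, 0L, 0L) | shift3d(m, -1L, 0L, 0L) |
      shift3d(m, 0L, 1L, 0L) | shift3d(m, 0L, -1L, 0L) |
      shift3d(m, 0L, 0L, 1L) | shift3d(m, 0L, 0L, -1L)
  }
  m
}

# Sampled, normalized Gaussian kernel; sigma in voxels, truncated at 4 sigma.
gaussianKernel <- function(sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3-D array. sigmaMM is converted per axis
# through `spacing`; axes with NA sigma are left unfiltered.
gaussianSmooth3d <- function(a, sigmaMM, spacing, axes = 1:3) {
  d <- dim(a)
  v <- as.numeric(a)
  for (ax in axes) {
    s <- sigmaMM / spacing[ax]
    if (!is.finite(s) || s <= 0) next
    v <- cpp_conv_axis(v, d, gaussianKernel(s), ax)
  }
  array(v, d)
}

# Connected-component labelling (wrapper over the compiled routine).
# connectivity 4/8 = per-slice 2-D; 6/26 = 3-D.
labelComponents <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  array(cpp_label(as.logical(mask), d, as.integer(connectivity)), d)
}

# Component sizes (in voxels) of a labelled array; names are label ids.
componentSizes <- function(lab) {
  tab <- tabulate(lab[lab > 0L])
  stats::setNames(tab, seq_along(tab))
}
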