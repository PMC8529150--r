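#' Load a NIfTI volume as a CTVolume
#'
#' Axes are permuted from NIfTI's on-disk (x, y, z) order to this package's
#' (slice, row, col) convention with slice = z; spacing is taken from the
#' affine. Values are assumed to be in HU already (documented contract: no
#' rescaling is applied).
#'
#' @param path path to a .nii or .nii.gz file containing a single 3-D volume.
#' @return a \linkS4class{CTVolume}.
#' @export
loadNifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a single 3-D volume, got ", length(d), "-D data: ", path)
  xf <- RNifti::xform(img)
  if (all(abs(xf[1:3, 1:3]) < .Machine$double.eps))
    stop("missing affine metadata in ", path)
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive voxel dimensions in ", path)
  arr <- aperm(array(as.numeric(img), d), c(3, 2, 1))
  orig <- as.numeric(xf[1:3, 4])  # (x, y, z) translation
  ctVolume(arr, spacing = rev(pd), origin = rev(orig),
           sourceMeta = list(path = path, format = "nifti"))
}

# Write a (slice, row, col) array to NIfTI with given spacing and origin.
.writeNiftiArray <- function(data, spacing, origin, path) {
  arr <- aperm(data, c(3, 2, 1))  # to (x, y, z)
  img <- RNifti::asNifti(arr)
  sp <- rev(spacing)
  RNifti::pixdim(img) <- sp
  mat <- diag(c(sp, 1))
  mat[1:3, 4] <- rev(origin)
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save a CTVolume to NIfTI
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param path output .nii or .nii.gz path.
#' @export
saveNifti <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  .writeNiftiArray(vol@data, vol@spacing, vol@origin, path)
}

.maskFormats <- c("nifti", "rds")

#' Save a BinaryMask losslessly
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path; extension must match the format (.nii/.nii.gz
#'   for \code{"nifti"}, .rds for \code{"rds"}).
#' @param format \code{"nifti"} (mask stored as 0/1 integers) or
#'   \code{"rds"} (compressed serialized array).
#' @param spacing voxel spacing recorded in NIfTI output (mm).
#' @export
saveMask <- function(mask, path, format = c("nifti", "rds"),
                     spacing = c(1, 1, 1)) {
  stopifnot(is(mask, "BinaryMask"))
  if (length(format) > 1L) format <- format[1L]
  if (!format %in% .maskFormats)
    stop("unsupported format '", format, "'; supported formats: ",
         paste(.maskFormats, collapse = ", "))
  ext_ok <- switch(format,
    nifti = grepl("\\.nii(\\.gz)?$", path),
    rds = grepl("\\.rds$", path, ignore.case = TRUE))
  if (!ext_ok)
    stop("path extension of '", basename(path),
         "' does not match format '", format, "'")
  if (format == "nifti") {
    .writeNiftiArray(array(as.integer(mask@data), dim(mask@data)),
                     spacing, c(0, 0, 0), path)
  } else {
    saveRDS(list(data = mask@data, role = mask@role, gridRef = mask@gridRef),
            path)
  }
  invisible(path)
}

#' Load a BinaryMask written by saveMask
#'
#' @param path input path.
#' @param format \code{"nifti"} or \code{"rds"}; inferred from the
#'   extension by default.
#' @param role role to assign when the format does not store one (NIfTI).
#' @export
loadMask <- function(path, format = NULL, role = "generic") {
  if (is.null(format)) {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds"
              else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
              else stop("cannot infer mask format from '", basename(path),
                        "'; supported formats: ",
                        paste(.maskFormats, collapse = ", "))
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) stop("mask file is not 3-D: ", path)
    binaryMask(aperm(array(as.numeric(img), d) != 0, c(3, 2, 1)), role = role)
  } else if (format == "rds") {
    x <- readRDS(path)
    binaryMask(x$data, role = x$role, gridRef = x$gridRef)
  } else {
    stop("unsupported format '", format, "'; supported formats: ",
         paste(.maskFormats, collapse = ", "))
  }
}
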