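# The Effective Lung Ventilation Area Ratio: ELVAR = (L - I)/L, where L is
# the total lung voxel count and I the interstitial voxel count. Low ELVAR
# means extensive interstitial involvement and poor ventilation.

#' ELVAR from raw counts
#'
#' Computes (L - I)/L with an explicit undefined marker when L = 0 (the
#' result never propagates NaN).
#'
#' @param L total lung voxel count (>= 0).
#' @param I interstitial voxel count, 0 <= I <= L.
#' @param provenance optional input identifier.
#' @param fingerprint optional parameter fingerprint.
#' @return an \linkS4class{ElvarResult} without per-slice detail.
#' @export
elvarFromCounts <- function(L, I, provenance = "", fingerprint = "") {
  if (I < 0 || L < 0) stop("counts must be non-negative")
  if (I > L) stop("I (", I, ") exceeds L (", L, "): invariant violation upstream")
  defined <- L > 0
  new("ElvarResult", L = as.numeric(L), I = as.numeric(I),
      elvar = if (defined) (L - I) / L else NA_real_,
      defined = defined,
      perSlice = data.frame(slice = integer(), L_s = numeric(),
                            I_s = numeric(), elvar_s = numeric()),
      paramsFingerprint = fingerprint, provenance = provenance)
}

#' Compute ELVAR from a segmentation and an interstitial map
#'
#' The whole-volume ratio is computed from the global counts L and I, not
#' as a mean of per-slice ratios; per-slice counts and ratios are reported
#' alongside, with slices of empty lung marked undefined (NA).
#'
#' @param seg a \linkS4class{LungSegmentation}.
#' @param imap an \linkS4class{InterstitialMap} on the same lattice.
#' @param provenance optional input identifier (defaults to the mask's
#'   grid reference).
#' @return an \linkS4class{ElvarResult}.
#' @export
computeElvar <- function(seg, imap, provenance = NULL) {
  stopifnot(is(seg, "LungSegmentation"), is(imap, "InterstitialMap"))
  lm <- seg@lungMask@data
  im <- imap@interstitiumMask@data
  if (!identical(dim(lm), dim(im)))
    stop("segmentation and interstitial map are not on the same lattice")
  if (any(im & !lm))
    stop("interstitium extends outside the lung mask: invariant violation upstream")
  L <- sum(lm); I <- sum(im)
  Ls <- apply(lm, 1, sum)
  Is <- apply(im, 1, sum)
  perSlice <- data.frame(slice = seq_along(Ls), L_s = as.numeric(Ls),
                         I_s = as.numeric(Is),
                         elvar_s = ifelse(Ls > 0, (Ls - Is) / Ls, NA_real_))
  defined <- L > 0
  new("ElvarResult", L = as.numeric(L), I = as.numeric(I),
      elvar = if (defined) (L - I) / L else NA_real_,
      defined = defined, perSlice = perSlice,
      paramsFingerprint = paramsFingerprint(seg@paramsUsed, imap@paramsUsed),
      provenance = provenance %||% seg@lungMask@gridRef)
}

# Stable row formatting shared by the CSV writer and the JSON round trip.
.reportRows <- function(results) {
  data.frame(
    provenance = vapply(results, function(r) r@provenance, ""),
    L = vapply(results, function(r) r@L, 0),
    I = vapply(results, function(r) r@I, 0),
    elvar = vapply(results, function(r)
      if (r@defined) sprintf("%.4f", r@elvar) else "undefined", ""),
    params_fingerprint = vapply(results, function(r) r@paramsFingerprint, ""),
    stringsAsFactors = FALSE)
}

.writeReportCSV <- function(rows, path) {
  con <- file(path, "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  writeLines(paste(colnames(rows), collapse = ","), con)
  for (i in seq_len(nrow(rows)))
    writeLines(paste(c(rows$provenance[i], format(rows$L[i], scientific = FALSE),
                       format(rows$I[i], scientific = FALSE), rows$elvar[i],
                       rows$params_fingerprint[i]), collapse = ","), con)
  invisible(path)
}

#' Write a tabular ELVAR report (CSV and JSON)
#'
#' One row per volume with provenance, L, I, ELVAR (4 decimal places) and
#' the parameter fingerprint, in a stable column order. The JSON twin
#' carries the same rows; \code{elvarReportFromJson} regenerates a
#' byte-identical CSV from it.
#'
#' @param results a list of \linkS4class{ElvarResult} objects (at least 1).
#' @param outPath output CSV path; the JSON twin replaces the extension
#'   with .json.
#' @return invisibly, c(csv, json) paths.
#' @export
elvarReport <- function(results, outPath) {
  if (is(results, "ElvarResult")) results <- list(results)
  if (!length(results)) stop("need at least one result")
  rows <- .reportRows(results)
  jsonPath <- sub("\\.[A-Za-z]+$", ".json", outPath)
  if (identical(jsonPath, outPath)) jsonPath <- paste0(outPath, ".json")
  .writeReportCSV(rows, outPath)
  jsonlite::write_json(rows, jsonPath, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv = outPath, json = jsonPath))
}

#' Regenerate the CSV report from its JSON twin
#'
#' @param jsonPath JSON report written by \code{elvarReport}.
#' @param csvPath output CSV path.
#' @export
elvarReportFromJson <- function(jsonPath, csvPath) {
  rows <- jsonlite::fromJSON(jsonPath)
  rows$L <- as.numeric(rows$L)
  rows$I <- as.numeric(rows$I)
  .writeReportCSV(rows, csvPath)
  invisible(csvPath)
}

#' Run the full analysis pipeline on one volume
#'
#' segment -> enhance -> ELVAR, returning all three results.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param segParams a \linkS4class{SegmentationParams}.
#' @param enhParams an \linkS4class{EnhancementParams}.
#' @param provenance optional input identifier.
#' @return list(segmentation, interstitialMap, result).
#' @export
elvarPipeline <- function(vol, segParams = segmentationParams(),
                          enhParams = enhancementParams(),
                          provenance = NULL) {
  seg <- segmentLungs(vol, segParams)
  imap <- enhanceInterstitium(vol, seg, enhParams)
  res <- computeElvar(seg, imap, provenance = provenance)
  list(segmentation = seg, interstitialMap = imap, result = res)
}
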