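# Minimal single-frame CT DICOM support (explicit VR little endian only).
# Covers the standard tags needed for calibrated volume reconstruction:
# rescale slope/intercept, pixel spacing, image position, series identity.
# Vendor private tags are ignored by design.

.dcmExplicitLE <- "1.2.840.10008.1.2.1"
.dcmCTSopClass <- "1.2.840.10008.5.1.4.1.1.2"
.dcmUIDRoot <- "1.2.826.0.1.3680043.9.7435"

.longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.uint16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}
.uint32le <- function(x) {
  r <- integer(4)
  for (i in 1:4) { r[i] <- x %% 256; x <- x %/% 256 }
  as.raw(r)
}

# Encode one data element (explicit VR little endian).
.dcmElement <- function(group, element, vr, value) {
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH", "PN")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else if (vr == "US") {
    v <- .uint16le(value)
  } else if (vr %in% c("OB", "OW")) {
    v <- value  # already raw
  } else if (vr == "UL") {
    v <- .uint32le(value)
  } else {
    stop("unsupported VR in writer: ", vr)
  }
  head <- c(.uint16le(group), .uint16le(element), charToRaw(vr))
  if (vr %in% .longVRs) {
    c(head, as.raw(c(0L, 0L)), .uint32le(length(v)), v)
  } else {
    if (length(v) > 65535L) stop("value too long for short-form VR ", vr)
    c(head, .uint16le(length(v)), v)
  }
}

# Write one slice file. `elements` is a list of list(group, element, vr,
# value) for the main dataset, already sorted by tag.
.writeDicomFile <- function(path, elements, sopInstanceUID) {
  meta <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcmElement(0x0002, 0x0002, "UI", .dcmCTSopClass),
    .dcmElement(0x0002, 0x0003, "UI", sopInstanceUID),
    .dcmElement(0x0002, 0x0010, "UI", .dcmExplicitLE),
    .dcmElement(0x0002, 0x0012, "UI", paste0(.dcmUIDRoot, ".1"))
  )
  body <- unlist(lapply(elements, function(e)
    .dcmElement(e$group, e$element, e$vr, e$value)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(.dcmElement(0x0002, 0x0000, "UL", length(meta)), meta, body), con)
  invisible(path)
}

#' Write a CTVolume as a single-frame DICOM series
#'
#' One explicit-VR little-endian CT file per slice. Stored pixel values are
#' 16-bit integers with RescaleSlope 1 and RescaleIntercept -1024, so the
#' volume must hold integer HU values (as calibrated CT data does); an error
#' is raised otherwise. Series and SOP instance UIDs are derived
#' deterministically from the volume content.
#'
#' @param vol a \linkS4class{CTVolume} with integer-valued HU data.
#' @param dir output directory (created if absent).
#' @param seriesUID optional series instance UID override.
#' @return invisibly, the vector of files written.
#' @export
writeDicomSeries <- function(vol, dir, seriesUID = NULL) {
  stopifnot(is(vol, "CTVolume"))
  data <- vol@data
  if (max(abs(data - round(data))) > 0)
    stop("DICOM writer stores integer HU; round the volume first")
  intercept <- -1024
  if (min(data) < intercept || max(data) > 31743)
    stop("HU values outside the representable range [-1024, 31743]")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(data)
  if (is.null(seriesUID))
    seriesUID <- paste0(.dcmUIDRoot, ".2.",
                        strtoi(substr(.fnv1a64(paste(d, collapse = "x")), 1, 7),
                               16L))
  studyUID <- paste0(seriesUID, ".0")
  files <- character(d[1])
  for (s in seq_len(d[1])) {
    slice <- data[s, , ]
    stored <- round(slice) - intercept
    pix <- writeBin(as.integer(as.vector(t(stored))),
                    raw(), size = 2L, endian = "little")
    sopUID <- paste0(seriesUID, ".", s)
    z <- vol@slicePositions[s]
    elements <- list(
      list(group = 0x0008, element = 0x0016, vr = "UI", value = .dcmCTSopClass),
      list(group = 0x0008, element = 0x0018, vr = "UI", value = sopUID),
      list(group = 0x0008, element = 0x0060, vr = "CS", value = "CT"),
      list(group = 0x0008, element = 0x0070, vr = "LO", value = "elvarkit"),
      list(group = 0x0018, element = 0x0050, vr = "DS",
           value = format(vol@spacing[1])),
      list(group = 0x0020, element = 0x000D, vr = "UI", value = studyUID),
      list(group = 0x0020, element = 0x000E, vr = "UI", value = seriesUID),
      list(group = 0x0020, element = 0x0013, vr = "IS", value = as.character(s)),
      list(group = 0x0020, element = 0x0032, vr = "DS",
           value = paste(format(c(vol@origin[3], vol@origin[2], z)),
                         collapse = "\\")),
      list(group = 0x0020, element = 0x0037, vr = "DS",
           value = "1\\0\\0\\0\\1\\0"),
      list(group = 0x0028, element = 0x0002, vr = "US", value = 1L),
      list(group = 0x0028, element = 0x0004, vr = "CS", value = "MONOCHROME2"),
      list(group = 0x0028, element = 0x0010, vr = "US", value = d[2]),
      list(group = 0x0028, element = 0x0011, vr = "US", value = d[3]),
      list(group = 0x0028, element = 0x0030, vr = "DS",
           value = paste(format(vol@spacing[2:3]), collapse = "\\")),
      list(group = 0x0028, element = 0x0100, vr = "US", value = 16L),
      list(group = 0x0028, element = 0x0101, vr = "US", value = 16L),
      list(group = 0x0028, element = 0x0102, vr = "US", value = 15L),
      list(group = 0x0028, element = 0x0103, vr = "US", value = 1L),
      list(group = 0x0028, element = 0x1052, vr = "DS",
           value = format(intercept)),
      list(group = 0x0028, element = 0x1053, vr = "DS", value = "1"),
      list(group = 0x7FE0, element = 0x0010, vr = "OW", value = pix)
    )
    files[s] <- file.path(dir, sprintf("slice_%04d.dcm", s))
    .writeDicomFile(files[s], elements, sopUID)
  }
  invisible(files)
}

# Parse one explicit-VR little-endian single-frame file into a tag list.
.readDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) {
    as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
      65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])
  }
  pos <- 133L
  tags <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("non explicit-VR encoding in ", path,
           " (only explicit VR little endian is supported)")
    if (vr %in% .longVRs) {
      len <- u32(pos + 8L); start <- pos + 12L
    } else {
      len <- u16(pos + 6L); start <- pos + 8L
    }
    if (start + len - 1L > n) stop("truncated DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, element)
    val <- raw[seq.int(start, length.out = len)]
    tags[[key]] <- list(vr = vr, bytes = val)
    pos <- start + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  tags
}

.dcmString <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  b <- t$bytes
  pad <- c(as.raw(0L), as.raw(0x20))
  while (length(b) && b[length(b)] %in% pad) b <- b[-length(b)]
  rawToChar(b)
}
.dcmNumbers <- function(tags, key) {
  s <- .dcmString(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcmUS <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  as.integer(t$bytes[1]) + 256L * as.integer(t$bytes[2])
}

#' Load a DICOM series as a calibrated CTVolume
#'
#' Reads every file in a directory, rejects mixed series, sorts slices by
#' physical position along the scan axis, and applies the HU calibration
#' (stored * RescaleSlope + RescaleIntercept) exactly once per file. Loading
#' is independent of on-disk file ordering.
#'
#' @param dir directory containing at least 3 single-frame CT slice files
#'   from one series.
#' @return a \linkS4class{CTVolume}.
#' @export
loadCTSeries <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 3L)
    stop("need at least 3 slice files for a 3-D volume, found ",
         length(files))
  slices <- vector("list", length(files))
  zpos <- numeric(length(files))
  series <- character(length(files))
  pixsp <- matrix(NA_real_, length(files), 2)
  ipp0 <- NULL
  vendor <- NA_character_
  slope1 <- NA_real_; icpt1 <- NA_real_
  for (i in seq_along(files)) {
    f <- files[i]
    tags <- .readDicomFile(f)
    slope <- .dcmNumbers(tags, "0028,1053")
    icpt <- .dcmNumbers(tags, "0028,1052")
    if (is.null(slope) || is.null(icpt))
      stop("missing rescale slope/intercept tags in ", basename(f))
    rows <- .dcmUS(tags, "0028,0010"); cols <- .dcmUS(tags, "0028,0011")
    pixrep <- .dcmUS(tags, "0028,0103")
    bits <- .dcmUS(tags, "0028,0100")
    if (is.null(rows) || is.null(cols) || is.null(bits) || bits != 16L)
      stop("unsupported pixel encoding in ", basename(f))
    pd <- tags[["7FE0,0010"]]
    if (is.null(pd)) stop("no pixel data in ", basename(f))
    stored <- readBin(pd$bytes, "integer", n = rows * cols, size = 2L,
                      signed = !is.null(pixrep) && pixrep == 1L,
                      endian = "little")
    slices[[i]] <- t(matrix(stored, nrow = cols, ncol = rows)) * slope + icpt
    ipp <- .dcmNumbers(tags, "0020,0032")
    zpos[i] <- if (!is.null(ipp)) ipp[3] else {
      sl <- .dcmNumbers(tags, "0020,1041")
      if (is.null(sl)) stop("no slice position information in ", basename(f))
      sl[1]
    }
    if (!is.null(ipp) && is.null(ipp0)) ipp0 <- ipp
    series[i] <- .dcmString(tags, "0020,000E") %||% ""
    ps <- .dcmNumbers(tags, "0028,0030")
    if (!is.null(ps)) pixsp[i, ] <- ps
    if (i == 1L) {
      vendor <- .dcmString(tags, "0008,0070") %||% NA_character_
      slope1 <- slope; icpt1 <- icpt
    }
  }
  if (length(unique(series)) != 1L)
    stop("mixed series: found ", length(unique(series)),
         " distinct series instance UIDs")
  if (any(is.na(pixsp)))
    stop("missing pixel spacing in at least one file")
  if (max(apply(pixsp, 2, function(v) diff(range(v)))) > 1e-6)
    stop("non-uniform in-plane pixel spacing across slices")
  o <- order(zpos)
  zs <- zpos[o]
  if (any(diff(zs) == 0))
    stop("duplicate slice positions are an error")
  dz <- diff(zs)
  modal <- stats::median(dz)
  if (any(dz > 2 * modal + 1e-9))
    stop("slice gap exceeds twice the modal spacing; ",
         "non-contiguous series are rejected rather than interpolated")
  d2 <- dim(slices[[1]])
  arr <- array(0, c(length(files), d2[1], d2[2]))
  for (k in seq_along(o)) arr[k, , ] <- slices[[o[k]]]
  origin <- if (!is.null(ipp0)) c(zs[1], ipp0[2], ipp0[1]) else c(zs[1], 0, 0)
  ctVolume(arr, spacing = c(modal, pixsp[1, 1], pixsp[1, 2]),
           origin = origin, slicePositions = zs,
           sourceMeta = list(seriesUID = series[1], rescaleSlope = slope1,
                             rescaleIntercept = icpt1, vendor = vendor,
                             nFiles = length(files), format = "dicom"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
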