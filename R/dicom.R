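# Minimal DICOM support for uncompressed single-frame axial CT.
#
# Only the subset of DICOM needed to round-trip calibrated CT series is
# implemented: explicit- and implicit-VR little endian, single-frame 16-bit
# MONOCHROME2 pixel data.  Compressed transfer syntaxes, sequences and
# multi-frame enhanced CT are out of scope.

EXPLICIT_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_LE <- "1.2.840.10008.1.2"
CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1458"

# VRs for the tags this reader understands, for implicit-VR parsing.
.dicom_dict <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0020" = "DA",
  "0008,0021" = "DA", "0008,0060" = "CS", "0010,0020" = "LO",
  "0018,0050" = "DS", "0018,1210" = "SH",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7FE0,0010" = "OW")

.tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

.raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

.element <- function(group, element, vr, value) {
  body <- switch(vr,
    US = .raw_uint16(value),
    UL = .raw_uint32(value),
    OW = value,
    UI = .pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    .pad_even(charToRaw(paste(value, collapse = "\\"))))
  head <- c(.raw_uint16(group), .raw_uint16(element))
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)), .raw_uint32(length(body)), body)
  } else {
    c(head, charToRaw(vr), .raw_uint16(length(body)), body)
  }
}

.fmt_ds <- function(x) {
  s <- formatC(x, format = "fg", digits = 10)
  gsub(" ", "", s)
}

#' Write a CT volume as a DICOM series
#'
#' Emits one explicit-VR little-endian single-frame CT file per slice.  HU
#' values are stored as unsigned 16-bit integers with rescale intercept
#' -1024 and slope 1, so the round trip quantizes radiodensity to 1 HU.
#'
#' @param vol a [ct_volume].
#' @param directory output directory (created if needed).
#' @param patient_id,exam_date series identity written into the files;
#'   `exam_date` as `"YYYYMMDD"` or a `Date`.
#' @param series_uid optional series instance UID; a deterministic UID is
#'   derived from patient, date and geometry when omitted.
#' @return invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(vol, directory, patient_id = "PHANTOM",
                               exam_date = "20200101", series_uid = NULL) {
  stopifnot(is_ct_volume(vol))
  if (inherits(exam_date, "Date")) exam_date <- format(exam_date, "%Y%m%d")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$voxels)
  if (is.null(series_uid)) {
    h <- sum(utf8ToInt(paste0(patient_id, exam_date))) %% 99999L
    series_uid <- sprintf("%s.%s.%d.%d.%d", UID_ROOT, exam_date, h, d[1], d[3])
  }
  study_uid <- paste0(series_uid, ".0")
  stored <- round(vol$voxels) + 1024
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sop_uid <- sprintf("%s.%d", series_uid, k)
    # pixel data row-major: DICOM rows are image rows
    px <- .raw_uint16(as.integer(t(stored[, , k])))
    meta <- c(
      .element(0x0002, 0x0002, "UI", CT_SOP_CLASS),
      .element(0x0002, 0x0003, "UI", sop_uid),
      .element(0x0002, 0x0010, "UI", EXPLICIT_LE))
    meta <- c(.element(0x0002, 0x0000, "UL", length(meta)), meta)
    ds <- c(
      .element(0x0008, 0x0016, "UI", CT_SOP_CLASS),
      .element(0x0008, 0x0018, "UI", sop_uid),
      .element(0x0008, 0x0020, "DA", exam_date),
      .element(0x0008, 0x0021, "DA", exam_date),
      .element(0x0008, 0x0060, "CS", "CT"),
      .element(0x0010, 0x0020, "LO", patient_id),
      .element(0x0018, 0x0050, "DS", .fmt_ds(vol$spacing[3])),
      if (nzchar(vol$kernel)) .element(0x0018, 0x1210, "SH", vol$kernel),
      .element(0x0020, 0x000D, "UI", study_uid),
      .element(0x0020, 0x000E, "UI", series_uid),
      .element(0x0020, 0x0013, "IS", as.character(k)),
      .element(0x0020, 0x0032, "DS",
               .fmt_ds(c(0, 0, vol$slice_z[k]))),
      .element(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      .element(0x0028, 0x0002, "US", 1L),
      .element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .element(0x0028, 0x0010, "US", d[1]),
      .element(0x0028, 0x0011, "US", d[2]),
      .element(0x0028, 0x0030, "DS", .fmt_ds(vol$spacing[1:2])),
      .element(0x0028, 0x0100, "US", 16L),
      .element(0x0028, 0x0101, "US", 16L),
      .element(0x0028, 0x0102, "US", 15L),
      .element(0x0028, 0x0103, "US", 0L),
      .element(0x0028, 0x1052, "DS", "-1024"),
      .element(0x0028, 0x1053, "DS", "1"),
      .element(0x7FE0, 0x0010, "OW", px))
    paths[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(paths)
}

.parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(r) >= 132 && rawToChar(r[129:132]) == "DICM") pos <- 133L
  u16 <- function(at) sum(as.integer(r[at:(at + 1)]) * c(1, 256))
  u32 <- function(at) sum(as.integer(r[at:(at + 3)]) * c(1, 256, 65536, 16777216))
  elems <- new.env(parent = emptyenv())
  syntax <- EXPLICIT_LE

  read_one <- function(pos, explicit) {
    group <- u16(pos); element <- u16(pos + 2)
    key <- .tag_key(group, element)
    if (explicit) {
      vr <- rawToChar(r[(pos + 4):(pos + 5)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8); body_at <- pos + 12L
      } else {
        len <- u16(pos + 6); body_at <- pos + 8L
      }
    } else {
      vr <- if (key %in% names(.dicom_dict)) .dicom_dict[[key]] else "UN"
      len <- u32(pos + 4); body_at <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    list(group = group, element = element, key = key, vr = vr,
         body_at = body_at, len = len, next_at = body_at + len)
  }
  decode <- function(e) {
    body <- if (e$len > 0) r[e$body_at:(e$body_at + e$len - 1)] else raw(0)
    switch(e$vr,
      US = readBin(body, "integer", n = e$len / 2, size = 2,
                   signed = FALSE, endian = "little"),
      UL = readBin(body, "integer", n = e$len / 4, size = 4, endian = "little"),
      OW = body,
      DS = as.numeric(strsplit(trimws(rawToChar(body)), "\\\\")[[1]]),
      IS = as.integer(strsplit(trimws(rawToChar(body)), "\\\\")[[1]]),
      trimws(gsub("\\x00", "", rawToChar(body), useBytes = TRUE)))
  }

  # file meta group (always explicit LE)
  while (pos + 7 <= length(r) && u16(pos) == 0x0002) {
    e <- read_one(pos, explicit = TRUE)
    if (e$key == "0002,0010") syntax <- decode(e)
    pos <- e$next_at
  }
  if (!syntax %in% c(EXPLICIT_LE, IMPLICIT_LE))
    stop("unsupported DICOM transfer syntax: ", syntax)
  explicit <- syntax == EXPLICIT_LE
  while (pos + 7 <= length(r)) {
    e <- read_one(pos, explicit)
    if (e$key %in% names(.dicom_dict) || e$key == "7FE0,0010")
      assign(e$key, decode(e), envir = elems)
    pos <- e$next_at
  }
  as.list(elems)
}

.require_tag <- function(el, key, what, path) {
  if (is.null(el[[key]]))
    stop(sprintf("DICOM file '%s' is missing %s (%s)", basename(path), what, key))
  el[[key]]
}

#' Read a DICOM series into a calibrated CT volume
#'
#' Reads every single-frame CT file in `directory`, rescales stored values to
#' Hounsfield units via the rescale slope/intercept, and sorts the slices
#' into canonical superior-to-inferior order regardless of on-disk file
#' order.  Files from more than one series UID, or files lacking pixel
#' spacing or rescale tags, are rejected.
#'
#' @param directory directory containing one DICOM series.
#' @param sentinel_hu padding cutoff passed to [ct_volume()].
#' @return list with elements `volume` (a [ct_volume]) and `metadata`
#'   (patient_id, exam_date, kernel, contrast_flag).
#' @export
read_dicom_series <- function(directory, sentinel_hu = -1500) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("DICOM series directory must contain at least 2 slices")
  parsed <- lapply(files, function(f) {
    el <- tryCatch(.parse_dicom_file(f),
                   error = function(e) stop(sprintf(
                     "failed to parse DICOM file '%s': %s",
                     basename(f), conditionMessage(e))))
    el
  })
  series <- vapply(seq_along(parsed), function(i)
    as.character(.require_tag(parsed[[i]], "0020,000E", "SeriesInstanceUID",
                              files[i])), "")
  if (length(unique(series)) != 1L)
    stop("directory mixes multiple DICOM series UIDs: ",
         paste(unique(series), collapse = ", "))
  slices <- lapply(seq_along(parsed), function(i) {
    el <- parsed[[i]]; f <- files[i]
    ps <- .require_tag(el, "0028,0030", "PixelSpacing", f)
    slope <- .require_tag(el, "0028,1053", "RescaleSlope", f)
    icpt <- .require_tag(el, "0028,1052", "RescaleIntercept", f)
    ipp <- .require_tag(el, "0020,0032", "ImagePositionPatient", f)
    rows <- .require_tag(el, "0028,0010", "Rows", f)
    cols <- .require_tag(el, "0028,0011", "Columns", f)
    bits <- .require_tag(el, "0028,0100", "BitsAllocated", f)
    if (bits != 16) stop("only 16-bit pixel data is supported: ", basename(f))
    signed <- identical(el[["0028,0103"]], 1L) || identical(el[["0028,0103"]], 1)
    body <- .require_tag(el, "7FE0,0010", "PixelData", f)
    px <- readBin(body, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
    hu <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE) * slope + icpt
    list(hu = hu, z = ipp[3], spacing = ps,
         thickness = el[["0018,0050"]],
         kernel = if (is.null(el[["0018,1210"]])) "" else el[["0018,1210"]],
         patient = if (is.null(el[["0010,0020"]])) "" else el[["0010,0020"]],
         date = if (is.null(el[["0008,0020"]])) "" else el[["0008,0020"]])
  })
  ord <- order(vapply(slices, `[[`, 0, "z"), decreasing = TRUE)  # superior first
  slices <- slices[ord]
  zs <- vapply(slices, `[[`, 0, "z")
  if (anyDuplicated(zs)) stop("duplicate slice positions in series")
  d1 <- nrow(slices[[1]]$hu); d2 <- ncol(slices[[1]]$hu)
  vox <- array(0, c(d1, d2, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  dz <- if (length(zs) > 1) stats::median(abs(diff(zs))) else
    if (!is.null(slices[[1]]$thickness)) slices[[1]]$thickness else 1
  vol <- ct_volume(vox, c(slices[[1]]$spacing[1], slices[[1]]$spacing[2], dz),
                   slice_z = zs, kernel = slices[[1]]$kernel,
                   sentinel_hu = sentinel_hu)
  date_raw <- slices[[1]]$date
  exam_date <- tryCatch(as.Date(date_raw, format = "%Y%m%d"),
                        error = function(e) as.Date(NA))
  list(volume = vol,
       metadata = list(patient_id = slices[[1]]$patient,
                       exam_date = exam_date,
                       kernel = slices[[1]]$kernel,
                       contrast_flag = NA))
}
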