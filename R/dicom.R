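# Minimal DICOM I/O: single-frame grayscale, Explicit VR Little Endian,
# uncompressed 16-bit pixel data. Covers the secondary-capture-style tag set
# the phantom generator writes (and that read_ap_view() needs); it is not a
# general-purpose DICOM implementation.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uid_from <- function(...) {
  h <- abs(sum(utf8ToInt(paste0(...)) * seq_along(utf8ToInt(paste0(...))))) %% 1e8
  paste0("1.2.826.0.1.3680043.9999.", h)
}

raw_uint16 <- function(v) {
  writeBin(as.integer(v), raw(), size = 2L, endian = "little")
}

raw_uint32 <- function(v) {
  writeBin(as.integer(v), raw(), size = 4L, endian = "little")
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dicom_element <- function(group, element, vr, value_raw) {
  head <- c(raw_uint16(group), raw_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw_uint32(length(value_raw)), value_raw)
  } else {
    c(head, raw_uint16(length(value_raw)), value_raw)
  }
}

el_str <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dicom_element(group, element, vr, pad_even(charToRaw(s), pad))
}

el_us <- function(group, element, v) dicom_element(group, element, "US", raw_uint16(v))

#' Write a minimal grayscale DICOM file
#'
#' Serialises one 2-D image as an uncompressed Explicit-VR-little-endian
#' DICOM file with 16-bit unsigned pixels and the geometry tags the
#' preprocessing pipeline reads back (Rows, Columns, PixelSpacing,
#' PhotometricInterpretation, rescale slope/intercept).
#'
#' @param path output file path.
#' @param pixels numeric matrix (rows = image rows); values are clipped to
#'   `[0, 65535]` and rounded to integers before storage.
#' @param row_spacing_mm,col_spacing_mm physical pixel spacing in mm.
#' @param photometric `"MONOCHROME2"` (higher stored value = brighter,
#'   default) or `"MONOCHROME1"`.
#' @param slope,intercept rescale slope and intercept stored in the file;
#'   readers recover `intensity = slope * stored + intercept`.
#' @param patient_id string stored as PatientID.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, pixels, row_spacing_mm, col_spacing_mm,
                        photometric = "MONOCHROME2", slope = 1, intercept = 0,
                        patient_id = "PHANTOM") {
  stopifnot(is.matrix(pixels), row_spacing_mm > 0, col_spacing_mm > 0)
  stored <- round(pmin(pmax(pixels, 0), 65535))
  nr <- nrow(stored); nc <- ncol(stored)
  # DICOM pixel data is row-major
  px_raw <- raw_uint16(as.integer(t(stored)))

  sop_uid <- uid_from(patient_id, nr, nc, sum(stored[1, ]))
  meta <- c(
    el_str(0x0002, 0x0002, "UI", DICOM_SC_SOP_CLASS),
    el_str(0x0002, 0x0003, "UI", sop_uid),
    el_str(0x0002, 0x0010, "UI", DICOM_EXPLICIT_LE),
    el_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.1")
  )
  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    meta
  )
  group_len <- dicom_element(0x0002, 0x0000, "UL", raw_uint32(length(meta)))

  spacing <- sprintf("%g\\%g", row_spacing_mm, col_spacing_mm)
  body <- c(
    el_str(0x0008, 0x0016, "UI", DICOM_SC_SOP_CLASS),
    el_str(0x0008, 0x0018, "UI", sop_uid),
    el_str(0x0008, 0x0060, "CS", "CR"),
    el_str(0x0010, 0x0020, "LO", patient_id),
    el_str(0x0020, 0x000D, "UI", uid_from(patient_id, "study")),
    el_str(0x0020, 0x000E, "UI", uid_from(patient_id, "series")),
    el_us(0x0028, 0x0002, 1L),
    el_str(0x0028, 0x0004, "CS", photometric),
    el_us(0x0028, 0x0010, nr),
    el_us(0x0028, 0x0011, nc),
    el_str(0x0028, 0x0030, "DS", spacing),
    el_us(0x0028, 0x0100, 16L),
    el_us(0x0028, 0x0101, 16L),
    el_us(0x0028, 0x0102, 15L),
    el_us(0x0028, 0x0103, 0L),
    el_str(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    el_str(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    dicom_element(0x7FE0, 0x0010, "OW", px_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

read_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

read_u32 <- function(bytes, at) {
  read_u16(bytes, at) + 65536 * read_u16(bytes, at + 2L)
}

#' Parse a minimal DICOM file into a tag list
#'
#' Reads an Explicit-VR-little-endian single-frame grayscale DICOM file and
#' returns its elements keyed by `"gggg,eeee"` tag strings. Pixel data is
#' decoded as 16-bit unsigned integers into a matrix.
#'
#' @param path file path.
#' @return named list of decoded element values; pixel data under
#'   `"7fe0,0010"` as an integer matrix.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  pos <- 133L
  out <- list()
  nbytes <- length(bytes)
  while (pos + 7L <= nbytes) {
    group <- read_u16(bytes, pos)
    element <- read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported (implicit-VR?) element encoding at byte ", pos)
    }
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- read_u16(bytes, pos + 6L)
      val_at <- pos + 8L
    }
    val_raw <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    out[[key]] <- decode_element(vr, val_raw)
    pos <- val_at + len
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts) && ts != DICOM_EXPLICIT_LE) {
    stop("unsupported transfer syntax: ", ts)
  }
  rows <- out[["0028,0010"]]; cols <- out[["0028,0011"]]
  px <- out[["7fe0,0010"]]
  if (!is.null(px) && !is.null(rows) && !is.null(cols)) {
    v <- readBin(px, "integer", n = rows * cols, size = 2L,
                 signed = FALSE, endian = "little")
    out[["7fe0,0010"]] <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  }
  out
}

trim_dicom_string <- function(val_raw) {
  while (length(val_raw) > 0 &&
         val_raw[length(val_raw)] %in% as.raw(c(0x00, 0x20))) {
    val_raw <- val_raw[-length(val_raw)]
  }
  rawToChar(val_raw)
}

decode_element <- function(vr, val_raw) {
  if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM")) {
    trim_dicom_string(val_raw)
  } else if (vr == "DS") {
    as.numeric(strsplit(trim_dicom_string(val_raw), "\\\\")[[1]])
  } else if (vr == "IS") {
    as.integer(strsplit(trim_dicom_string(val_raw), "\\\\")[[1]])
  } else if (vr == "US") {
    readBin(val_raw, "integer", n = length(val_raw) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else if (vr == "UL") {
    readBin(val_raw, "integer", n = length(val_raw) %/% 4L, size = 4L,
            endian = "little")
  } else {
    val_raw
  }
}
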