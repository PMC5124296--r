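# Minimal DICOM I/O for uncompressed monochrome slices.
#
# Scope is deliberately narrow: single-frame MONOCHROME1/2 images with
# uncompressed little-endian pixel data (implicit VR "1.2.840.10008.1.2" or
# explicit VR "1.2.840.10008.1.2.1"). Anything else -- compressed transfer
# syntaxes, colour, multi-frame -- raises an explicit unsupported-format
# error rather than a partial read. No R package in our dependency stack
# reads DICOM, and the format subset needed here is small enough to handle
# directly with readBin/writeBin.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_MR_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.10.1474"

# acquisition tag <-> DICOM (group, element), all VR DS
dicom_acq_tags <- list(
  slice_thickness_mm    = c(0x0018L, 0x0050L),
  repetition_time_ms    = c(0x0018L, 0x0080L),
  echo_time_ms          = c(0x0018L, 0x0081L),
  imaging_frequency_mhz = c(0x0018L, 0x0084L),
  pixel_bandwidth_hz    = c(0x0018L, 0x0095L)
)

uint16le <- function(x) as.raw(rbind(x %% 256L, x %/% 256L))
uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# One data element. Explicit VR uses the 2-byte length layout for short VRs
# and the reserved+4-byte layout for OB/OW; implicit VR always 4-byte length.
dicom_element <- function(group, element, vr, value, explicit = TRUE) {
  tag <- c(uint16le(group), uint16le(element))
  if (explicit) {
    if (vr %in% c("OB", "OW")) {
      c(tag, charToRaw(vr), as.raw(c(0, 0)), uint32le(length(value)), value)
    } else {
      c(tag, charToRaw(vr), uint16le(length(value)), value)
    }
  } else {
    c(tag, uint32le(length(value)), value)
  }
}

str_value <- function(s, pad = as.raw(0x20)) pad_even(charToRaw(s), pad)
ui_value  <- function(s) pad_even(charToRaw(s), as.raw(0L))

#' Write an image as an uncompressed monochrome DICOM file
#'
#' Writes a standard Part-10 file (128-byte preamble, "DICM", explicit-VR
#' file meta group) whose data set is either implicit or explicit VR
#' little endian, MONOCHROME2, single frame. Present acquisition tags are
#' written as DS elements; absent tags are omitted.
#'
#' @param img An [image2d()] with `bits_allocated` 8 or 16.
#' @param path Output file path.
#' @param transfer_syntax `"implicit"` (little endian, the default) or
#'   `"explicit"`.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(img, path, transfer_syntax = c("implicit", "explicit")) {
  stopifnot(inherits(img, "image2d"))
  transfer_syntax <- match.arg(transfer_syntax)
  if (!img$bits_allocated %in% c(8L, 16L))
    stop("only 8- and 16-bit containers are supported")
  ts_uid <- if (transfer_syntax == "implicit") TS_IMPLICIT_LE else TS_EXPLICIT_LE
  explicit <- transfer_syntax == "explicit"

  meta_body <- c(
    dicom_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002L, 0x0002L, "UI", ui_value(UID_MR_STORAGE)),
    dicom_element(0x0002L, 0x0003L, "UI", ui_value(paste0(UID_IMPL_CLASS, ".1"))),
    dicom_element(0x0002L, 0x0010L, "UI", ui_value(ts_uid)),
    dicom_element(0x0002L, 0x0012L, "UI", ui_value(UID_IMPL_CLASS))
  )
  meta <- c(dicom_element(0x0002L, 0x0000L, "UL", uint32le(length(meta_body))),
            meta_body)

  el <- function(g, e, vr, value) dicom_element(g, e, vr, value, explicit)
  ds <- c(
    el(0x0008L, 0x0016L, "UI", ui_value(UID_MR_STORAGE)),
    el(0x0008L, 0x0018L, "UI", ui_value(paste0(UID_IMPL_CLASS, ".1"))),
    el(0x0008L, 0x0060L, "CS", str_value("MR"))
  )
  for (tag in names(dicom_acq_tags)) {
    v <- img$acquisition[[tag]]
    if (!is.null(v)) {
      ge <- dicom_acq_tags[[tag]]
      ds <- c(ds, el(ge[1], ge[2], "DS", str_value(format(v, scientific = FALSE))))
    }
  }
  rows <- nrow(img$pixels); cols <- ncol(img$pixels)
  ds <- c(ds,
    el(0x0028L, 0x0002L, "US", uint16le(1L)),
    el(0x0028L, 0x0004L, "CS", str_value("MONOCHROME2")),
    el(0x0028L, 0x0010L, "US", uint16le(rows)),
    el(0x0028L, 0x0011L, "US", uint16le(cols)),
    el(0x0028L, 0x0100L, "US", uint16le(img$bits_allocated)),
    el(0x0028L, 0x0101L, "US", uint16le(img$bits_stored)),
    el(0x0028L, 0x0102L, "US", uint16le(img$bits_stored - 1L)),
    el(0x0028L, 0x0103L, "US", uint16le(0L))
  )
  v <- as.integer(t(img$pixels))  # row-major, as DICOM expects
  pix <- if (img$bits_allocated == 16L) uint16le(v) else as.raw(v)
  ds <- c(ds, el(0x7FE0L, 0x0010L, "OW", pix))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

read_uint16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
read_uint32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

# Parse data elements from raw bytes starting at `pos` (1-based), calling
# `keep(group, element, value_raw)` for each. Stops at end of `r` or when
# `stop_group` is exceeded. Returns position after the last element parsed.
parse_elements <- function(r, pos, explicit, keep, stop_at_group = NULL) {
  n <- length(r)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- read_uint16(r, pos)
    element <- read_uint16(r, pos + 2L)
    if (!is.null(stop_at_group) && group > stop_at_group) return(pos)
    hdr <- pos + 4L
    if (explicit) {
      vr <- rawToChar(r[hdr:(hdr + 1L)])
      if (vr %in% long_vrs) {
        len <- read_uint32(r, hdr + 4L)
        val_at <- hdr + 8L
      } else {
        len <- read_uint16(r, hdr + 2L)
        val_at <- hdr + 4L
      }
    } else {
      len <- read_uint32(r, hdr)
      val_at <- hdr + 4L
    }
    if (len == 4294967295) stop("unsupported: undefined-length element")
    if (val_at + len - 1 > n)
      stop("truncated DICOM file: element (",
           sprintf("%04x,%04x", group, element), ") exceeds file size")
    value <- if (len > 0) r[val_at:(val_at + len - 1L)] else raw(0)
    keep(group, element, value)
    pos <- val_at + len
  }
  pos
}

#' Read an uncompressed monochrome DICOM file
#'
#' Supports single-frame MONOCHROME1/2 images in implicit or explicit VR
#' little endian. Compressed transfer syntaxes, colour images and
#' multi-frame objects raise an unsupported-format error; a file whose
#' pixel data runs past the end of file raises a truncation error and no
#' partial image is returned. Acquisition tags present in the header are
#' copied onto the image; absent tags stay absent.
#'
#' @param path Path to a DICOM Part-10 file.
#' @return An [image2d()].
#' @export
read_dicom <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)

  meta <- new.env(parent = emptyenv())
  keep_meta <- function(g, e, v) {
    if (g == 0x0002L && e == 0x0010L)
      assign("ts", rawToChar(v[v != as.raw(0) & v != as.raw(0x20)]), envir = meta)
  }
  pos <- parse_elements(r, 133L, explicit = TRUE, keep = keep_meta,
                        stop_at_group = 0x0002L)
  if (!exists("ts", envir = meta)) stop("missing TransferSyntaxUID")
  ts <- get("ts", envir = meta)
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
    stop("unsupported transfer syntax (compressed or big-endian): ", ts)
  explicit <- ts == TS_EXPLICIT_LE

  tags <- new.env(parent = emptyenv())
  keep_ds <- function(g, e, v) {
    key <- sprintf("%04x%04x", g, e)
    assign(key, v, envir = tags)
  }
  parse_elements(r, pos, explicit = explicit, keep = keep_ds)

  get_tag <- function(g, e) {
    key <- sprintf("%04x%04x", g, e)
    if (exists(key, envir = tags)) get(key, envir = tags) else NULL
  }
  us <- function(g, e) {
    v <- get_tag(g, e)
    if (is.null(v)) NULL else read_uint16(v, 1L)
  }
  ds_num <- function(g, e) {
    v <- get_tag(g, e)
    if (is.null(v)) NULL else as.numeric(trimws(rawToChar(v)))
  }
  cs <- function(g, e) {
    v <- get_tag(g, e)
    if (is.null(v)) NULL else trimws(rawToChar(v[v != as.raw(0) & v != as.raw(0x20)]))
  }

  spp <- us(0x0028L, 0x0002L)
  if (!is.null(spp) && spp != 1L) stop("unsupported: SamplesPerPixel != 1")
  photometric <- cs(0x0028L, 0x0004L)
  if (!is.null(photometric) && !photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("unsupported photometric interpretation: ", photometric)
  nframes <- cs(0x0028L, 0x0008L)
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stop("unsupported: multi-frame DICOM")

  rows <- us(0x0028L, 0x0010L)
  cols <- us(0x0028L, 0x0011L)
  bits_alloc <- us(0x0028L, 0x0100L)
  bits_stored <- us(0x0028L, 0x0101L)
  pix_raw <- get_tag(0x7FE0L, 0x0010L)
  if (is.null(rows) || is.null(cols) || is.null(bits_alloc) || is.null(pix_raw))
    stop("missing image geometry or pixel data")
  expected <- rows * cols * (bits_alloc / 8)
  if (length(pix_raw) < expected) stop("truncated pixel data")
  v <- if (bits_alloc == 16L) {
    readBin(pix_raw, "integer", n = rows * cols, size = 2L,
            signed = FALSE, endian = "little")
  } else {
    as.integer(pix_raw[seq_len(rows * cols)])
  }
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)

  acquisition <- list()
  for (tag in names(dicom_acq_tags)) {
    ge <- dicom_acq_tags[[tag]]
    val <- ds_num(ge[1], ge[2])
    if (!is.null(val) && is.finite(val)) acquisition[[tag]] <- val
  }
  image2d(px, bits_allocated = bits_alloc,
          bits_stored = if (is.null(bits_stored)) bits_alloc else bits_stored,
          acquisition = acquisition)
}
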