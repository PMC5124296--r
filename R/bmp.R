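# Minimal 8-bit BMP I/O (Windows device-independent bitmap).
#
# Down-converted images are archived as 8-bit BMPs with a 256-entry
# grayscale palette, the format the study's extraction tooling produced.
# Only uncompressed 8-bit palette BMPs (plus 24-bit grayscale RGB as a
# reading convenience) are handled.

#' Write an 8-bit grayscale BMP
#'
#' @param img An 8-bit [image2d()] (see [to_8bit()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bmp <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  if (img$bits_allocated != 8L)
    stop("write_bmp expects an 8-bit image; convert with to_8bit() first")
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  stride <- ((w + 3L) %/% 4L) * 4L
  palette <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))  # B,G,R,0
  offset <- 14L + 40L + 1024L
  img_size <- stride * h
  file_header <- c(charToRaw("BM"), uint32le(offset + img_size),
                   uint16le(0L), uint16le(0L), uint32le(offset))
  info_header <- c(uint32le(40L), uint32le(w), uint32le(h),
                   uint16le(1L), uint16le(8L), uint32le(0L),
                   uint32le(img_size), uint32le(2835L), uint32le(2835L),
                   uint32le(256L), uint32le(0L))
  rows <- lapply(h:1, function(i) {           # bottom-up row order
    row <- as.integer(img$pixels[i, ])
    as.raw(c(row, rep(0L, stride - w)))
  })
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(file_header, info_header, palette, unlist(rows)), con)
  invisible(path)
}

#' Read an uncompressed 8-bit (or grayscale 24-bit) BMP
#'
#' 8-bit files are mapped through their palette (required to be grayscale);
#' 24-bit files must have equal channels.
#'
#' @param path Path to a BMP file.
#' @return An 8-bit [image2d()].
#' @export
read_bmp <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 54 || rawToChar(r[1:2]) != "BM")
    stop("not a BMP file: ", path)
  offset <- read_uint32(r, 11L)
  w <- read_uint32(r, 19L)
  h_raw <- read_uint32(r, 23L)
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bitcount <- read_uint16(r, 29L)
  compression <- read_uint32(r, 31L)
  if (compression != 0) stop("unsupported: compressed BMP")
  if (!bitcount %in% c(8L, 24L))
    stop("unsupported BMP bit depth: ", bitcount)

  if (bitcount == 8L) {
    header_size <- read_uint32(r, 15L)
    ncolors <- read_uint32(r, 47L)
    if (ncolors == 0) ncolors <- 256
    pal_at <- 14L + header_size
    pal <- matrix(as.integer(r[(pal_at + 1):(pal_at + 4 * ncolors)]),
                  nrow = 4)
    if (any(pal[1, ] != pal[2, ]) || any(pal[1, ] != pal[3, ]))
      stop("unsupported: non-grayscale BMP palette")
    gray <- pal[1, ]
    stride <- ((w + 3L) %/% 4L) * 4L
    px <- matrix(0L, nrow = h, ncol = w)
    for (i in seq_len(h)) {
      at <- offset + (i - 1L) * stride
      if (at + w > length(r)) stop("truncated BMP pixel data")
      row_idx <- as.integer(r[(at + 1):(at + w)])
      dest <- if (top_down) i else h - i + 1L
      px[dest, ] <- gray[row_idx + 1L]
    }
  } else {
    stride <- ((3L * w + 3L) %/% 4L) * 4L
    px <- matrix(0L, nrow = h, ncol = w)
    for (i in seq_len(h)) {
      at <- offset + (i - 1L) * stride
      if (at + 3L * w > length(r)) stop("truncated BMP pixel data")
      trip <- matrix(as.integer(r[(at + 1):(at + 3 * w)]), nrow = 3)
      if (any(trip[1, ] != trip[2, ]) || any(trip[1, ] != trip[3, ]))
        stop("unsupported: non-grayscale 24-bit BMP")
      dest <- if (top_down) i else h - i + 1L
      px[dest, ] <- trip[1, ]
    }
  }
  image2d(px, bits_allocated = 8L, bits_stored = 8L)
}
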