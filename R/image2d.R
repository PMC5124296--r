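#' Construct a 2-D grayscale image with bit-depth metadata
#'
#' An `image2d` couples an integer pixel grid with its container bit depth
#' (`bits_allocated`), the stored bit depth claimed by the source
#' (`bits_stored`, e.g. the DICOM BitsStored tag) and optional acquisition
#' tags. Pixels are stored as a base R matrix in which row `i` is the i-th
#' image row from the top and column `j` the j-th pixel from the left.
#'
#' @param pixels Integer-valued matrix, all values in
#'   `[0, 2^bits_allocated - 1]`.
#' @param bits_allocated Container bit depth (8 or 16 in practice).
#' @param bits_stored Reported stored bit depth; defaults to
#'   `bits_allocated`. Must not exceed `bits_allocated`.
#' @param acquisition Named list of optional acquisition tags; recognised
#'   names are `slice_thickness_mm`, `repetition_time_ms`, `echo_time_ms`,
#'   `imaging_frequency_mhz`, `pixel_bandwidth_hz`. Absent tags stay absent
#'   and are never defaulted.
#' @return An object of class `image2d`.
#' @seealso [measure_usable_bits()], [to_8bit()], [read_dicom()]
#' @export
image2d <- function(pixels, bits_allocated = 16L, bits_stored = NULL,
                    acquisition = list()) {
  if (!is.matrix(pixels) || !is_whole(pixels))
    stop("`pixels` must be an integer-valued matrix")
  bits_allocated <- as.integer(bits_allocated)
  if (is.null(bits_stored)) bits_stored <- bits_allocated
  bits_stored <- as.integer(bits_stored)
  if (bits_stored > bits_allocated)
    stop("`bits_stored` must not exceed `bits_allocated`")
  if (any(pixels < 0) || any(pixels > 2^bits_allocated - 1))
    stop("pixel values must lie in [0, 2^bits_allocated - 1]")
  known <- c("slice_thickness_mm", "repetition_time_ms", "echo_time_ms",
             "imaging_frequency_mhz", "pixel_bandwidth_hz")
  if (length(acquisition) && !all(names(acquisition) %in% known))
    stop("unknown acquisition tag(s): ",
         paste(setdiff(names(acquisition), known), collapse = ", "))
  pixels <- round(pixels)
  if (2^bits_allocated - 1 <= .Machine$integer.max)
    storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, bits_allocated = bits_allocated,
         bits_stored = bits_stored, acquisition = acquisition),
    class = "image2d"
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d, %d-bit container, %d stored bits reported\n",
              nrow(x$pixels), ncol(x$pixels), x$bits_allocated, x$bits_stored))
  cat(sprintf("  pixel range [%d, %d]\n", min(x$pixels), max(x$pixels)))
  if (length(x$acquisition))
    cat("  acquisition:",
        paste(names(x$acquisition), unlist(x$acquisition), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' Audit the bit depth actually occupied by pixel values
#'
#' Measures how many bits of the container a pixel grid really uses, as
#' opposed to what its header claims. The measured usable bit depth is the
#' smallest `b` with `max(pixels) <= 2^b - 1` (an all-zero image measures 1
#' bit by convention). A discrepancy flag is raised when the measured depth
#' differs from the reported stored bits, which happens e.g. when a 16-bit
#' container only holds 12 bits of signal under zero MSB padding.
#'
#' @param img An [image2d()].
#' @return A `bit_report` with `max_value`, `min_value`, `occupied_levels`
#'   (count of distinct grey levels), `span_levels` (`max - min + 1`),
#'   `usable_bits_measured`, `bits_stored_reported` and `discrepancy`.
#' @export
measure_usable_bits <- function(img) {
  stopifnot(inherits(img, "image2d"))
  if (length(img$pixels) == 0) stop("empty pixel grid")
  mx <- max(img$pixels)
  mn <- min(img$pixels)
  usable <- max(1L, as.integer(ceiling(log2(mx + 1))))
  structure(
    list(max_value = mx, min_value = mn,
         occupied_levels = length(unique(as.vector(img$pixels))),
         span_levels = mx - mn + 1,
         usable_bits_measured = usable,
         bits_stored_reported = img$bits_stored,
         discrepancy = usable != img$bits_stored),
    class = "bit_report"
  )
}

#' @export
print.bit_report <- function(x, ...) {
  cat(sprintf(
    "<bit_report> range [%d, %d], span %d levels (%d occupied)\n",
    x$min_value, x$max_value, x$span_levels, x$occupied_levels))
  cat(sprintf("  usable bits measured: %d, reported: %d%s\n",
              x$usable_bits_measured, x$bits_stored_reported,
              if (x$discrepancy) "  ** DISCREPANCY **" else ""))
  invisible(x)
}

#' Down-convert an image to 8 bits
#'
#' `lsb_shift` discards least-significant bits: `v8 = v >> (b - 8)` where
#' `b` is the *measured* usable bit depth (never the reported one, so padded
#' headers cannot distort the conversion). `linear_rescale` maps
#' `[min, max]` linearly onto `[0, 255]`.
#'
#' @param img An [image2d()].
#' @param mode `"lsb_shift"` (default) or `"linear_rescale"`.
#' @return An 8-bit [image2d()] with the acquisition tags carried over.
#' @export
to_8bit <- function(img, mode = c("lsb_shift", "linear_rescale")) {
  stopifnot(inherits(img, "image2d"))
  mode <- match.arg(mode)
  px <- img$pixels
  if (mode == "lsb_shift") {
    b <- measure_usable_bits(img)$usable_bits_measured
    if (b < 8) stop("lsb_shift needs at least 8 measured usable bits")
    out <- px %/% 2^(b - 8)
  } else {
    mn <- min(px); mx <- max(px)
    if (mx == mn) {
      warning("constant image: linear rescale returns all zeros")
      out <- px * 0
    } else {
      out <- round(255 * (px - mn) / (mx - mn))
    }
  }
  image2d(out, bits_allocated = 8L, bits_stored = 8L,
          acquisition = img$acquisition)
}

acquisition_intervals <- list(
  slice_thickness_mm    = c(3, 5),
  repetition_time_ms    = c(800, 2100),
  echo_time_ms          = c(1, 95),
  imaging_frequency_mhz = c(60, 130),
  pixel_bandwidth_hz    = c(400, 1200)
)

#' Check an image's acquisition tags against the selection criteria
#'
#' The sample-selection windows (closed intervals) are: slice thickness 3-5
#' mm, repetition time 800-2100 ms, echo time 1-95 ms, imaging frequency
#' 60-130 MHz, pixel bandwidth 400-1200 Hz. Tags absent from the image do
#' not fail the check but are reported as unverified.
#'
#' @param img An [image2d()].
#' @return A list with `pass` (TRUE iff every *present* tag is in range),
#'   `failures` (names of violated criteria) and `unverified` (absent tags).
#' @export
check_acquisition_criteria <- function(img) {
  stopifnot(inherits(img, "image2d"))
  failures <- character(0)
  unverified <- character(0)
  for (tag in names(acquisition_intervals)) {
    v <- img$acquisition[[tag]]
    if (is.null(v)) {
      unverified <- c(unverified, tag)
    } else {
      rng <- acquisition_intervals[[tag]]
      if (v < rng[1] || v > rng[2]) failures <- c(failures, tag)
    }
  }
  list(pass = length(failures) == 0, failures = failures,
       unverified = unverified)
}
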