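# Synthetic labeled brain phantom.
#
# Generates MR-like slices with the statistical structure the downstream
# analysis assumes: four piecewise-constant anatomical regions (ventricles,
# thalamus, grey matter, white matter) on a dark background, optional
# acquisition blur, additive Gaussian noise, integer quantisation and a
# configurable stored-bit depth inside a 16-bit container. It stands in for
# patient data; it is not a physics-based MR simulator.

region_labels <- c(ventricles = 1L, thalamus = 2L, grey_matter = 3L,
                   white_matter = 4L)

#' Specify a synthetic brain phantom
#'
#' @param matrix_size Image side length in pixels.
#' @param container_bits Container bit depth (default 16).
#' @param stored_bits Stored bit depth in `[8, 16]`; region means live on
#'   this scale.
#' @param padding_mode How stored bits sit in the container: `"zero_msb"`
#'   stores values as-is (upper bits zero), `"shift_lsb"` left-shifts by
#'   `container_bits - stored_bits`.
#' @param region_means Named intensities (stored-bit scale) for
#'   `ventricles`, `thalamus`, `grey_matter`, `white_matter`.
#' @param noise_sigma Additive Gaussian noise standard deviation
#'   (stored-bit intensity units).
#' @param blur_sigma Gaussian blur standard deviation in pixels, applied in
#'   floating point before noise and quantisation.
#' @param seed Integer seed; the same spec always generates bit-identical
#'   output.
#' @param acquisition Optional acquisition tags forwarded to the image.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size, container_bits = 16L, stored_bits = 16L,
                         padding_mode = c("zero_msb", "shift_lsb"),
                         region_means, noise_sigma = 0, blur_sigma = 0,
                         seed = 1L, acquisition = list()) {
  padding_mode <- match.arg(padding_mode)
  matrix_size <- as.integer(matrix_size)
  container_bits <- as.integer(container_bits)
  stored_bits <- as.integer(stored_bits)
  if (matrix_size < 32L) stop("matrix_size too small for the region layout")
  if (stored_bits < 8L || stored_bits > 16L)
    stop("stored_bits must be in [8, 16]")
  if (stored_bits > container_bits)
    stop("stored_bits must not exceed container_bits")
  if (!all(names(region_labels) %in% names(region_means)))
    stop("region_means must name all of: ",
         paste(names(region_labels), collapse = ", "))
  region_means <- unlist(region_means)[names(region_labels)]
  full <- 2^stored_bits - 1
  if (any(region_means < 0) || any(region_means > full))
    stop("region means must lie in [0, 2^stored_bits - 1]")
  if (noise_sigma < 0 || blur_sigma < 0)
    stop("noise_sigma and blur_sigma must be non-negative")
  structure(
    list(matrix_size = matrix_size, container_bits = container_bits,
         stored_bits = stored_bits, padding_mode = padding_mode,
         region_means = region_means, noise_sigma = noise_sigma,
         blur_sigma = blur_sigma, seed = as.integer(seed),
         acquisition = acquisition),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d, %d stored bits in %d-bit container (%s)\n",
    x$matrix_size, x$matrix_size, x$stored_bits, x$container_bits,
    x$padding_mode))
  cat("  region means:",
      paste(names(x$region_means), round(x$region_means), sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("  noise_sigma=%.6g, blur_sigma=%.6g, seed=%d\n",
              x$noise_sigma, x$blur_sigma, x$seed))
  invisible(x)
}

# Region means as fractions of the full stored-bit scale, T2-like contrast:
# bright CSF-filled ventricles, intermediate cortical grey matter rim,
# brighter unmyelinated white matter, darker thalamic nuclei.
preset_mean_fractions <- c(ventricles = 0.85, thalamus = 0.40,
                           grey_matter = 0.50, white_matter = 0.65)

#' Acquisition presets for the two field strengths
#'
#' `"t1p5"` emulates the 1.5 T product: 256 x 256 matrix, 12 stored bits
#' zero-MSB-padded into a 16-bit container, relative noise 3% of full
#' scale. `"t3"` emulates the 3 T product: 446 x 446 matrix, 16 stored
#' bits, relative noise 1.5% of full scale. Both share the same fractional
#' region means and a 1-pixel acquisition blur, so the presets differ in
#' resolution, dynamic range and noise only.
#'
#' @param name `"t1p5"` or `"t3"`.
#' @param seed Seed stored in the returned spec.
#' @return A [phantom_spec()].
#' @export
modality_preset <- function(name = c("t1p5", "t3"), seed = 1L) {
  name <- match.arg(name)
  if (name == "t1p5") {
    full <- 2^12 - 1
    phantom_spec(
      matrix_size = 256L, container_bits = 16L, stored_bits = 12L,
      padding_mode = "zero_msb",
      region_means = preset_mean_fractions * full,
      noise_sigma = 0.03 * full, blur_sigma = 1, seed = seed,
      acquisition = list(slice_thickness_mm = 4, repetition_time_ms = 1500,
                         echo_time_ms = 90, imaging_frequency_mhz = 63.9,
                         pixel_bandwidth_hz = 500)
    )
  } else {
    full <- 2^16 - 1
    phantom_spec(
      matrix_size = 446L, container_bits = 16L, stored_bits = 16L,
      padding_mode = "zero_msb",
      region_means = preset_mean_fractions * full,
      noise_sigma = 0.015 * full, blur_sigma = 1, seed = seed,
      acquisition = list(slice_thickness_mm = 4, repetition_time_ms = 1500,
                         echo_time_ms = 90, imaging_frequency_mhz = 127.7,
                         pixel_bandwidth_hz = 500)
    )
  }
}

# Elliptical region layout in normalized [-1,1]^2 coordinates (u = x, v = y,
# y increasing downwards). The geometry is a documented constant, not a
# contract: a central thalamic ellipse, two ventricle ellipses above it, a
# cortical grey-matter rim and white matter filling the interior.
phantom_label_map <- function(matrix_size) {
  c0 <- (matrix_size - 1) / 2
  u <- matrix(rep((0:(matrix_size - 1) - c0) / c0, each = matrix_size),
              nrow = matrix_size)          # column coordinate
  v <- matrix(rep((0:(matrix_size - 1) - c0) / c0, times = matrix_size),
              nrow = matrix_size)          # row coordinate
  inside <- function(cu, cv, au, av) ((u - cu) / au)^2 + ((v - cv) / av)^2 <= 1
  brain <- inside(0, 0, 0.82, 0.92)
  inner <- inside(0, 0, 0.66, 0.78)
  thal  <- inside(0, 0.08, 0.20, 0.16)
  vent  <- inside(-0.30, -0.22, 0.11, 0.26) | inside(0.30, -0.22, 0.11, 0.26)
  labels <- matrix(0L, matrix_size, matrix_size)
  labels[brain & !inner] <- region_labels[["grey_matter"]]
  labels[inner] <- region_labels[["white_matter"]]
  labels[vent & inner] <- region_labels[["ventricles"]]
  labels[thal & inner] <- region_labels[["thalamus"]]
  labels
}

#' Generate a labeled synthetic brain phantom
#'
#' Builds the piecewise-constant region image from the spec's means,
#' applies Gaussian blur in floating point (acquisition blur precedes
#' digitisation), adds Gaussian noise, clips to the stored-bit range and
#' rounds to integers. Under `"shift_lsb"` padding the quantised values are
#' then left-shifted into the container's most significant bits.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `image` ([image2d()]),
#'   `roi` ([roi_set()]), `labels` (integer label matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_label_map(spec$matrix_size)
  base <- matrix(0, spec$matrix_size, spec$matrix_size)
  for (nm in names(region_labels))
    base[labels == region_labels[[nm]]] <- spec$region_means[[nm]]
  if (spec$blur_sigma > 0)
    base <- EBImage::gblur(base, sigma = spec$blur_sigma,
                           boundary = "replicate")
  if (spec$noise_sigma > 0)
    base <- base + with_seed(spec$seed,
                             matrix(stats::rnorm(length(base),
                                                 sd = spec$noise_sigma),
                                    nrow = nrow(base)))
  full <- 2^spec$stored_bits - 1
  px <- round(pmin(pmax(base, 0), full))
  if (spec$padding_mode == "shift_lsb")
    px <- px * 2^(spec$container_bits - spec$stored_bits)
  img <- image2d(px, bits_allocated = spec$container_bits,
                 bits_stored = spec$stored_bits,
                 acquisition = spec$acquisition)
  masks <- lapply(region_labels, function(k) labels == k)
  list_out <- list(image = img, roi = roi_set(masks), labels = labels,
                   spec = spec)
  class(list_out) <- "phantom"
  list_out
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$spec)
  sizes <- vapply(x$roi$masks, sum, numeric(1))
  cat("  region sizes (px):",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a phantom spec as JSON
#'
#' @param spec A [phantom_spec()].
#' @param path JSON file path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- unclass(spec)
  out$region_means <- as.list(out$region_means)  # keep names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_spec(
    matrix_size = x$matrix_size, container_bits = x$container_bits,
    stored_bits = x$stored_bits, padding_mode = x$padding_mode,
    region_means = x$region_means, noise_sigma = x$noise_sigma,
    blur_sigma = x$blur_sigma, seed = x$seed,
    acquisition = as.list(x$acquisition)
  )
}
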