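# First-order histogram features and Haar wavelet subband energies.
#
# Moments here are population (1/n) moments with excess kurtosis, matching
# the conventions of the texture-analysis software the pipeline emulates.
# The group-comparison module deliberately uses sample (n-1) statistics
# instead; the split is intentional and documented per module.

#' First-order histogram features of a pixel sample
#'
#' Population moments: `mean = sum(x)/n`, `variance = sum((x-mu)^2)/n`,
#' `skewness = m3/sigma^3`, excess kurtosis `m4/sigma^4 - 3`. For a
#' constant sample the variance is 0 and skewness/kurtosis are undefined
#' (`NA` with `defined = FALSE`), never silently 0 — downstream indices
#' refuse such samples.
#'
#' @param sample Numeric vector of pixel values, length >= 1 (see
#'   [extract_pixels()]).
#' @return An object of class `feature_set` with fields `n`, `mean`,
#'   `variance`, `skewness`, `kurtosis_excess`, `defined`.
#' @export
histogram_features <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 1 || any(!is.finite(sample))) stop("need a finite, non-empty sample")
  mu <- sum(sample) / n
  d <- sample - mu
  m2 <- sum(d^2) / n
  if (m2 > 0) {
    m3 <- sum(d^3) / n
    m4 <- sum(d^4) / n
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
    defined <- TRUE
  } else {
    skew <- NA_real_
    kurt <- NA_real_
    defined <- FALSE
  }
  structure(
    list(n = n, mean = mu, variance = m2, skewness = skew,
         kurtosis_excess = kurt, defined = defined),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> n=%d mean=%.6g variance=%.6g\n",
              x$n, x$mean, x$variance))
  if (x$defined)
    cat(sprintf("  skewness=%.6g kurtosis_excess=%.6g\n",
                x$skewness, x$kurtosis_excess))
  else
    cat("  skewness/kurtosis undefined (constant sample)\n")
  invisible(x)
}

haar_step_cols <- function(M) {
  odd <- M[, seq(1, ncol(M), 2), drop = FALSE]
  even <- M[, seq(2, ncol(M), 2), drop = FALSE]
  list(lo = (odd + even) / sqrt(2), hi = (odd - even) / sqrt(2))
}

haar_step_rows <- function(M) {
  odd <- M[seq(1, nrow(M), 2), , drop = FALSE]
  even <- M[seq(2, nrow(M), 2), , drop = FALSE]
  list(lo = (odd + even) / sqrt(2), hi = (odd - even) / sqrt(2))
}

#' Orthonormal Haar subband decomposition of a window
#'
#' Separable analysis with filters `(1, 1)/sqrt(2)` (low-pass) and
#' `(1, -1)/sqrt(2)` (high-pass). Naming follows the x-then-y convention:
#' `HL` is high-pass along x (columns) and low-pass along y (rows), so it
#' responds to vertical edges. For `scale > 1` the transform recurses on
#' the LL band and the subbands of the final level are returned. Being
#' orthonormal, the transform preserves total energy level by level
#' (Parseval).
#'
#' @param window Numeric matrix whose sides are divisible by `2^scale`
#'   (callers pad or crop explicitly).
#' @param scale Decomposition level, integer >= 1.
#' @return List with matrices `LL`, `LH`, `HL`, `HH` and the `scale`.
#' @export
haar_subbands <- function(window, scale = 1L) {
  window <- as.matrix(window)
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  if (nrow(window) %% 2^scale != 0 || ncol(window) %% 2^scale != 0)
    stop("window sides must be divisible by 2^scale")
  M <- window
  for (s in seq_len(scale)) {
    cx <- haar_step_cols(M)
    lo_y <- haar_step_rows(cx$lo)
    hi_y <- haar_step_rows(cx$hi)
    LL <- lo_y$lo; LH <- lo_y$hi; HL <- hi_y$lo; HH <- hi_y$hi
    M <- LL
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH, scale = scale)
}

#' Wavelet subband energies over an ROI
#'
#' The Haar transform is computed over the largest `2^scale`-aligned square
#' window centred in the mask's bounding box (the exact ROI-to-dyadic-grid
#' mapping of the reference software is undocumented; this inscribed-window
#' policy is this package's documented choice). The energy of a subband is
#' the mean of its squared coefficients; `wavenhl`, the HL energy, is the
#' region "fingerprint" feature.
#'
#' @param img An [image2d()].
#' @param mask Logical matrix matching the image shape, non-empty.
#' @param scale Decomposition level (default 1).
#' @return An object of class `wavelet_energies` with fields `scale`,
#'   `wavenll`, `wavenlh`, `wavenhl`, `wavenhh`, plus the window geometry.
#' @export
wavelet_energies <- function(img, mask, scale = 1L) {
  stopifnot(inherits(img, "image2d"), is.logical(mask))
  if (!identical(dim(img$pixels), dim(mask)))
    stop("mask shape must equal image shape")
  if (!any(mask)) stop("empty mask")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  h <- rows[2] - rows[1] + 1L
  w <- cols[2] - cols[1] + 1L
  unit <- 2^as.integer(scale)
  side <- (min(h, w) %/% unit) * unit
  if (side < unit)
    stop("mask bounding box too small for a 2^scale-aligned window")
  r0 <- rows[1] + (h - side) %/% 2L
  c0 <- cols[1] + (w - side) %/% 2L
  win <- img$pixels[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
  sb <- haar_subbands(win, scale)
  structure(
    list(scale = as.integer(scale),
         wavenll = mean(sb$LL^2), wavenlh = mean(sb$LH^2),
         wavenhl = mean(sb$HL^2), wavenhh = mean(sb$HH^2),
         window = c(row = r0, col = c0, side = side)),
    class = "wavelet_energies"
  )
}

#' @export
print.wavelet_energies <- function(x, ...) {
  cat(sprintf(
    "<wavelet_energies> scale %d, window %dpx @(%d,%d)\n",
    x$scale, x$window[["side"]], x$window[["row"]], x$window[["col"]]))
  cat(sprintf("  LL=%.6g LH=%.6g HL=%.6g HH=%.6g\n",
              x$wavenll, x$wavenlh, x$wavenhl, x$wavenhh))
  invisible(x)
}

#' Euclidean distance between wavelet energy signatures
#'
#' Zero iff the two four-band signatures are identical; used to match
#' ("fingerprint") anatomical regions across images.
#'
#' @param a,b [wavelet_energies()] objects of the same scale.
#' @return Non-negative scalar.
#' @export
wavelet_signature_distance <- function(a, b) {
  stopifnot(inherits(a, "wavelet_energies"), inherits(b, "wavelet_energies"))
  if (a$scale != b$scale) stop("wavelet signatures have different scales")
  va <- c(a$wavenll, a$wavenlh, a$wavenhl, a$wavenhh)
  vb <- c(b$wavenll, b$wavenlh, b$wavenhl, b$wavenhh)
  sqrt(sum((va - vb)^2))
}
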