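# Regions of interest: labeled masks, polygon rasterization, pixel
# extraction. Conventions used throughout the package: 0-based (x, y)
# pixel-center coordinates, x along columns, y along rows from the top;
# extracted samples are row-major.

#' Bundle labeled region masks
#'
#' @param masks Named list of logical matrices of identical shape, one per
#'   region. Masks must be pairwise disjoint. The canonical anatomical
#'   labels are `ventricles` (1), `thalamus` (2), `grey_matter` (3) and
#'   `white_matter` (4).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks) {
  if (!length(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a non-empty named list")
  dims <- lapply(masks, dim)
  if (!all(vapply(masks, is.logical, logical(1))))
    stop("masks must be logical matrices")
  if (length(unique(dims)) != 1)
    stop("all masks must share the same shape")
  total <- Reduce(`+`, masks)
  if (any(total > 1)) stop("masks must be pairwise disjoint")
  structure(list(masks = masks, dim = dims[[1]]), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  sizes <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<roi_set> %d x %d, %d regions\n", x$dim[1], x$dim[2],
              length(x$masks)))
  cat(" ", paste(names(sizes), sizes, sep = "=", collapse = ", "), "px\n")
  invisible(x)
}

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd-rule fill: a pixel belongs to the mask iff its center is inside
#' the polygon (or exactly on its boundary). Self-intersecting polygons are
#' allowed and filled by parity; vertices may lie outside the image (the
#' mask is simply clipped to the grid).
#'
#' @param vertices Numeric n x 2 matrix (or data.frame) of `(x, y)`
#'   vertices in 0-based pixel-center coordinates, `n >= 3`.
#' @param shape Target mask shape `c(nrow, ncol)`.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_polygon <- function(vertices, shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("`vertices` must be an n x 2 matrix with n >= 3")
  vx <- as.numeric(vertices[, 1]); vy <- as.numeric(vertices[, 2])
  # all vertices collinear (or coincident) -> nothing to fill; note a
  # self-intersecting polygon can have zero *signed* area yet still fill
  dx <- vx - vx[1]; dy <- vy - vy[1]
  ref <- which.max(dx^2 + dy^2)
  if (all(abs(dx * dy[ref] - dy * dx[ref]) < 1e-9)) {
    warning("degenerate polygon (collinear vertices): empty mask")
    return(matrix(FALSE, shape[1], shape[2]))
  }
  px <- rep(0:(shape[2] - 1), each = shape[1])   # x of every pixel center
  py <- rep(0:(shape[1] - 1), times = shape[2])  # y of every pixel center
  crossings <- integer(length(px))
  on_edge <- logical(length(px))
  n <- length(vx)
  eps <- 1e-9
  for (k in seq_len(n)) {
    x1 <- vx[k]; y1 <- vy[k]
    x2 <- vx[k %% n + 1]; y2 <- vy[k %% n + 1]
    cross <- ((y1 > py) != (y2 > py))
    if (any(cross)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(cross & px < xint - eps)
    }
    # points exactly on the (closed) segment count as inside
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seg_len > 0) {
      tpar <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / seg_len^2
      on_edge <- on_edge | (d <= eps * max(1, seg_len) &
                              tpar >= -eps & tpar <= 1 + eps)
    }
  }
  inside <- (crossings %% 2L == 1L) | on_edge
  matrix(inside, nrow = shape[1], ncol = shape[2])
}

#' Extract ROI pixel values in deterministic row-major order
#'
#' @param img An [image2d()].
#' @param mask Logical matrix matching the image shape.
#' @return Integer vector of the masked pixels, ordered row by row from the
#'   top-left (its length equals the mask popcount).
#' @export
extract_pixels <- function(img, mask) {
  stopifnot(inherits(img, "image2d"), is.logical(mask))
  if (!identical(dim(img$pixels), dim(mask)))
    stop("mask shape must equal image shape")
  if (!any(mask)) stop("empty mask: features are undefined")
  tp <- t(img$pixels)
  as.integer(tp[t(mask)])
}

#' Write / read an ROI set as an 8-bit PNG label map
#'
#' Background is 0; each region is stored as its small integer label.
#'
#' @param roi An [roi_set()]; label values follow the order of its masks.
#' @param path PNG file path.
#' @param labels Named integer labels to use; defaults to the canonical
#'   four-region labels for canonical names, else `1:n` in mask order.
#' @return `write_roi_png` returns `path` invisibly; `read_roi_png` an
#'   [roi_set()].
#' @export
write_roi_png <- function(roi, path, labels = NULL) {
  stopifnot(inherits(roi, "roi_set"))
  if (is.null(labels)) {
    labels <- if (all(names(roi$masks) %in% names(region_labels)))
      region_labels[names(roi$masks)]
    else
      stats::setNames(seq_along(roi$masks), names(roi$masks))
  }
  lab <- matrix(0L, roi$dim[1], roi$dim[2])
  for (nm in names(roi$masks)) lab[roi$masks[[nm]]] <- labels[[nm]]
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' @rdname write_roi_png
#' @param names_map Named integer vector mapping region names to label
#'   values when reading; defaults to the canonical four-region labels.
#' @export
read_roi_png <- function(path, names_map = region_labels) {
  lab <- round(png::readPNG(path) * 255)
  if (length(dim(lab)) == 3) lab <- lab[, , 1]
  present <- names_map[names_map %in% unique(as.integer(lab))]
  if (!length(present)) stop("no known region labels found in ", path)
  roi_set(lapply(present, function(k) lab == k))
}

#' Canonical region labels
#'
#' @return Named integer vector mapping the four anatomical region names to
#'   their mask labels.
#' @export
roi_labels <- function() region_labels
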