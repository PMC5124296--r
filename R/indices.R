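# The two derived quality indices and the focus-based retention filter.

#' Focus index (skewness-to-kurtosis ratio)
#'
#' `focus_index = skewness / kurtosis_excess`. An ideal, well-focused
#' texture scores near zero; samples outside `[-1, +1]` behave like noisy
#' quantum mottle and are excluded by [filter_by_focus()]. The index is
#' undefined for constant samples and whenever `|kurtosis| <= eps`, in
#' which case an error of class `mritexture_undefined_index` is raised so
#' callers can exclude and log the sample.
#'
#' @param f A [histogram_features()] result.
#' @param eps Kurtosis magnitude below which the ratio is refused
#'   (default `1e-12`).
#' @return Dimensionless scalar.
#' @export
focus_index <- function(f, eps = 1e-12) {
  stopifnot(inherits(f, "feature_set"))
  if (!f$defined)
    stop_mritexture("focus index undefined: constant sample",
                    "mritexture_undefined_index")
  if (abs(f$kurtosis_excess) <= eps)
    stop_mritexture("focus index undefined: |kurtosis| below eps",
                    "mritexture_undefined_index")
  f$skewness / f$kurtosis_excess
}

#' Dispersion index (variance-to-mean ratio)
#'
#' `dispersion_index = variance / mean` (VMR), in intensity units. Larger
#' spread between per-region VMR values indicates better discriminability
#' of anatomical structures. Undefined for non-positive means.
#'
#' @param f A [histogram_features()] result with `mean > 0`.
#' @return Scalar in intensity units.
#' @export
dispersion_index <- function(f) {
  stopifnot(inherits(f, "feature_set"))
  if (f$mean <= 0)
    stop_mritexture("dispersion index undefined: mean <= 0",
                    "mritexture_undefined_index")
  f$variance / f$mean
}

#' Both indices plus the focus retention flag
#'
#' Convenience wrapper computing [focus_index()] and [dispersion_index()];
#' an undefined index is reported as `NA` rather than an error, so batch
#' pipelines can log and skip the sample.
#'
#' @param f A [histogram_features()] result.
#' @param lo,hi Closed focus retention interval (default `[-1, 1]`).
#' @return An object of class `index_set` with `focus_index`,
#'   `dispersion_index` and `in_focus_range` (FALSE when focus is NA).
#' @export
index_set <- function(f, lo = -1, hi = 1) {
  fi <- tryCatch(focus_index(f), mritexture_undefined_index = function(e) NA_real_)
  di <- tryCatch(dispersion_index(f), mritexture_undefined_index = function(e) NA_real_)
  structure(
    list(focus_index = fi, dispersion_index = di,
         in_focus_range = !is.na(fi) && fi >= lo && fi <= hi),
    class = "index_set"
  )
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("<index_set> focus=%.6g dispersion=%.6g %s\n",
              x$focus_index, x$dispersion_index,
              if (isTRUE(x$in_focus_range)) "(in focus range)"
              else "(outside focus range)"))
  invisible(x)
}

#' Retain samples whose focus index lies in a closed interval
#'
#' Samples with focus index in `[lo, hi]` (boundaries included) are kept in
#' their original order; values outside — typically noisy, mottled samples
#' — and undefined (`NA`) indices are dropped.
#'
#' @param x Numeric vector of focus-index values, or a list of
#'   [index_set()] objects.
#' @param lo,hi Interval bounds, `lo <= hi` (defaults -1, +1).
#' @return The retained subset of `x`, same type, order preserved.
#' @export
filter_by_focus <- function(x, lo = -1, hi = 1) {
  if (lo > hi) stop("lo must not exceed hi")
  vals <- if (is.list(x))
    vapply(x, function(s) s$focus_index, numeric(1))
  else
    as.numeric(x)
  keep <- !is.na(vals) & vals >= lo & vals <= hi
  if (is.list(x)) x[keep] else x[keep]
}
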