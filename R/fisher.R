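# Feature-selection coefficient (between-class / within-class variance),
# control-point injection and leave-one-out 1-NN misclassification error.
#
# F = D^2 / V^2 with
#   D^2 = [1 / (1 - sum_k P_k^2)] * sum_k sum_j P_k P_j ||mu_k - mu_j||^2
#   V^2 = sum_k P_k V_k^2,  V_k^2 = (1/n_k) sum_i ||x_i - mu_k||^2
# where P_k = n_k / N. Distances are multivariate Euclidean over the full
# feature vector (trace form) and within-class variance is the population
# (1/n) form; a per-feature univariate mode is provided for ranking.

#' Build a samples-by-features matrix with class labels
#'
#' @param x Numeric matrix (rows = samples, columns = features); no missing
#'   values.
#' @param classes Class label per row (character or factor).
#' @param sample_ids Optional sample identifiers (default `s1, s2, ...`).
#' @param feature_names Optional feature names (default from `colnames`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, classes, sample_ids = NULL,
                           feature_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "numeric"
  if (any(!is.finite(x))) stop("feature matrix must not contain missing values")
  classes <- as.character(classes)
  if (length(classes) != nrow(x))
    stop("`classes` must have one label per row")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  if (is.null(feature_names))
    feature_names <- if (!is.null(colnames(x))) colnames(x)
      else paste0("f", seq_len(ncol(x)))
  colnames(x) <- feature_names
  structure(
    list(x = x, classes = classes, sample_ids = as.character(sample_ids),
         feature_names = feature_names),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(unique(x$classes))))
  cat("  classes:", paste(names(table(x$classes)), table(x$classes),
                          sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, class = x$classes,
             as.data.frame(x$x), check.names = FALSE)
}

#' Read / write a feature matrix as CSV
#'
#' The schema is `sample_id, class, <feature columns...>`.
#'
#' @param path CSV file path.
#' @return `read_feature_matrix` returns a [feature_matrix()];
#'   `write_feature_matrix` returns `path` invisibly.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)))
    stop("feature matrix CSV needs `sample_id` and `class` columns")
  feats <- setdiff(names(df), c("sample_id", "class"))
  feature_matrix(as.matrix(df[feats]), classes = df$class,
                 sample_ids = df$sample_id, feature_names = feats)
}

#' @rdname read_feature_matrix
#' @param M A [feature_matrix()].
#' @export
write_feature_matrix <- function(M, path) {
  stopifnot(inherits(M, "feature_matrix"))
  utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  invisible(path)
}

#' Per-class summaries feeding the feature-selection coefficient
#'
#' @param M A [feature_matrix()] with at least two classes, each non-empty.
#' @return List of `class_summary` objects, one per class, each with
#'   `label`, `n`, `P` (class probability `n_k/N`), `mu` (mean vector) and
#'   `Vk2` (population mean squared Euclidean distance to the centroid).
#' @export
class_summaries <- function(M) {
  stopifnot(inherits(M, "feature_matrix"))
  labs <- unique(M$classes)
  N <- nrow(M$x)
  lapply(labs, function(lab) {
    xi <- M$x[M$classes == lab, , drop = FALSE]
    mu <- colMeans(xi)
    structure(
      list(label = lab, n = nrow(xi), P = nrow(xi) / N, mu = mu,
           Vk2 = mean(rowSums((xi - matrix(mu, nrow(xi), ncol(xi),
                                           byrow = TRUE))^2))),
      class = "class_summary"
    )
  })
}

#' Feature-selection coefficient F = D^2 / V^2
#'
#' Between-class variance `D^2` uses the probability-weighted sum of
#' squared Euclidean distances between all class-mean pairs, normalised by
#' `1/(1 - sum P_k^2)`; within-class variance `V^2` pools the population
#' per-class variances. When every class is internally constant
#' (`V^2 = 0`) the coefficient is capped at `f_max` and flagged.
#'
#' @param M A [feature_matrix()] with >= 2 classes.
#' @param f_max Cap returned when `V^2 = 0` (default `1e6`, configurable).
#' @return An object of class `fisher_result` with `F`, `D2`, `V2`,
#'   `capped`, `f_max` and the per-class summaries.
#' @export
fisher_coefficient <- function(M, f_max = 1e6) {
  stopifnot(inherits(M, "feature_matrix"))
  cs <- class_summaries(M)
  if (length(cs) < 2)
    stop("need at least two classes (single class gives 1 - sum(P^2) = 0)")
  P <- vapply(cs, `[[`, numeric(1), "P")
  mu <- do.call(rbind, lapply(cs, `[[`, "mu"))
  Vk2 <- vapply(cs, `[[`, numeric(1), "Vk2")
  # pairwise identity: sum_kj Pk Pj ||mu_k - mu_j||^2
  #                  = 2 (sum_k Pk ||mu_k||^2 - ||sum_k Pk mu_k||^2)
  mubar <- colSums(mu * P)
  pairsum <- 2 * (sum(P * rowSums(mu^2)) - sum(mubar^2))
  D2 <- pairsum / (1 - sum(P^2))
  V2 <- sum(P * Vk2)
  capped <- V2 <= 0
  structure(
    list(F = if (capped) f_max else D2 / V2,
         D2 = D2, V2 = V2, capped = capped, f_max = f_max, classes = cs),
    class = "fisher_result"
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result> F = %.6g%s\n", x$F,
              if (x$capped) sprintf(" (capped at f_max = %g, V2 = 0)", x$f_max)
              else ""))
  cat(sprintf("  D2 (between-class) = %.6g, V2 (within-class) = %.6g\n",
              x$D2, x$V2))
  invisible(x)
}

#' Univariate feature-selection coefficient per feature
#'
#' Secondary ranking mode: [fisher_coefficient()] applied to each feature
#' column on its own.
#'
#' @inheritParams fisher_coefficient
#' @return Named numeric vector of per-feature F values.
#' @export
fisher_per_feature <- function(M, f_max = 1e6) {
  stopifnot(inherits(M, "feature_matrix"))
  vapply(M$feature_names, function(f) {
    sub <- feature_matrix(M$x[, f, drop = FALSE], M$classes, M$sample_ids, f)
    fisher_coefficient(sub, f_max)$F
  }, numeric(1))
}

#' Leave-one-out 1-nearest-neighbour misclassification error
#'
#' Each sample is classified by its nearest Euclidean neighbour among the
#' remaining samples; the misclassified-data-error (MDE) is the percentage
#' whose neighbour carries a different class label. Distance ties are
#' broken by the lowest sample index. With `standardize = TRUE` each
#' feature is z-scored (sample sd) before distances; zero-variance features
#' are dropped with a warning. The default, matching the RAW analysis this
#' package reproduces, is no standardization.
#'
#' @param M A [feature_matrix()] with >= 2 samples.
#' @param standardize Logical (default FALSE).
#' @return An object of class `nn_result` with `mde_percent`,
#'   `n_misclassified`, `n_total`, `misclassified` (logical per sample).
#' @export
loo_1nn_mde <- function(M, standardize = FALSE) {
  stopifnot(inherits(M, "feature_matrix"))
  X <- M$x
  if (nrow(X) < 2) stop("need at least two samples")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    drop <- sds == 0
    if (any(drop)) {
      warning("dropping zero-variance feature(s) under standardization: ",
              paste(colnames(X)[drop], collapse = ", "))
      X <- X[, !drop, drop = FALSE]
      if (ncol(X) == 0) stop("no features left after dropping")
      sds <- sds[!drop]
    }
    X <- scale(X, center = TRUE, scale = sds)
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)  # which.min takes the lowest index on ties
  mis <- M$classes[nn] != M$classes
  structure(
    list(mde_percent = 100 * sum(mis) / length(mis),
         n_misclassified = sum(mis), n_total = length(mis),
         misclassified = mis, standardized = standardize),
    class = "nn_result"
  )
}

#' @export
print.nn_result <- function(x, ...) {
  cat(sprintf("<nn_result> MDE = %.4g%% (%d of %d misclassified)%s\n",
              x$mde_percent, x$n_misclassified, x$n_total,
              if (x$standardized) ", standardized features" else ""))
  invisible(x)
}

#' Append control-point classes to a feature matrix
#'
#' Adds two calibration classes, `control_min` and `control_max`, each as
#' `replicates` copies of a fixed coordinate, bounding the feature space
#' before Fisher / 1-NN analysis.
#'
#' @param M A [feature_matrix()] (may be empty: zero rows).
#' @param c_min,c_max Numeric control coordinates matching the feature
#'   dimension.
#' @param replicates Copies of each control point (default 2).
#' @return A new [feature_matrix()]; existing rows are untouched.
#' @export
add_controls <- function(M, c_min, c_max, replicates = 2L) {
  stopifnot(inherits(M, "feature_matrix"))
  d <- ncol(M$x)
  if (length(c_min) != d || length(c_max) != d)
    stop("control dimension must match the feature matrix")
  replicates <- as.integer(replicates)
  ctrl <- rbind(
    matrix(rep(as.numeric(c_min), replicates), nrow = replicates, byrow = TRUE),
    matrix(rep(as.numeric(c_max), replicates), nrow = replicates, byrow = TRUE)
  )
  feature_matrix(
    rbind(M$x, ctrl),
    classes = c(M$classes, rep(c("control_min", "control_max"),
                               each = replicates)),
    sample_ids = c(M$sample_ids,
                   paste0("control_min_", seq_len(replicates)),
                   paste0("control_max_", seq_len(replicates))),
    feature_names = M$feature_names
  )
}

#' Control-point coordinates for the two acquisition presets
#'
#' In the `(dispersion, focus, wavenhl)` feature space the controls are
#' `C_min = (0, -1, 0)` for both presets and `C_max = (5500, 1, 120000)`
#' at 3 T versus `(307, 1, 120000)` at 1.5 T — only the dispersion axis
#' differs, reflecting the narrower dynamic range of the 1.5 T samples.
#'
#' @param preset `"t3"` or `"t1p5"`.
#' @return List with `c_min`, `c_max` and `feature_names`.
#' @export
control_points <- function(preset = c("t3", "t1p5")) {
  preset <- match.arg(preset)
  list(
    c_min = c(0, -1, 0),
    c_max = if (preset == "t3") c(5500, 1, 120000) else c(307, 1, 120000),
    feature_names = c("dispersion", "focus", "wavenhl")
  )
}

#' Fisher coefficient and 1-NN error in one call
#'
#' @inheritParams fisher_coefficient
#' @inheritParams loo_1nn_mde
#' @return An object of class `fisher_analysis` holding the
#'   [fisher_coefficient()] result and the [loo_1nn_mde()] result.
#' @export
fisher_analysis <- function(M, f_max = 1e6, standardize = FALSE) {
  structure(
    list(fisher = fisher_coefficient(M, f_max),
         nn = loo_1nn_mde(M, standardize)),
    class = "fisher_analysis"
  )
}

#' @export
print.fisher_analysis <- function(x, ...) {
  print(x$fisher)
  print(x$nn)
  invisible(x)
}
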