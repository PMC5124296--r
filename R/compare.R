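# Group-level statistics for the 1.5 T vs 3 T comparison: best-n
# selection, pooled two-sample t-tests, between-ROI variability and the
# summary table. Unlike the feature module, means and standard deviations
# here are sample (n-1) statistics, the convention of the tabulated group
# results this module reproduces.

#' Select the n best index values of a cell
#'
#' For the focus index "best" means closest to the ideal of zero (the `n`
#' smallest absolute values); for the dispersion index it means the `n`
#' largest values (greater inter-ROI spread). Survivors keep their original
#' relative order.
#'
#' @param values Numeric vector, length >= `n`.
#' @param n Number of values to keep (default 9).
#' @param criterion `"focus_best"` or `"dispersion_best"`.
#' @return Numeric vector of length `n`.
#' @export
select_best <- function(values, n = 9L,
                        criterion = c("focus_best", "dispersion_best")) {
  criterion <- match.arg(criterion)
  values <- as.numeric(values)
  if (length(values) < n) stop("fewer than n values to select from")
  key <- if (criterion == "focus_best") abs(values) else -values
  keep <- sort(order(key)[seq_len(n)])
  values[keep]
}

#' Pooled (equal-variance) two-sample t-test
#'
#' Classic two-sided pooled t: `sp^2 = [(n_a-1) s_a^2 + (n_b-1) s_b^2] /
#' (n_a + n_b - 2)`, `t = (xbar_a - xbar_b) / sqrt(sp^2 (1/n_a + 1/n_b))`,
#' `df = n_a + n_b - 2`. The pooled (not Welch) form is used because it is
#' the one the tabulated `t(16)` group results follow.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return An object of class `pooled_t_test` with `t`, `df`, `p`
#'   (two-sided), `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
pooled_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance: t undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value,
         mean_a = mean(a), mean_b = mean(b),
         sd_a = stats::sd(a), sd_b = stats::sd(b),
         n_a = length(a), n_b = length(b)),
    class = "pooled_t_test"
  )
}

#' @export
print.pooled_t_test <- function(x, ...) {
  cat(sprintf("<pooled_t_test> t(%d) = %.4g, p = %.4g\n", x$df, x$t, x$p))
  cat(sprintf("  a: n=%d m=%.4g sd=%.4g | b: n=%d m=%.4g sd=%.4g\n",
              x$n_a, x$mean_a, x$sd_a, x$n_b, x$mean_b, x$sd_b))
  invisible(x)
}

#' Between-ROI variability of a scalar index
#'
#' The between-class variance `D^2` of the feature-selection coefficient,
#' computed over the ROI classes of a single scalar index (class
#' probabilities `P_k = n_k / N`). Used to quantify how far apart the
#' region classes sit.
#'
#' @param values_by_roi Named list mapping ROI label to a numeric vector of
#'   index values; >= 2 non-empty classes.
#' @return Non-negative scalar `D^2`.
#' @export
roi_variability <- function(values_by_roi) {
  if (length(values_by_roi) < 2) stop("need >= 2 ROI classes")
  if (any(vapply(values_by_roi, length, integer(1)) == 0))
    stop("every ROI class must be non-empty")
  vals <- unlist(values_by_roi, use.names = FALSE)
  labs <- rep(names(values_by_roi),
              vapply(values_by_roi, length, integer(1)))
  M <- feature_matrix(matrix(vals, ncol = 1), classes = labs,
                      feature_names = "index")
  fisher_coefficient(M)$D2
}

#' Group summary table with pooled t-tests
#'
#' Takes a long-format table of index values (`modality` in
#' `{"t1p5", "t3"}`, `age_group`, `index_kind` in `{"focus",
#' "dispersion"}`, `value`), keeps the best `n_select` values per cell
#' ([select_best()], criterion matched to the index kind), and reports per
#' cell the sample mean `m` and sample sd, plus the pooled two-sample t of
#' 1.5 T versus 3 T within each (index kind, age group) pair. The t sign
#' convention is `t1p5 - t3`.
#'
#' @param df Data frame with columns `modality`, `age_group`, `index_kind`,
#'   `value`; every (index_kind, age_group, modality) cell must hold at
#'   least `n_select` values.
#' @param n_select Values kept per cell (default 9).
#' @return Data frame with one row per cell: `index_kind`, `age_group`,
#'   `modality`, `n`, `m`, `sd`, `t`, `df`, `p` (test columns repeated on
#'   both rows of a pair).
#' @export
summary_table <- function(df, n_select = 9L) {
  need <- c("modality", "age_group", "index_kind", "value")
  if (!all(need %in% names(df)))
    stop("df needs columns: ", paste(need, collapse = ", "))
  out <- NULL
  for (kind in unique(df$index_kind)) {
    crit <- if (kind == "focus") "focus_best" else "dispersion_best"
    for (g in unique(df$age_group)) {
      cells <- lapply(c(t1p5 = "t1p5", t3 = "t3"), function(mod) {
        v <- df$value[df$modality == mod & df$age_group == g &
                        df$index_kind == kind]
        if (length(v) < n_select)
          stop(sprintf("incomplete cell: %s/%s/%s has %d < %d values",
                       kind, g, mod, length(v), n_select))
        select_best(v, n_select, crit)
      })
      tt <- pooled_t_test(cells$t1p5, cells$t3)
      rows <- data.frame(
        index_kind = kind, age_group = g,
        modality = c("t1p5", "t3"),
        n = n_select,
        m = c(mean(cells$t1p5), mean(cells$t3)),
        sd = c(stats::sd(cells$t1p5), stats::sd(cells$t3)),
        t = tt$t, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE
      )
      out <- rbind(out, rows)
    }
  }
  out
}
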