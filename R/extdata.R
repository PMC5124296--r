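# Accessors for the small CSV fixtures bundled under inst/extdata.

#' Bundled example index measurements from a 1.5 T vs 3 T fetal-brain study
#'
#' Long-format table of focus-index and dispersion-index values measured
#' on fetal-brain regions of interest, nine best-selected values per cell,
#' split by scanner field strength (`t1p5`, `t3`) and gestational age
#' group (`g1` 20-28 weeks, `g2` 29-40 weeks). Feed it to
#' [summary_table()] to reproduce the group statistics.
#'
#' @return Data frame with columns `modality`, `age_group`, `index_kind`,
#'   `value`.
#' @export
example_grouped_indices <- function() {
  path <- system.file("extdata", "grouped_indices.csv",
                      package = "mritexture", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled control-point feature matrices
#'
#' Three 4-row, two-class matrices in the `(dispersion, focus, wavenhl)`
#' space: the unperturbed control configurations for each preset (two
#' replicates each of `C_min` and `C_max`), and the perturbed 3 T
#' configuration in which one `C_max` replicate is displaced to
#' `(0, -1, 60000)` — the worked example in which the feature-selection
#' coefficient drops to about 18 and the leave-one-out 1-NN error rises
#' to 25%.
#'
#' @param name `"t3"`, `"t1p5"` or `"t3_perturbed"`.
#' @return A [feature_matrix()].
#' @export
control_matrix <- function(name = c("t3", "t1p5", "t3_perturbed")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("control_matrix_", name, ".csv"),
                      package = "mritexture", mustWork = TRUE)
  read_feature_matrix(path)
}
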