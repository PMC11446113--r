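#' Published cohort counts and their derived percentages
#'
#' The package ships the published renal-lesion cohort's histology counts
#' (`inst/extdata/cohort_counts.csv`) as a plain-text input. This helper
#' recomputes the derived fractions from those counts: malignant fraction
#' of the cohort, clear-cell fraction among malignant lesions,
#' angiomyolipoma fraction among benign lesions, the development/test split
#' proportions, and the small-renal-lesion fraction.
#'
#' @param path CSV with columns `group`, `count`; defaults to the shipped
#'   table.
#' @return named numeric vector of percentages (0-100 scale, unrounded).
#' @export
cohort_count_summary <- function(path = system.file(
  "extdata", "cohort_counts.csv", package = "renorad")) {
  counts <- read.csv(path, stringsAsFactors = FALSE)
  cn <- setNames(counts$count, counts$group)
  c(malignant_pct = 100 * cn[["malignant"]] / cn[["total"]],
    benign_pct = 100 * cn[["benign"]] / cn[["total"]],
    clear_cell_among_malignant_pct =
      100 * cn[["clear_cell_rcc"]] / cn[["malignant"]],
    aml_among_benign_pct = 100 * cn[["angiomyolipoma"]] / cn[["benign"]],
    development_pct = 100 * cn[["development"]] / cn[["total"]],
    test_pct = 100 * cn[["test"]] / cn[["total"]],
    male_pct = 100 * cn[["male"]] / cn[["total"]],
    srl_pct = 100 * cn[["srl"]] / cn[["total"]])
}
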