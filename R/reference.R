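#' Published group-comparison p-values from a healthy-aging cohort
#'
#' Two-group (younger vs older adults) comparison p-values for OEF, CBF and
#' CMRO2 across the 11 standard regions, as published for a healthy-aging
#' qBOLD/ASL cohort. Entries printed as "< 0.001" are stored as 0.001 (an
#' upper bound). Useful as a worked input for [bh_adjust()]: applying the
#' step-up adjustment within each metric family (m = 11) reproduces the
#' published corrected q-values.
#'
#' @return Tibble with columns `family` (`oef`, `cbf`, `cmro2`), `region`,
#'   and `p`.
#' @examples
#' tab <- reference_group_pvalues()
#' cm <- tab[tab$family == "cmro2", ]
#' round(bh_adjust(cm$p)[cm$region == "ag"], 3) # 0.121
#' @export
reference_group_pvalues <- function() {
  path <- system.file("extdata", "aging_cohort_tests.tsv",
                      package = "oxibold", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Published sex-by-age-group contingency counts
#'
#' Counts of males and females in the younger and older groups of the same
#' published healthy-aging cohort (rows: young, old; columns: male, female).
#' The Pearson chi-square without continuity correction on this table is the
#' published sex-balance check.
#'
#' @return 2x2 integer matrix with dimnames.
#' @examples
#' chi_square_2x2(reference_sex_counts())
#' @export
reference_sex_counts <- function() {
  matrix(c(11L, 14L, 4L, 5L), nrow = 2,
         dimnames = list(group = c("young", "old"), sex = c("M", "F")))
}
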