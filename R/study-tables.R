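#' Published study summary tables
#'
#' Printed summary statistics from the validation study, shipped as plain
#' CSV inputs: per-measure accuracy summaries against the reference
#' modality (means, SDs, Pearson r and the CT-to-reference calibration
#' lines), the pilot-cohort category counts, and the unadjusted
#' fracture-group comparison summaries (group means, SDs, mean
#' differences, pooled SDs, p-values, effect sizes). These are inputs for
#' worked examples and consistency checks, not outputs of this package.
#'
#' @param table one of `"accuracy"`, `"cohort"`, `"fracture_groups"`.
#' @return A tibble.
#' @export
study_table <- function(table = c("accuracy", "cohort",
                                  "fracture_groups")) {
  table <- match.arg(table)
  file <- switch(table,
                 accuracy = "cadaver_accuracy_summary.csv",
                 cohort = "pilot_cohort_counts.csv",
                 fracture_groups = "fracture_group_summary.csv")
  path <- system.file("extdata", file, package = "bonemicro",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
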