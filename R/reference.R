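#' Published summary statistics of the reference NDAR cohort
#'
#' The clinical cohort this pipeline was designed around (NDAR study
#' 2021; 72 ASD / 113 TD, 61 ADOS-scored subjects) is restricted and
#' cannot be redistributed, but its published summary statistics can:
#' the per-subgroup demographic moments (count, age mean, age SD by
#' diagnosis and sex) and the per-feature counts of severity-
#' correlated features found by the |r| >= 0.32 screen. These
#' summaries serve as inputs — e.g. [demographic_tests_from_moments()]
#' reconstructs the cohort's age comparison exactly from the moments —
#' and as the template the synthetic generator's demographics mirror.
#'
#' @return A list with `demographics` (data frame `label, sex, n,
#'   age_mean, age_sd`), `screen_counts` (data frame `feature, count`)
#'   and `optimal_prefix` (named vector: reported optimal ranked-
#'   prefix lengths per modality, sMRI 34 and fMRI 4).
#' @export
reference_cohort_summaries <- function() {
  dem <- read.csv(system.file("extdata", "reference_demographics.csv",
                              package = "neurofuse"),
                  stringsAsFactors = FALSE)
  cnt <- read.csv(system.file("extdata", "reference_screen_counts.csv",
                              package = "neurofuse"),
                  stringsAsFactors = FALSE)
  list(demographics = dem,
       screen_counts = cnt,
       optimal_prefix = c(sMRI = 34L, fMRI = 4L))
}
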