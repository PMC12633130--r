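# Published summary statistics of the MDACC oropharyngeal-cancer cohort
# (N = 676) that parameterise the default schema and synthetic-cohort
# generator. Counts are the authoritative quantities; percentages are kept
# as printed for cross-checking (a handful of printed percentages are
# internally inconsistent with their counts; see cohort_demographics()).

#' Published categorical demographics of the reference cohort
#'
#' One row per (variable, category) with the category count among the 676
#' patients of the reference cohort and the percentage as printed in the
#' source demographic tables. Counts are used to derive default generator
#' probabilities; percentages are retained for arithmetic cross-checks.
#'
#' @return A tibble with columns `variable`, `category`, `count`,
#'   `percent_printed`, and `group` (feature group the variable belongs to).
#' @export
#' @examples
#' cohort_demographics() |> dplyr::filter(variable == "gender")
cohort_demographics <- function() {
  tibble::tribble(
    ~variable, ~category, ~count, ~percent_printed, ~group,
    "gender", "Male", 616L, 91.1, "PTF",
    "gender", "Female", 60L, 8.9, "PTF",
    "ethnicity", "Not Hispanic or Latino", 612L, 90.5, "PTF",
    "ethnicity", "Hispanic or Latino", 49L, 7.2, "PTF",
    "ethnicity", "Unknown", 15L, 2.2, "PTF",
    "race", "White", 640L, 94.7, "PTF",
    "race", "Black or African American", 14L, 2.1, "PTF",
    "race", "Other Race", 17L, 2.5, "PTF",
    "race", "Asian", 4L, 0.6, "PTF",
    "race", "American Indian/Alaska Native", 1L, 0.1, "PTF",
    "smoking_status", "4", 290L, 42.9, "PTF",
    "smoking_status", "5", 344L, 50.9, "PTF",
    "smoking_status", "1", 26L, 3.8, "PTF",
    "smoking_status", "2", 5L, 0.7, "PTF",
    "smoking_status", "7", 6L, 0.9, "PTF",
    "smoking_status", "9", 2L, 0.3, "PTF",
    "smoking_status", "10", 3L, 0.4, "PTF",
    "site_of_tumor", "BOT (base of tongue)", 337L, 49.9, "PTF",
    "site_of_tumor", "NOS (not ow specified)", 10L, 1.5, "PTF",
    "site_of_tumor", "Tonsil", 312L, 46.2, "PTF",
    "site_of_tumor", "Soft Palate", 8L, 1.2, "PTF",
    "site_of_tumor", "GPS", 6L, 0.9, "PTF",
    "site_of_tumor", "Pharyngeal Wall", 3L, 0.4, "PTF",
    "ajcc_version", "7th Version", 48L, 7.1, "PTF",
    "ajcc_version", "8th Version", 628L, 92.9, "PTF",
    "p16_hpv_postive", "Yes", 596L, 88.2, "PTF",
    "p16_hpv_postive", "No", 56L, 8.3, "PTF",
    "p16_hpv_postive", "Unknown", 24L, 3.6, "PTF",
    "tumor_laterality", "Right", 345L, 51.0, "PTF",
    "tumor_laterality", "Left", 314L, 46.4, "PTF",
    "tumor_laterality", "Bilateral", 17L, 2.5, "PTF",
    "t_nominal", "t1", 223L, 32.8, "PTF",
    "t_nominal", "t0", 9L, 1.3, "PTF",
    "t_nominal", "t2", 243L, 35.9, "PTF",
    "t_nominal", "t3", 116L, 17.0, "PTF",
    "t_nominal", "t4", 82L, 12.1, "PTF",
    "t_nominal", "tx", 3L, 0.4, "PTF",
    "n_nominal", "n2b", 35L, 5.2, "PTF",
    "n_nominal", "n1", 446L, 65.7, "PTF",
    "n_nominal", "n2", 94L, 13.9, "PTF",
    "n_nominal", "n0", 54L, 8.0, "PTF",
    "n_nominal", "n2c", 23L, 3.4, "PTF",
    "n_nominal", "n3", 18L, 2.7, "PTF",
    "n_nominal", "nx", 2L, 0.3, "PTF",
    "n_nominal", "n2a", 4L, 0.6, "PTF",
    "m", "m0", 661L, 97.8, "PTF",
    "m", "mx", 10L, 1.5, "PTF",
    "m", "m1", 5L, 0.7, "PTF",
    "status_at_enrollememt", "Previously_Untreated", 605L, 89.5, "PTF",
    "status_at_enrollememt", "Previously_Treated", 71L, 10.5, "PTF",
    "definitive", "No", 609L, 90.1, "ACTIONS",
    "definitive", "Yes", 67L, 9.9, "ACTIONS",
    "induction", "No", 600L, 88.8, "ACTIONS",
    "induction", "Yes", 76L, 11.2, "ACTIONS",
    "radio/chemo", "2 Yes with concurrent chemo?", 473L, 70.0, "ACTIONS",
    "radio/chemo", "0 No", 29L, 4.3, "ACTIONS",
    "radio/chemo", "1 Yes", 174L, 25.7, "ACTIONS",
    "ENE", "Positive", 50L, 7.4, "PIO",
    "ENE", "Negative", 13L, 1.9, "PIO",
    "ENE", "Unknown", 613L, 90.6, "PIO",
    "Margin", "Negative", 38L, 5.6, "PIO",
    "Margin", "Positive", 14L, 2.1, "PIO",
    "Margin", "<1mm", 3L, 0.4, "PIO",
    "Margin", "<2mm", 1L, 0.1, "PIO",
    "Margin", "<1m", 1L, 0.1, "PIO",
    "Margin", "<2m", 1L, 0.1, "PIO",
    "Margin", "1mm", 1L, 0.1, "PIO",
    "rt_type", "IMPT", 165L, 24.4, "PIO",
    "rt_type", "Vmat", 389L, 57.5, "PIO",
    "rt_type", "IMRT", 105L, 15.5, "PIO",
    "rt_type", "3d Conformal", 2L, 0.3, "PIO",
    "rt_type", "Other", 15L, 2.2, "PIO",
    "relapse_yr3", "False", 153L, 22.6, "TPO",
    "relapse_yr3", "True", 35L, 5.2, "TPO"
  )
}

#' Published numerical demographics of the reference cohort
#'
#' Mean and standard deviation for every numerical feature, as printed in
#' the source tables for the all-patients column (N = 676). The four
#' MDASI-HN symptoms modelled are fatigue, drymouth, swallow and taste at
#' five assessments (pre-treatment baseline, end of radiotherapy, week 6,
#' month 3, month 12); the source tables print moments only for fatigue and
#' drymouth, so the swallow/taste rows carry this package's own documented
#' defaults (`printed = FALSE`): means chosen as clinically plausible for
#' oropharyngeal cohorts and standard deviations matching the test-set
#' variance implied by the published constant-mean benchmark errors.
#'
#' @return A tibble with columns `variable`, `mean`, `sd`, `group`,
#'   `printed`.
#' @export
cohort_moments <- function() {
  tibble::tribble(
    ~variable, ~mean, ~sd, ~group, ~printed,
    "age", 60.49, 8.92, "PTF", TRUE,
    "tobacco_packs_per_day", 0.65, 0.72, "PTF", TRUE,
    "tobacco_used_years", 13.49, 15.47, "PTF", TRUE,
    "pack_years", 14.99, 22.78, "PTF", TRUE,
    "mdasi_baseline_fatigue", 2.00, 2.36, "PTF", TRUE,
    "mdasi_baseline_drymouth", 1.08, 2.02, "PTF", TRUE,
    "mdasi_baseline_swallow", 1.20, 2.10, "PTF", FALSE,
    "mdasi_baseline_taste", 0.80, 1.80, "PTF", FALSE,
    "rt_dose", 6823.85, 307.80, "PIO", TRUE,
    "rt_fraction", 32.56, 1.27, "PIO", TRUE,
    "mdasi_endrt_fatigue", 4.67, 2.62, "PRS", TRUE,
    "mdasi_endrt_drymouth", 4.97, 2.96, "PRS", TRUE,
    "mdasi_endrt_swallow", 4.50, 3.13, "PRS", FALSE,
    "mdasi_endrt_taste", 5.00, 2.68, "PRS", FALSE,
    "mdasi_wk6_fatigue", 3.01, 2.38, "PRS", TRUE,
    "mdasi_wk6_drymouth", 4.04, 2.78, "PRS", TRUE,
    "mdasi_wk6_swallow", 3.00, 2.53, "PRS", FALSE,
    "mdasi_wk6_taste", 4.00, 2.76, "PRS", FALSE,
    "mdasi_m3_fatigue", 2.05, 2.14, "PRS", TRUE,
    "mdasi_m3_drymouth", 4.22, 2.79, "PRS", TRUE,
    "mdasi_m3_swallow", 2.20, 2.27, "PRS", FALSE,
    "mdasi_m3_taste", 3.00, 2.80, "PRS", FALSE,
    "mdasi_m12_fatigue", 1.76, 1.99, "PRS", TRUE,
    "mdasi_m12_drymouth", 3.35, 2.69, "PRS", TRUE,
    "mdasi_m12_swallow", 1.90, 2.50, "PRS", FALSE,
    "mdasi_m12_taste", 2.00, 2.75, "PRS", FALSE
  )
}

#' Published first-cycle treatment-sequence patterns
#'
#' The eight mined first-cycle treatment-sequence patterns with their counts
#' among the 651 patients whose sequences matched a pattern, together with
#' the decoding into the three first-cycle action variables:
#' definitive surgery (no/yes), induction therapy (no/yes), and
#' radiotherapy (no / yes / yes with concurrent chemotherapy).
#'
#' @return A tibble with columns `pattern`, `count`, `definitive`,
#'   `induction`, `radio_chemo`.
#' @export
#' @examples
#' treatment_sequences()
treatment_sequences <- function() {
  tibble::tribble(
    ~pattern, ~count, ~definitive, ~induction, ~radio_chemo,
    "n/a -> n/a -> radiotherapy (w/ concurrent chemotherapy)", 398L, "no", "no", "yes_with_concurrent_chemotherapy",
    "n/a -> n/a -> radiotherapy", 120L, "no", "no", "yes",
    "n/a -> induction therapy -> radiotherapy (w/ concurrent chemotherapy)", 52L, "no", "yes", "yes_with_concurrent_chemotherapy",
    "definitive surgery -> n/a -> radiotherapy", 29L, "yes", "no", "yes",
    "n/a -> induction therapy -> radiotherapy", 19L, "no", "yes", "yes",
    "definitive surgery -> n/a -> radiotherapy (w/ concurrent chemotherapy)", 19L, "yes", "no", "yes_with_concurrent_chemotherapy",
    "definitive surgery -> n/a -> n/a", 10L, "yes", "no", "no",
    "n/a -> induction therapy -> n/a", 4L, "no", "yes", "no"
  )
}

# Number of patients in the reference cohort / in the mined-sequence table.
REFERENCE_N <- 676L
SEQUENCE_N <- 651L
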