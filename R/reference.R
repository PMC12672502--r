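#' Published adjusted odds ratios of the final multilevel model
#'
#' The 14 risk conditions of the Sao Paulo 2009-2018 neonatal mortality score
#' with their adjusted odds ratios and published integer points, as printed in
#' the study's final-model table. These serve as inputs: the scaling constants
#' and weights can be recomputed from the ORs alone and checked against the
#' printed points.
#'
#' @return tibble with `condition`, `label`, `or`, `published_weight`.
#' @export
ref_model_or <- function() {
  tibble::tibble(
    condition = c("male", "low_bw", "extreme_maternal_age",
                  "severity_1", "severity_2", "severity_3",
                  "cesarean_term", "cesarean_preterm", "vaginal_preterm",
                  "few_prenatal", "spring_summer", "multiple_preg",
                  "low_nurse_density", "low_insurance"),
    label = c("Male sex", "Birth weight <2,500 g", "Maternal age <17 or >=40 years",
              "Congenital anomaly - Grade 1", "Congenital anomaly - Grade 2",
              "Congenital anomaly - Grade 3",
              "Cesarean delivery, >=37 weeks", "Cesarean delivery, <37 weeks",
              "Vaginal delivery, <37 weeks",
              "<7 prenatal visits", "Season: Spring/Summer", "Multiple pregnancy",
              "Nurse density in public system (<mean)",
              "Private health insurance coverage (<mean)"),
    or = c(1.2491, 8.4592, 1.0733, 9.1751, 58.620, 284.78,
           1.2742, 5.0770, 8.4771, 2.7434, 1.0412, 1.0967, 1.0618, 1.1765),
    published_weight = c(1L, 4L, 1L, 4L, 7L, 10L, 1L, 4L, 4L, 3L, 1L, 1L, 1L, 1L)
  )
}

#' Published per-cutoff performance tables
#'
#' The internal (2009-2018 development cohort) and external (2008 cohort)
#' validation tables of the published score: sensitivity, specificity, PPV,
#' NPV, correctly-classified percentage and Youden index at every integer
#' cutoff (classification is positive when score >= cutoff). The internal
#' table's last printed row (">25") is encoded as cutoff 26, the external
#' ">24" as 25. NPV is undefined when no record is classified negative.
#'
#' @param cohort `"internal"` or `"external"`.
#' @return tibble with columns `cutoff, sensitivity, specificity, ppv, npv,
#'   correctly_classified, youden` (percentages).
#' @export
ref_cutoff_table <- function(cohort = c("internal", "external")) {
  cohort <- match.arg(cohort)
  if (cohort == "internal") {
    tibble::tribble(
      ~cutoff, ~sensitivity, ~specificity, ~ppv, ~npv, ~correctly_classified, ~youden,
      0L, 100.00, 0.00, 0.72, NA, 0.72, 0.00,
      1L, 99.90, 0.50, 0.73, 99.85, 1.22, 0.40,
      2L, 99.18, 4.79, 0.75, 99.88, 5.47, 3.97,
      3L, 96.91, 19.88, 0.87, 99.89, 20.44, 16.79,
      4L, 93.14, 44.63, 1.21, 99.89, 44.98, 37.77,
      5L, 89.93, 64.90, 1.83, 99.89, 65.08, 54.83,
      6L, 87.64, 75.51, 2.54, 99.88, 75.59, 63.15,
      7L, 85.14, 83.21, 3.56, 99.87, 83.23, 68.35,
      8L, 82.44, 89.22, 5.28, 99.86, 89.17, 71.66,
      9L, 80.41, 91.95, 6.79, 99.85, 91.87, 72.36,
      10L, 77.57, 93.46, 7.95, 99.83, 93.34, 71.03,
      11L, 72.07, 95.20, 9.87, 99.79, 95.04, 67.28,
      12L, 65.31, 96.69, 12.56, 99.74, 96.46, 61.99,
      13L, 56.82, 97.61, 14.78, 99.68, 97.32, 54.43,
      14L, 40.73, 98.51, 16.59, 99.56, 98.09, 39.24,
      15L, 21.46, 99.40, 20.78, 99.43, 98.84, 20.87,
      16L, 10.96, 99.85, 34.42, 99.35, 99.20, 10.81,
      17L, 8.03, 99.94, 48.41, 99.33, 99.27, 7.97,
      18L, 6.13, 99.96, 52.52, 99.32, 99.28, 6.09,
      19L, 4.43, 99.98, 58.70, 99.31, 99.29, 4.41,
      20L, 3.23, 99.99, 64.47, 99.30, 99.29, 3.21,
      21L, 2.35, 99.99, 69.41, 99.29, 99.29, 2.34,
      22L, 1.34, 100.00, 74.32, 99.29, 99.28, 1.34,
      23L, 0.83, 100.00, 82.28, 99.28, 99.28, 0.83,
      24L, 0.48, 100.00, 84.26, 99.28, 99.28, 0.48,
      25L, 0.19, 100.00, 85.56, 99.28, 99.28, 0.19,
      26L, 0.03, 100.00, 100.00, 99.28, 99.28, 0.03
    )
  } else {
    tibble::tribble(
      ~cutoff, ~sensitivity, ~specificity, ~ppv, ~npv, ~correctly_classified, ~youden,
      1L, 99.97, 0.55, 0.77, 99.96, 1.31, 0.52,
      2L, 98.84, 7.87, 0.82, 99.89, 8.56, 6.71,
      3L, 95.22, 29.58, 1.03, 99.88, 30.08, 24.80,
      4L, 91.15, 55.38, 1.54, 99.88, 55.65, 46.53,
      5L, 87.84, 70.52, 2.24, 99.87, 70.65, 58.36,
      6L, 85.26, 79.51, 3.10, 99.86, 79.55, 64.77,
      7L, 82.03, 87.52, 4.81, 99.84, 87.48, 69.56,
      8L, 79.53, 91.78, 6.92, 99.83, 91.69, 71.31,
      9L, 78.03, 93.36, 8.28, 99.82, 93.24, 71.39,
      10L, 74.03, 94.84, 9.93, 99.79, 94.69, 68.88,
      11L, 67.22, 96.50, 12.85, 99.74, 96.28, 63.72,
      12L, 60.69, 97.48, 15.60, 99.69, 97.20, 58.17,
      13L, 50.67, 98.16, 17.45, 99.62, 97.80, 48.83,
      14L, 31.39, 99.06, 20.48, 99.47, 98.55, 30.45,
      15L, 14.69, 99.73, 29.36, 99.35, 99.08, 14.42,
      16L, 8.44, 99.92, 45.35, 99.30, 99.22, 8.36,
      17L, 6.71, 99.96, 54.39, 99.29, 99.25, 6.67,
      18L, 4.75, 99.98, 60.33, 99.27, 99.25, 4.73,
      19L, 3.12, 99.99, 66.85, 99.26, 99.25, 3.11,
      20L, 2.27, 99.99, 70.97, 99.25, 99.25, 2.26,
      21L, 1.39, 100.00, 75.00, 99.25, 99.24, 1.39,
      22L, 0.70, 100.00, 79.41, 99.24, 99.24, 0.70,
      23L, 0.39, 100.00, 93.75, 99.24, 99.24, 0.39,
      24L, 0.23, 100.00, 100.00, 99.24, 99.24, 0.23,
      25L, 0.05, 100.00, 100.00, 99.24, 99.24, 0.05
    )
  }
}

#' Published risk-group summaries
#'
#' Birth and death counts per risk group in the published internal and
#' external validations.
#'
#' @param cohort `"internal"` or `"external"`.
#' @return tibble with `group, score_min, score_max, births, deaths`.
#' @export
ref_risk_groups <- function(cohort = c("internal", "external")) {
  cohort <- match.arg(cohort)
  if (cohort == "internal") {
    tibble::tibble(
      group = c("Very Low Risk", "Low to Moderate Risk", "High Risk", "Very High Risk"),
      score_min = c(0L, 5L, 10L, 16L), score_max = c(4L, 9L, 15L, NA),
      births = c(3655902L, 1612024L, 387030L, 13055L),
      deaths = c(4129L, 5067L, 27316L, 4493L)
    )
  } else {
    tibble::tibble(
      group = c("Very Low Risk", "Low to Moderate Risk", "High Risk", "Very High Risk"),
      score_min = c(0L, 5L, 10L, 16L), score_max = c(4L, 9L, 15L, NA),
      births = c(356156L, 123209L, 28151L, 721L),
      deaths = c(471L, 535L, 2541L, 327L)
    )
  }
}

#' Published cohort totals
#'
#' Birth and neonatal-death counts of the study cohorts: the full descriptive
#' cohort, the complete-case modelling cohort, and the external 2008 cohort.
#'
#' @return tibble with `cohort, births, deaths`.
#' @export
ref_cohort_counts <- function() {
  tibble::tibble(
    cohort = c("descriptive", "modelling", "external"),
    births = c(6113178L, 5668011L, 508237L),
    deaths = c(47036L, 41005L, 3874L)
  )
}
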