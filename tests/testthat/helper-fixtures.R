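# Fixtures are built in code at test time; no files ship with the package.

# A derived-predictor tibble with every model variable at its reference level
# unless overridden; vectors recycle to length n.
toy_predictors <- function(n = 1,
                           male = 0L, low_bw = 0L, extreme_maternal_age = 0L,
                           severity_grade = 0L, delivery_ga = "vaginal_term",
                           few_prenatal = 0L, spring_summer = 0L,
                           multiple_preg = 0L, low_nurse_density = 0L,
                           low_insurance = 0L,
                           municipality_code = "3500001",
                           neonatal_death = FALSE) {
  tibble::tibble(
    male = rep_len(as.integer(male), n),
    low_bw = rep_len(as.integer(low_bw), n),
    extreme_maternal_age = rep_len(as.integer(extreme_maternal_age), n),
    severity_grade = rep_len(as.integer(severity_grade), n),
    delivery_ga = factor(rep_len(delivery_ga, n),
                         levels = c("vaginal_term", "cesarean_term",
                                    "cesarean_preterm", "vaginal_preterm")),
    few_prenatal = rep_len(as.integer(few_prenatal), n),
    spring_summer = rep_len(as.integer(spring_summer), n),
    multiple_preg = rep_len(as.integer(multiple_preg), n),
    low_nurse_density = rep_len(as.integer(low_nurse_density), n),
    low_insurance = rep_len(as.integer(low_insurance), n),
    municipality_code = rep_len(municipality_code, n),
    neonatal_death = rep_len(neonatal_death, n),
    complete = TRUE
  )
}

# The reference score table rebuilt from the published adjusted ORs.
reference_score_table <- function() {
  assign_weights(ref_model_or()[, c("condition", "or")])
}

# Minimal cohort CSV on disk; returns the path.
write_toy_cohort_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste(c("record_id", "sex", "birthweight_g", "maternal_age_y",
                    "gestational_weeks", "delivery", "prenatal_visits", "pregnancy",
                    "birth_date", "municipality_code", "anomaly_flag", "anomaly_codes",
                    "neonatal_death"), collapse = ",")
  writeLines(c(header, rows), path)
  path
}

# Exhaustive pair-counting AUC: the probability a random death outranks a
# random survivor, ties counting one half.
pair_count_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
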