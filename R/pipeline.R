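#' Municipal dichotomous flags for the individual-level model
#'
#' Dichotomizes the named indicators at their pooled development means
#' (value < mean = risk flag 1) and returns them under the model's flag
#' names. Pass the stored `means` when flagging a validation cohort so the
#' development cutpoints are reused.
#'
#' @param indicators indicator tibble (`municipality_code`, `year`, columns).
#' @param flag_map named character vector mapping model flag name ->
#'   indicator column (default: the two municipal conditions of the final
#'   model).
#' @param means optional named vector of stored development means (named by
#'   indicator column).
#' @return list: `flags` tibble (`municipality_code`, `year`, one 0/1 column
#'   per flag), `means`.
#' @export
municipal_flags <- function(indicators,
                            flag_map = c(low_nurse_density = "nurse_density",
                                         low_insurance = "insurance_coverage"),
                            means = NULL) {
  missing_ind <- setdiff(unname(flag_map), names(indicators))
  if (length(missing_ind) > 0) {
    stop("indicator table lacks column(s): ", paste(missing_ind, collapse = ", "),
         call. = FALSE)
  }
  dich <- dichotomize_by_mean(indicators[unname(flag_map)], means = means)
  flags <- indicators[, c("municipality_code", "year")]
  for (i in seq_along(flag_map)) {
    flags[[names(flag_map)[i]]] <- dich$flags[[flag_map[[i]]]]
  }
  list(flags = flags, means = dich$means)
}

#' Develop the risk score from a cohort and indicator table
#'
#' Runs the development pipeline end to end: empirical severity grading of
#' anomalies, the ecological indicator screen, municipal flag construction,
#' predictor derivation, univariate screening (p < 0.20), the multilevel
#' ENTER fit with non-significant variables pruned, and conversion of the
#' adjusted ORs into the 1-10 integer score table.
#'
#' @param cohort birth-cohort tibble (with outcome).
#' @param indicators municipal indicator tibble.
#' @param nAGQ quadrature points for the multilevel fit.
#' @param flag_map see [municipal_flags()].
#' @param run_ecological_screen run [municipal_screen()] and report it
#'   (diagnostic; the flags in `flag_map` define the municipal conditions of
#'   the score regardless).
#' @return list of class `score_development`: frozen artifacts
#'   (`severity_table`, `means`, `score_table`) plus `fit`, `univariate`,
#'   `ecological`, `predictors`, `scores`.
#' @export
develop_score <- function(cohort, indicators, nAGQ = 11,
                          flag_map = c(low_nurse_density = "nurse_density",
                                       low_insurance = "insurance_coverage"),
                          run_ecological_screen = TRUE) {
  cats <- parse_anomaly_codes(cohort$anomaly_codes)
  severity_table <- build_severity_table(cats, cohort$neonatal_death)

  ecological <- if (run_ecological_screen) municipal_screen(cohort, indicators) else NULL
  mf <- municipal_flags(indicators, flag_map)
  predictors <- derive_predictors(cohort, severity_table, mf$flags)

  cc <- predictors$complete
  uni <- univariate_screen(predictors[cc, ], predictors$neonatal_death[cc])
  individual_vars <- setdiff(unique(variable_of_condition), names(flag_map))
  passing <- unique(uni$variable[uni$pass])
  enter_vars <- c(intersect(individual_vars, passing), names(flag_map))
  enter_conditions <- condition_order[variable_of_condition[condition_order] %in% enter_vars]

  fit <- fit_multilevel_logistic(
    predictors[cc, ], predictors$neonatal_death[cc],
    predictors$municipality_code[cc],
    conditions = enter_conditions, nAGQ = nAGQ
  )
  score_table <- assign_weights(fit)
  scores <- score_records(predictors, score_table)
  structure(list(
    severity_table = severity_table, means = mf$means, muni_flags = mf$flags,
    flag_map = flag_map, ecological = ecological, univariate = uni,
    fit = fit, score_table = score_table,
    predictors = predictors, scores = scores
  ), class = "score_development")
}

#' @export
print.score_development <- function(x, ...) {
  cat("Risk-score development\n")
  print(x$fit)
  print(x$score_table)
  invisible(x)
}

#' Apply frozen score artifacts to a cohort
#'
#' External-validation path: the severity table, the dichotomization means
#' and the score table all come from the development cohort; nothing is
#' re-derived here.
#'
#' @param cohort birth-cohort tibble.
#' @param indicators indicator tibble for the cohort's municipality-years.
#' @param severity_table frozen `severity_table`.
#' @param means frozen dichotomization means (named by indicator column).
#' @param score_table frozen `score_table`.
#' @param flag_map see [municipal_flags()].
#' @return the cohort with predictors, `score` and `risk_group` columns.
#' @export
apply_score <- function(cohort, indicators, severity_table, means, score_table,
                        flag_map = c(low_nurse_density = "nurse_density",
                                     low_insurance = "insurance_coverage")) {
  mf <- municipal_flags(indicators, flag_map, means = means)
  predictors <- derive_predictors(cohort, severity_table, mf$flags)
  predictors$score <- score_records(predictors, score_table)
  predictors$risk_group <- stratify(predictors$score, score_table)
  predictors
}
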