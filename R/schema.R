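#' Cohort schema configuration
#'
#' Declares how a birth-cohort CSV encodes its fields: the value used for each
#' enum level and the plausibility ranges outside which numeric values are
#' treated as missing (secondary-data cleaning: out-of-range values become
#' `NA`, never errors). The defaults match the canonical encodings written by
#' [write_cohort()].
#'
#' @param sex named character of length 2, encodings for `male` and `female`.
#' @param delivery named character, encodings for `vaginal` and `cesarean`.
#' @param yes_no named character, encodings for `yes` and `no` (used by the
#'   anomaly flag and the neonatal-death outcome).
#' @param pregnancy named character, encodings for `singleton` and `multiple`.
#' @param ranges named list of length-2 numeric vectors giving the plausible
#'   `[min, max]` for `birthweight_g`, `maternal_age_y`, `gestational_weeks`
#'   and `prenatal_visits`.
#' @return a list of class `neorisk_schema`.
#' @export
cohort_schema <- function(sex = c(male = "M", female = "F"),
                          delivery = c(vaginal = "vaginal", cesarean = "cesarean"),
                          yes_no = c(yes = "yes", no = "no"),
                          pregnancy = c(singleton = "singleton", multiple = "multiple"),
                          ranges = list(
                            birthweight_g = c(100, 9999),
                            maternal_age_y = c(8, 65),
                            gestational_weeks = c(20, 45),
                            prenatal_visits = c(0, 40)
                          )) {
  structure(
    list(sex = sex, delivery = delivery, yes_no = yes_no,
         pregnancy = pregnancy, ranges = ranges),
    class = "neorisk_schema"
  )
}

cohort_columns <- c(
  "record_id", "sex", "birthweight_g", "maternal_age_y", "gestational_weeks",
  "delivery", "prenatal_visits", "pregnancy", "birth_date",
  "municipality_code", "anomaly_flag", "anomaly_codes", "neonatal_death"
)

decode_enum <- function(x, encoding, column) {
  out <- rep(NA_character_, length(x))
  for (level in names(encoding)) out[!is.na(x) & x == encoding[[level]]] <- level
  bad <- sum(!is.na(x) & is.na(out))
  if (bad > 0) {
    nr_log(sprintf("%d unrecognized value(s) in '%s' coerced to missing", bad, column),
           level = "WARN")
  }
  out
}

coerce_range <- function(x, range, column) {
  x <- suppressWarnings(as.numeric(x))
  out_of_range <- !is.na(x) & (x < range[1] | x > range[2])
  if (any(out_of_range)) {
    nr_log(sprintf("%d out-of-range value(s) in '%s' coerced to missing",
                   sum(out_of_range), column), level = "WARN")
  }
  x[out_of_range] <- NA_real_
  as.integer(round(x))
}

#' Read a birth-cohort CSV
#'
#' Each row is one live birth. Enum encodings are taken from `schema`;
#' out-of-range numeric values are coerced to missing with a logged count; a
#' non-empty anomaly-code field forces the anomaly flag to `yes`.
#'
#' @param path path to a CSV with header columns `record_id, sex,
#'   birthweight_g, maternal_age_y, gestational_weeks, delivery,
#'   prenatal_visits, pregnancy, birth_date` (ISO-8601), `municipality_code,
#'   anomaly_flag, anomaly_codes, neonatal_death`.
#' @param schema a [cohort_schema()].
#' @return a tibble with one row per birth, typed columns, and a
#'   `coercion_counts` attribute recording how many values each cleaning rule
#'   set to missing. Row order is preserved.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  dates <- as.Date(raw$birth_date, format = "%Y-%m-%d")
  bad_date <- which(!is.na(raw$birth_date) & is.na(dates))
  if (length(bad_date) > 0) {
    stop(sprintf("unparseable birth_date at data line %d: '%s'",
                 bad_date[1], raw$birth_date[bad_date[1]]), call. = FALSE)
  }

  count_na <- function(x) sum(is.na(x))
  cohort <- tibble::tibble(
    record_id = raw$record_id,
    sex = decode_enum(raw$sex, schema$sex, "sex"),
    birthweight_g = coerce_range(raw$birthweight_g, schema$ranges$birthweight_g, "birthweight_g"),
    maternal_age_y = coerce_range(raw$maternal_age_y, schema$ranges$maternal_age_y, "maternal_age_y"),
    gestational_weeks = coerce_range(raw$gestational_weeks, schema$ranges$gestational_weeks, "gestational_weeks"),
    delivery = decode_enum(raw$delivery, schema$delivery, "delivery"),
    prenatal_visits = coerce_range(raw$prenatal_visits, schema$ranges$prenatal_visits, "prenatal_visits"),
    pregnancy = decode_enum(raw$pregnancy, schema$pregnancy, "pregnancy"),
    birth_date = dates,
    municipality_code = raw$municipality_code,
    anomaly_flag = decode_enum(raw$anomaly_flag, schema$yes_no, "anomaly_flag"),
    anomaly_codes = ifelse(is.na(raw$anomaly_codes), "", raw$anomaly_codes),
    neonatal_death = decode_enum(raw$neonatal_death, schema$yes_no, "neonatal_death") == "yes"
  )

  # invariant: a recorded code implies the anomaly flag
  has_codes <- !is.na(cohort$anomaly_codes) & nzchar(trimws(cohort$anomaly_codes))
  fix <- has_codes & (is.na(cohort$anomaly_flag) | cohort$anomaly_flag != "yes")
  if (any(fix)) {
    nr_log(sprintf("%d record(s) with anomaly codes but flag != yes; flag set to yes", sum(fix)),
           level = "WARN")
    cohort$anomaly_flag[fix] <- "yes"
  }

  attr(cohort, "coercion_counts") <- vapply(
    cohort[c("birthweight_g", "maternal_age_y", "gestational_weeks", "prenatal_visits")],
    count_na, integer(1)
  )
  cohort
}

#' Write a birth cohort to CSV in canonical encodings
#'
#' Inverse of [read_cohort()] under the default schema: a written file read
#' back reproduces every field.
#'
#' @param cohort tibble as produced by [read_cohort()] or [simulate_cohort()].
#' @param path output path.
#' @param schema a [cohort_schema()] giving the encodings to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema = cohort_schema()) {
  encode <- function(x, encoding) {
    out <- rep(NA_character_, length(x))
    for (level in names(encoding)) out[!is.na(x) & x == level] <- encoding[[level]]
    out
  }
  out <- tibble::tibble(
    record_id = cohort$record_id,
    sex = encode(cohort$sex, schema$sex),
    birthweight_g = cohort$birthweight_g,
    maternal_age_y = cohort$maternal_age_y,
    gestational_weeks = cohort$gestational_weeks,
    delivery = encode(cohort$delivery, schema$delivery),
    prenatal_visits = cohort$prenatal_visits,
    pregnancy = encode(cohort$pregnancy, schema$pregnancy),
    birth_date = format(cohort$birth_date, "%Y-%m-%d"),
    municipality_code = cohort$municipality_code,
    anomaly_flag = encode(cohort$anomaly_flag, schema$yes_no),
    anomaly_codes = cohort$anomaly_codes,
    neonatal_death = ifelse(cohort$neonatal_death, schema$yes_no[["yes"]], schema$yes_no[["no"]])
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a municipal indicator table
#'
#' One row per (municipality, year); any further column is an indicator.
#' Indicators with more than `max_missing` missing values are flagged for
#' exclusion (returned in the `excluded_indicators` attribute) but kept in the
#' table so the exclusion is auditable.
#'
#' @param path CSV with columns `municipality_code`, `year`, then indicators.
#' @param max_missing maximum tolerated missing fraction per indicator
#'   (default 0.10).
#' @return tibble keyed by `(municipality_code, year)` with an
#'   `excluded_indicators` character attribute.
#' @export
read_indicators <- function(path, max_missing = 0.10) {
  ind <- readr::read_csv(path, col_types = readr::cols(
    municipality_code = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("municipality_code", "year") %in% names(ind))) {
    stop("indicator file must have 'municipality_code' and 'year' columns", call. = FALSE)
  }
  key <- paste(ind$municipality_code, ind$year)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (municipality_code, year) key: ", dup, call. = FALSE)
  }
  ind_cols <- setdiff(names(ind), c("municipality_code", "year"))
  miss_share <- vapply(ind[ind_cols], function(x) mean(is.na(x)), numeric(1))
  excluded <- ind_cols[miss_share > max_missing]
  if (length(excluded) > 0) {
    nr_log("indicator(s) flagged for exclusion (>",
           round(100 * max_missing), "% missing): ", paste(excluded, collapse = ", "),
           level = "WARN")
  }
  attr(ind, "excluded_indicators") <- excluded
  ind
}

#' Spring/summer season flag
#'
#' Pure function of the birth date and the configured season boundaries.
#' Defaults are the Southern-Hemisphere astronomical boundaries: spring/summer
#' runs Sep 23 through Mar 20, inclusive (a window that wraps the year end).
#'
#' @param dates a `Date` vector.
#' @param bounds character `c(start, end)` in `"MM-DD"` form.
#' @return integer 0/1 vector (`NA` where the date is missing).
#' @export
is_spring_summer <- function(dates, bounds = c(start = "09-23", end = "03-20")) {
  md <- format(dates, "%m-%d")
  if (bounds[["start"]] > bounds[["end"]]) {
    flag <- md >= bounds[["start"]] | md <= bounds[["end"]]
  } else {
    flag <- md >= bounds[["start"]] & md <= bounds[["end"]]
  }
  as.integer(flag)
}

model_variables <- c(
  "male", "low_bw", "extreme_maternal_age", "severity_grade", "delivery_ga",
  "few_prenatal", "spring_summer", "multiple_preg",
  "low_nurse_density", "low_insurance"
)

#' Derive model predictors from raw certificate fields
#'
#' Adds the binary flags, the combined delivery x gestational-age category
#' (reference: vaginal term), the anomaly severity grade, the municipal
#' dichotomous flags (joined by municipality and birth year), and a
#' `complete` indicator that is `TRUE` only when every final-model variable
#' is non-missing (complete-case rule; no imputation).
#'
#' @param cohort tibble from [read_cohort()] / [simulate_cohort()].
#' @param severity_table a `severity_table` used to grade each record's
#'   anomalies (see [assign_individual_severity()]); if `NULL` and the cohort
#'   already has a `severity_grade` column that column is kept.
#' @param muni_flags optional tibble `(municipality_code, year,
#'   low_nurse_density, low_insurance)` of municipal dichotomous risk flags.
#'   Records whose (municipality, year) is absent get missing flags and are
#'   marked incomplete (logged).
#' @param season_bounds see [is_spring_summer()].
#' @return the cohort with predictor columns and `complete` appended.
#' @export
derive_predictors <- function(cohort, severity_table = NULL, muni_flags = NULL,
                              season_bounds = c(start = "09-23", end = "03-20")) {
  out <- cohort
  out$male <- as.integer(out$sex == "male")
  out$low_bw <- as.integer(out$birthweight_g < 2500)
  out$extreme_maternal_age <- as.integer(out$maternal_age_y < 17 | out$maternal_age_y >= 40)
  out$few_prenatal <- as.integer(out$prenatal_visits < 7)
  out$multiple_preg <- as.integer(out$pregnancy == "multiple")
  out$spring_summer <- is_spring_summer(out$birth_date, season_bounds)
  out$year <- as.integer(format(out$birth_date, "%Y"))

  preterm <- out$gestational_weeks < 37
  out$delivery_ga <- factor(
    ifelse(is.na(preterm) | is.na(out$delivery), NA,
           paste0(out$delivery, ifelse(preterm, "_preterm", "_term"))),
    levels = c("vaginal_term", "cesarean_term", "cesarean_preterm", "vaginal_preterm")
  )

  if (!is.null(severity_table)) {
    out$severity_grade <- assign_individual_severity(
      out$anomaly_flag, out$anomaly_codes, severity_table
    )
  } else if (!"severity_grade" %in% names(out)) {
    out$severity_grade <- NA_integer_
  }

  if (!is.null(muni_flags)) {
    out <- dplyr::left_join(
      out,
      muni_flags[, c("municipality_code", "year", "low_nurse_density", "low_insurance")],
      by = c("municipality_code", "year")
    )
    unknown <- is.na(out$low_nurse_density) | is.na(out$low_insurance)
    if (any(unknown)) {
      nr_log(sprintf("%d record(s) with unknown municipality-year marked incomplete",
                     sum(unknown)), level = "WARN")
    }
  } else if (!all(c("low_nurse_density", "low_insurance") %in% names(out))) {
    out$low_nurse_density <- NA_integer_
    out$low_insurance <- NA_integer_
  }

  out$complete <- stats::complete.cases(out[, model_variables])
  out
}
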