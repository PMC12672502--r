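#' Parse a raw anomaly-code field into ICD-10 Chapter XVII categories
#'
#' The certificate stores congenital malformations and anomalies as a single
#' free-text field of comma-separated ICD-10 codes (categories or
#' subcategories). Only the first three characters of each token are kept, so
#' subcategories collapse onto their category (`"Q00.0"` -> `"Q00"`);
#' duplicates are collapsed; tokens outside `Q00`-`Q99` after truncation are
#' dropped. Tokens longer than three characters are truncated before
#' validation (so `"Q999"` is accepted as `"Q99"`); shorter tokens are
#' invalid.
#'
#' @param raw character vector of raw code fields (may be empty strings).
#' @return a list, one character vector of distinct categories per input
#'   element, with an `n_invalid` attribute counting dropped tokens.
#' @export
parse_anomaly_codes <- function(raw) {
  raw[is.na(raw)] <- ""
  tokens <- strsplit(raw, ",", fixed = TRUE)
  n_invalid <- 0L
  out <- lapply(tokens, function(tk) {
    tk <- toupper(trimws(tk))
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0) return(character(0))
    tk3 <- substr(tk, 1, 3)
    valid <- grepl("^Q[0-9]{2}$", tk3)
    n_invalid <<- n_invalid + sum(!valid)
    unique(tk3[valid])
  })
  if (n_invalid > 0) {
    nr_log(sprintf("%d invalid anomaly code token(s) dropped", n_invalid), level = "WARN")
  }
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Select births with exactly one anomaly category
#'
#' The severity table is estimated on the subset of live births with a single
#' distinct ICD-10 category recorded, so the observed death proportion is
#' attributable to that category alone. Births with an anomaly flag but no
#' valid category (unspecified type) are excluded from this subset.
#'
#' @param categories list of per-record category vectors
#'   (from [parse_anomaly_codes()]).
#' @return logical vector: `TRUE` where the record has exactly one category.
#' @export
select_unique_cases <- function(categories) {
  lengths(categories) == 1L
}

grade_from_counts <- function(n_cases, p_death, min_cases = 10) {
  ifelse(n_cases < min_cases | p_death < 0.20, 1L,
         ifelse(p_death < 0.40, 2L, 3L))
}

#' Build the empirical severity table
#'
#' For every ICD-10 category `Q00`-`Q99`, counts single-category cases and
#' the neonatal deaths among them, and assigns an ordinal severity grade:
#' grade 1 if fewer than 10 cases or death proportion < 20%; grade 2 for a
#' proportion in \[20%, 40%); grade 3 for >= 40%. Categories with no
#' single-category case get grade 1 (the fewer-than-10-cases rule, n = 0).
#'
#' An optional clinical-coherence review can override empirical grades via
#' `overrides` (category name -> grade), mirroring the expert-review step.
#'
#' @param categories list of per-record category vectors, already restricted
#'   by the caller or not; only records selected by [select_unique_cases()]
#'   enter the counts.
#' @param deaths logical vector of neonatal-death outcomes, same length.
#' @param min_cases minimum case count for a category to be gradable above 1.
#' @param overrides optional named integer vector of grade overrides.
#' @return a tibble of class `severity_table` with columns `category`,
#'   `n_cases`, `n_deaths`, `proportion`, `grade`.
#' @export
build_severity_table <- function(categories, deaths, min_cases = 10, overrides = NULL) {
  stopifnot(length(categories) == length(deaths))
  unique_case <- select_unique_cases(categories)
  if (!any(unique_case)) {
    stop("no single-category births available to grade; supply a larger cohort",
         call. = FALSE)
  }
  cat1 <- vapply(categories[unique_case], `[`, character(1), 1)
  dth <- deaths[unique_case]
  all_cats <- sprintf("Q%02d", 0:99)
  n_cases <- as.integer(table(factor(cat1, levels = all_cats)))
  n_deaths <- as.integer(tapply(dth, factor(cat1, levels = all_cats), sum))
  n_deaths[is.na(n_deaths)] <- 0L
  proportion <- ifelse(n_cases > 0, n_deaths / n_cases, NA_real_)
  grade <- grade_from_counts(n_cases, ifelse(is.na(proportion), 0, proportion), min_cases)
  tab <- tibble::tibble(
    category = all_cats, n_cases = n_cases, n_deaths = n_deaths,
    proportion = proportion, grade = as.integer(grade)
  )
  if (!is.null(overrides)) {
    idx <- match(names(overrides), tab$category)
    if (anyNA(idx)) stop("override for unknown category", call. = FALSE)
    tab$grade[idx] <- as.integer(overrides)
  }
  class(tab) <- c("severity_table", class(tab))
  tab
}

#' Assign the per-birth ordinal severity grade
#'
#' 0 for births without any anomaly; for births with an anomaly, the maximum
#' grade over the recorded categories ("most severe category recorded");
#' grade 1 when the anomaly flag is set but no valid category was recorded
#' (unspecified type). Missing anomaly flag gives a missing grade, so the
#' record is incomplete downstream.
#'
#' @param anomaly_flag character vector `"yes"`/`"no"`/`NA`.
#' @param anomaly_codes raw code strings (parsed internally), or a list of
#'   already-parsed category vectors.
#' @param severity_table a `severity_table`, typically frozen from the
#'   development cohort (external validation must reuse it, not re-derive it).
#' @return integer vector of grades in `{0, 1, 2, 3}` (or `NA`).
#' @export
assign_individual_severity <- function(anomaly_flag, anomaly_codes, severity_table) {
  cats <- if (is.list(anomaly_codes)) anomaly_codes else parse_anomaly_codes(anomaly_codes)
  grade_of <- stats::setNames(severity_table$grade, severity_table$category)
  max_grade <- vapply(cats, function(cc) {
    if (length(cc) == 0) return(NA_integer_)
    max(grade_of[cc], na.rm = TRUE)
  }, integer(1))
  out <- ifelse(is.na(anomaly_flag), NA_integer_,
                ifelse(anomaly_flag == "no", 0L,
                       ifelse(is.na(max_grade), 1L, max_grade)))
  as.integer(out)
}

#' Write / read a severity table as CSV
#'
#' The severity table is a first-class artifact: validation cohorts reuse the
#' development-cohort table rather than re-deriving it (circularity control).
#'
#' @param table a `severity_table`.
#' @param path CSV path.
#' @return `path` (write) or the `severity_table` (read).
#' @export
write_severity_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_severity_table
#' @export
read_severity_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    category = readr::col_character(), n_cases = readr::col_integer(),
    n_deaths = readr::col_integer(), proportion = readr::col_double(),
    grade = readr::col_integer()
  ), progress = FALSE)
  class(tab) <- c("severity_table", class(tab))
  tab
}

#' @export
print.severity_table <- function(x, ...) {
  present <- x[x$n_cases > 0, ]
  cat(sprintf("Severity table: %d ICD-10 categories with cases (of 100)\n", nrow(present)))
  cat(sprintf("  grade 1: %d   grade 2: %d   grade 3: %d (categories with cases)\n",
              sum(present$grade == 1), sum(present$grade == 2), sum(present$grade == 3)))
  print(tibble::as_tibble(utils::head(present[order(-present$n_cases), ], 10)))
  invisible(x)
}
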