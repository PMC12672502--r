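#' Scaling constants mapping ln(OR) onto the 1-10 point range
#'
#' `a = 9 / (max ln(OR) - min ln(OR))` and `b = 1 - a * min ln(OR)`, so the
#' smallest coefficient maps to 1 and the largest to 10 before rounding. All
#' final conditions must be risk-increasing (ln(OR) > 0): a protective
#' condition has no defined weight in this scheme.
#'
#' @param ln_ors numeric vector of ln(OR)s (named or not).
#' @return list with full-precision `a` and `b`.
#' @export
compute_scaling <- function(ln_ors) {
  if (length(ln_ors) < 2 || max(ln_ors) == min(ln_ors)) {
    stop("need at least two distinct ln(OR) values to define the scale", call. = FALSE)
  }
  if (any(ln_ors <= 0)) {
    bad <- if (!is.null(names(ln_ors))) paste(names(ln_ors)[ln_ors <= 0], collapse = ", ")
           else paste(which(ln_ors <= 0), collapse = ", ")
    stop("non-positive ln(OR) for: ", bad,
         " (protective conditions are outside the point scheme)", call. = FALSE)
  }
  a <- (10 - 1) / (max(ln_ors) - min(ln_ors))
  b <- 1 - a * min(ln_ors)
  list(a = a, b = b)
}

default_strata <- function() {
  tibble::tibble(
    group = c("Very Low Risk", "Low to Moderate Risk", "High Risk", "Very High Risk"),
    score_min = c(0L, 5L, 10L, 16L),
    score_max = c(4L, 9L, 15L, NA_integer_)
  )
}

#' Build the integer score table from fitted odds ratios
#'
#' Converts each condition's ln(OR) into an integer point via
#' `round(a * ln(OR) + b)` (round half away from zero); reference categories
#' contribute 0. ln(OR)s are computed from the full-precision ORs, never from
#' rounded log columns.
#'
#' @param fit a `model_fit` from [fit_multilevel_logistic()], or a data frame
#'   with columns `condition` and `or`.
#' @param strata risk-group boundaries; default groups 0-4 / 5-9 / 10-15 /
#'   >=16 (Very Low / Low-to-Moderate / High / Very High).
#' @return a list of class `score_table`: `conditions` (tibble with `or`,
#'   `ln_or`, `weight`), scaling constants `a`, `b`, and `strata`.
#' @export
assign_weights <- function(fit, strata = default_strata()) {
  cond <- if (inherits(fit, "model_fit")) fit$conditions else tibble::as_tibble(fit)
  stopifnot(all(c("condition", "or") %in% names(cond)))
  ln_or <- log(cond$or)
  sc <- compute_scaling(stats::setNames(ln_or, cond$condition))
  weight <- as.integer(round_half_away(sc$a * ln_or + sc$b))
  out <- list(
    conditions = tibble::tibble(condition = cond$condition, or = cond$or,
                                ln_or = ln_or, weight = weight),
    a = sc$a, b = sc$b, reference_weight = 0L, strata = strata
  )
  class(out) <- "score_table"
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Neonatal mortality risk score table: %d conditions, a = %.4f, b = %.5f\n",
              nrow(x$conditions), x$a, x$b))
  print(x$conditions)
  invisible(x)
}

score_weight <- function(table, condition) {
  w <- table$conditions$weight[match(condition, table$conditions$condition)]
  if (anyNA(w)) stop("score table lacks condition(s): ",
                     paste(condition[is.na(w)], collapse = ", "), call. = FALSE)
  w
}

# weight of a condition, or 0 when the table does not carry it: a condition
# pruned from the final model is not part of the score and contributes nothing
score_weight_opt <- function(table, condition) {
  w <- table$conditions$weight[match(condition, table$conditions$condition)]
  ifelse(is.na(w), 0L, w)
}

#' Score birth records
#'
#' The score of a record is the sum of the points of all conditions present:
#' each binary flag contributes its weight when 1, the combined delivery x
#' gestational-age category contributes exactly one term (0 for the vaginal
#' term reference), and the anomaly severity grade contributes its grade's
#' weight (0 for no anomaly). Incomplete records get a missing score (counted
#' and logged).
#'
#' @param predictors tibble from [derive_predictors()] (needs the model
#'   variable columns and `complete`).
#' @param table a `score_table`.
#' @return integer vector of scores (`NA` for incomplete records).
#' @export
score_records <- function(predictors, table) {
  w <- function(cond) score_weight_opt(table, cond)
  delivery_w <- c(vaginal_term = 0L, cesarean_term = w("cesarean_term"),
                  cesarean_preterm = w("cesarean_preterm"),
                  vaginal_preterm = w("vaginal_preterm"))
  severity_w <- c(`0` = 0L, `1` = w("severity_1"), `2` = w("severity_2"),
                  `3` = w("severity_3"))
  score <- predictors$male * w("male") +
    predictors$low_bw * w("low_bw") +
    predictors$extreme_maternal_age * w("extreme_maternal_age") +
    predictors$few_prenatal * w("few_prenatal") +
    predictors$spring_summer * w("spring_summer") +
    predictors$multiple_preg * w("multiple_preg") +
    predictors$low_nurse_density * w("low_nurse_density") +
    predictors$low_insurance * w("low_insurance") +
    delivery_w[as.character(predictors$delivery_ga)] +
    severity_w[as.character(predictors$severity_grade)]
  score <- as.integer(score)
  if ("complete" %in% names(predictors)) score[!predictors$complete] <- NA_integer_
  n_missing <- sum(is.na(score))
  if (n_missing > 0) {
    nr_log(sprintf("%d incomplete record(s) received a missing score", n_missing))
  }
  unname(score)
}

#' Assign risk-group labels to scores
#'
#' @param score integer scores (>= 0).
#' @param table a `score_table` (its `strata` define the groups).
#' @return factor of group labels, ordered by increasing risk.
#' @export
stratify <- function(score, table) {
  strata <- table$strata
  if (any(score < 0, na.rm = TRUE)) stop("negative score", call. = FALSE)
  hi <- ifelse(is.na(strata$score_max), Inf, strata$score_max)
  ord <- order(strata$score_min)
  if (nrow(strata) > 1 && any(strata$score_min[ord][-1] <= hi[ord][-nrow(strata)])) {
    stop("overlapping risk strata", call. = FALSE)
  }
  idx <- rep(NA_integer_, length(score))
  for (g in seq_len(nrow(strata))) {
    idx[!is.na(score) & score >= strata$score_min[g] & score <= hi[g]] <- g
  }
  factor(strata$group[idx], levels = strata$group)
}

#' Serialize / read a score table as JSON
#'
#' Full-precision floats; the score table is the deployable artifact, so
#' validation cohorts load it rather than refitting.
#'
#' @param table a `score_table`.
#' @param path JSON path.
#' @return `path` (write) or the `score_table` (read).
#' @export
write_score_table <- function(table, path) {
  jsonlite::write_json(
    list(conditions = table$conditions, a = table$a, b = table$b,
         reference_weight = table$reference_weight, strata = table$strata),
    path, auto_unbox = TRUE, digits = I(17), dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    conditions = tibble::as_tibble(x$conditions),
    a = x$a, b = x$b, reference_weight = as.integer(x$reference_weight),
    strata = tibble::as_tibble(x$strata)
  )
  out$conditions$weight <- as.integer(out$conditions$weight)
  out$strata$score_min <- as.integer(out$strata$score_min)
  out$strata$score_max <- as.integer(out$strata$score_max)
  class(out) <- "score_table"
  out
}
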