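#' ROC area under the curve with DeLong confidence interval
#'
#' AUC by the rank (Mann-Whitney) statistic with tie correction; the 95% CI
#' uses the DeLong variance estimate.
#'
#' @param scores numeric scores (higher = more likely to die).
#' @param outcomes logical/0-1 outcome vector.
#' @param conf_level confidence level (default 0.95).
#' @return list `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, outcomes, conf_level = 0.95) {
  outcomes <- as.integer(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  if (length(unique(outcomes)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = outcomes, predictor = as.numeric(scores),
                 direction = "<", levels = c(0, 1), quiet = TRUE)
  ci <- pROC::ci.auc(r, conf.level = conf_level, method = "delong")
  list(auc = as.numeric(pROC::auc(r)), ci_low = ci[1], ci_high = ci[3])
}

#' Per-cutoff performance table
#'
#' One row per integer cutoff from 0 to `max(score) + 1`; at each cutoff a
#' record is classified positive when `score >= cutoff`. Sensitivity,
#' specificity, PPV, NPV, the correctly-classified percentage and the Youden
#' index (sensitivity + specificity - 100) are reported as percentages to 2
#' decimal places (half away from zero). NPV is missing when no record is
#' classified negative.
#'
#' @param scores integer scores.
#' @param outcomes logical/0-1 outcomes.
#' @return tibble of class `cutoff_table`.
#' @export
cutoff_table <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- as.integer(scores[keep]); outcomes <- outcomes[keep]
  pos <- sum(outcomes == 1)
  neg <- sum(outcomes == 0)
  rows <- lapply(0:(max(scores) + 1L), function(cut) {
    pred <- scores >= cut
    tp <- sum(pred & outcomes == 1); fp <- sum(pred & outcomes == 0)
    fn <- pos - tp; tn <- neg - fp
    sens <- 100 * tp / pos
    spec <- 100 * tn / neg
    ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
    tibble::tibble(
      cutoff = cut,
      sensitivity = round_half_away(sens, 2),
      specificity = round_half_away(spec, 2),
      ppv = round_half_away(ppv, 2),
      npv = round_half_away(npv, 2),
      correctly_classified = round_half_away(100 * (tp + tn) / (pos + neg), 2),
      youden = round_half_away(sens + spec - 100, 2)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cutoff_table", class(out))
  out
}

#' Youden-optimal cutoff
#'
#' The cutoff maximizing the Youden index; ties resolve to the lowest cutoff.
#'
#' @param rows a [cutoff_table()] (or any data frame with `cutoff`, `youden`).
#' @return integer cutoff.
#' @export
optimal_cutoff <- function(rows) {
  stopifnot(nrow(rows) > 0)
  rows$cutoff[which.max(rows$youden)]
}

#' Risk-group summary
#'
#' Births, share of births, deaths, and the observed death proportion per
#' risk group, plus the PPV range text read from the cutoff table (PPV at the
#' group's lower cutoff up to the PPV at the next group's lower cutoff).
#'
#' @param scores integer scores.
#' @param outcomes logical/0-1 outcomes.
#' @param table a `score_table` (its `strata` define the groups).
#' @return tibble `group, score_min, score_max, births, pct_births, deaths,
#'   death_pct, ppv_range`.
#' @export
risk_group_summary <- function(scores, outcomes, table) {
  outcomes <- as.integer(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  grp <- stratify(scores, table)
  ct <- cutoff_table(scores, outcomes)
  strata <- table$strata
  n_total <- length(scores)
  rows <- lapply(seq_len(nrow(strata)), function(g) {
    in_g <- grp == strata$group[g]
    births <- sum(in_g)
    deaths <- sum(outcomes[in_g] == 1)
    ppv_lo <- ct$ppv[match(strata$score_min[g], ct$cutoff)]
    ppv_hi <- if (g < nrow(strata)) ct$ppv[match(strata$score_min[g + 1], ct$cutoff)]
              else NA_real_
    tibble::tibble(
      group = strata$group[g],
      score_min = strata$score_min[g], score_max = strata$score_max[g],
      births = births,
      pct_births = round_half_away(100 * births / n_total, 2),
      deaths = deaths,
      death_pct = if (births > 0) round_half_away(100 * deaths / births, 2) else NA_real_,
      ppv_range = if (is.na(ppv_hi)) sprintf(">=%.1f", ppv_lo)
                  else sprintf("%.1f to %.1f", ppv_lo, ppv_hi)
    )
  })
  dplyr::bind_rows(rows)
}

#' Grouped calibration points
#'
#' (mean score, observed death rate) per risk group, ordered by group.
#'
#' @inheritParams risk_group_summary
#' @return tibble `group, mean_score, death_rate` (rate as a proportion).
#' @export
calibration_by_group <- function(scores, outcomes, table) {
  outcomes <- as.integer(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  grp <- stratify(scores, table)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp, score = scores, y = outcomes), .data$group),
    mean_score = mean(.data$score), death_rate = mean(.data$y), .groups = "drop"
  )
}

#' McFadden pseudo-R-squared of the score
#'
#' `1 - l(score model) / l(null)` from a univariate logistic regression of
#' the outcome on the ordinal score. Invariant to affine rescaling of the
#' score.
#'
#' @param scores numeric scores.
#' @param outcomes logical/0-1 outcomes.
#' @return numeric in [0, 1).
#' @export
pseudo_r2 <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  if (length(unique(outcomes)) < 2) stop("both outcome classes must be present",
                                         call. = FALSE)
  fit <- suppressWarnings(stats::glm(outcomes ~ scores, family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    warning("possible separation: pseudo-R2 approaches 1", call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(outcomes ~ 1, family = stats::binomial())))
  1 - ll / ll0
}

#' Full validation report
#'
#' Discrimination (AUC with DeLong CI, per-cutoff table, Youden-optimal
#' cutoff), risk-group summary, grouped calibration, and the score's McFadden
#' pseudo-R-squared.
#'
#' @inheritParams risk_group_summary
#' @return list of class `validation_report`.
#' @export
validate_score <- function(scores, outcomes, table) {
  auc <- roc_auc(scores, outcomes)
  ct <- cutoff_table(scores, outcomes)
  structure(list(
    auc = auc,
    cutoffs = ct,
    optimal_cutoff = optimal_cutoff(ct),
    risk_groups = risk_group_summary(scores, outcomes, table),
    calibration = calibration_by_group(scores, outcomes, table),
    pseudo_r2 = pseudo_r2(scores, outcomes),
    n = sum(!is.na(scores) & !is.na(outcomes))
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (n = %d)\n", x$n))
  cat(sprintf("  AUC %.4f (95%% CI %.4f-%.4f); optimal cutoff >= %d; pseudo-R2 %.2f%%\n",
              x$auc$auc, x$auc$ci_low, x$auc$ci_high, x$optimal_cutoff,
              100 * x$pseudo_r2))
  print(x$risk_groups)
  invisible(x)
}

#' Write a validation report
#'
#' Writes `report.json`, `cutoff_table.csv` and `risk_groups.csv` to `dir`.
#'
#' @param report a `validation_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  readr::write_csv(report$cutoffs, file.path(dir, "cutoff_table.csv"), progress = FALSE)
  readr::write_csv(report$risk_groups, file.path(dir, "risk_groups.csv"), progress = FALSE)
  invisible(dir)
}

#' ROC and grouped calibration plots
#'
#' @param scores,outcomes,table as in [validate_score()].
#' @return a ggplot object.
#' @export
plot_roc <- function(scores, outcomes) {
  ct <- cutoff_table(scores, outcomes)
  df <- tibble::tibble(fpr = (100 - ct$specificity) / 100, tpr = ct$sensitivity / 100)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
plot_calibration <- function(scores, outcomes, table) {
  cal <- calibration_by_group(scores, outcomes, table)
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$mean_score, y = 100 * .data$death_rate)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean score in group", y = "Observed death rate (%)") +
    ggplot2::theme_minimal()
}
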