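test_that("AUC is 1 for perfect separation and matches pair counting in general", {
  scores <- c(5, 6, 7, 1, 2, 3)
  outcomes <- c(1, 1, 1, 0, 0, 0)
  expect_equal(suppressWarnings(roc_auc(scores, outcomes))$auc, 1.0)

  set.seed(81)
  for (rep in 1:5) {
    n <- sample(30:500, 1)
    s <- sample(0:20, n, replace = TRUE)
    y <- stats::rbinom(n, 1, stats::plogis(-2 + 0.2 * s))
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, pair_count_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2, 3), c(1, 1, 1)), "both outcome classes")
})

test_that("an uninformative score gives AUC near one half", {
  set.seed(82)
  s <- sample(0:10, 20000, replace = TRUE)
  y <- stats::rbinom(20000, 1, 0.05)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.03)
})

test_that("cutoff rows reproduce hand-tabulated 2x2 arithmetic", {
  # 6 records: scores 0..5, deaths at 2, 4, 5
  scores <- 0:5
  outcomes <- c(0, 0, 1, 0, 1, 1)
  ct <- cutoff_table(scores, outcomes)
  expect_equal(nrow(ct), 7)  # cutoffs 0..6
  # cutoff 0: everyone positive
  r0 <- ct[ct$cutoff == 0, ]
  expect_equal(r0$sensitivity, 100)
  expect_equal(r0$specificity, 0)
  expect_equal(r0$ppv, 50)    # overall death proportion
  expect_true(is.na(r0$npv))  # no negatives predicted
  # cutoff 3: TP = 2 (scores 4,5), FN = 1 (score 2), TN = 2 (0,1), FP = 1 (3)
  r3 <- ct[ct$cutoff == 3, ]
  expect_equal(r3$sensitivity, round(100 * 2 / 3, 2))
  expect_equal(r3$specificity, round(100 * 2 / 3, 2))
  expect_equal(r3$ppv, round(100 * 2 / 3, 2))
  expect_equal(r3$npv, round(100 * 2 / 3, 2))
  expect_equal(r3$correctly_classified, round(100 * 4 / 6, 2))
  # cutoff 6: nobody positive
  r6 <- ct[ct$cutoff == 6, ]
  expect_equal(r6$sensitivity, 0)
  expect_equal(r6$specificity, 100)
  expect_true(is.na(r6$ppv))
})

test_that("cutoff-table invariants hold on a simulated cohort", {
  set.seed(83)
  s <- sample(0:25, 5000, replace = TRUE)
  y <- stats::rbinom(5000, 1, stats::plogis(-5 + 0.25 * s))
  ct <- cutoff_table(s, y)
  expect_true(all(diff(ct$sensitivity) <= 0))
  expect_true(all(diff(ct$specificity) >= 0))
  expect_equal(ct$youden, ct$sensitivity + ct$specificity - 100, tolerance = 0.011)
  ok <- !is.na(ct$ppv) & !is.na(ct$npv)
  expect_true(all(ct$correctly_classified >= 0 & ct$correctly_classified <= 100))
})

test_that("the Youden-optimal cutoff is the argmax, lowest on ties", {
  expect_equal(optimal_cutoff(tibble::tibble(cutoff = 4L, youden = 10)), 4L)
  expect_equal(optimal_cutoff(tibble::tibble(cutoff = c(2L, 3L, 4L),
                                             youden = c(50, 70, 70))), 3L)
})

test_that("risk groups conserve births and deaths and report shares", {
  tab <- reference_score_table()
  set.seed(84)
  s <- sample(0:26, 8000, replace = TRUE, prob = stats::dpois(0:26, 5))
  y <- stats::rbinom(8000, 1, stats::plogis(-6 + 0.3 * s))
  rg <- risk_group_summary(s, y, tab)
  expect_equal(sum(rg$births), 8000L)
  expect_equal(sum(rg$deaths), sum(y))
  expect_lt(abs(sum(rg$pct_births) - 100), 0.011)
  expect_equal(rg$death_pct, round(100 * rg$deaths / rg$births, 2), tolerance = 0.011)
})

test_that("an empty group reports zero counts and a missing proportion", {
  tab <- reference_score_table()
  s <- c(0L, 2L, 3L, 5L, 7L)  # nobody at >= 10
  y <- c(0L, 0L, 1L, 0L, 1L)
  rg <- risk_group_summary(s, y, tab)
  expect_equal(rg$births[rg$group == "High Risk"], 0L)
  expect_true(is.na(rg$death_pct[rg$group == "High Risk"]))
})

test_that("calibration points are per-group means and observed rates", {
  tab <- reference_score_table()
  s <- c(1L, 3L, 6L, 8L, 12L, 14L)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  cal <- calibration_by_group(s, y, tab)
  expect_equal(cal$mean_score[cal$group == "Very Low Risk"], 2)
  expect_equal(cal$death_rate[cal$group == "Low to Moderate Risk"], 0.5)
  expect_equal(cal$death_rate[cal$group == "High Risk"], 1)
  # a single populated group reproduces the overall rate
  cal1 <- calibration_by_group(rep(2L, 10), rep(c(1L, 0L), 5), tab)
  expect_equal(nrow(cal1), 1)
  expect_equal(cal1$death_rate, 0.5)
})

test_that("rates increase across the four groups on a model-generated cohort", {
  tab <- reference_score_table()
  sim <- simulate_cohort(sim_config(n_births = 100000, n_municipalities = 100),
                         seed = 85)
  st <- build_severity_table(parse_anomaly_codes(sim$cohort$anomaly_codes),
                             sim$cohort$neonatal_death)
  mf <- municipal_flags(sim$indicators)
  pr <- suppressMessages(derive_predictors(sim$cohort, st, mf$flags))
  s <- suppressMessages(score_records(pr, tab))
  keep <- !is.na(s)
  cal <- calibration_by_group(s[keep], pr$neonatal_death[keep], tab)
  expect_equal(nrow(cal), 4)
  expect_true(all(diff(cal$death_rate) > 0))
  expect_true(all(diff(cal$mean_score) > 0))
})

test_that("pseudo-R2 is 0 for a constant score and matches a closed form", {
  y4 <- c(1, 1, 0, 0)
  expect_equal(pseudo_r2(c(2, 2, 2, 2), y4), 0, tolerance = 1e-9)
  # hand-computed 4-record likelihood ratio: scores (1,1,0,0), outcomes (1,1,0,0)
  # separate perfectly -> ll(model) -> 0, ll(null) = 4*log(1/2)
  expect_warning(r2 <- pseudo_r2(c(1, 1, 0, 0), y4), "separation")
  expect_gt(r2, 0.99)
  # a partially informative hand case with exact Bernoulli likelihoods
  s <- c(0, 0, 1, 1, 2, 2)
  y <- c(0, 1, 0, 0, 1, 1)
  fit <- stats::glm(y ~ s, family = stats::binomial())
  ll <- sum(stats::dbinom(y, 1, stats::fitted(fit), log = TRUE))
  ll0 <- sum(stats::dbinom(y, 1, mean(y), log = TRUE))
  expect_equal(pseudo_r2(s, y), 1 - ll / ll0, tolerance = 1e-8)
  # invariance under affine rescaling of the score
  expect_equal(pseudo_r2(10 + 3 * s, y), pseudo_r2(s, y), tolerance = 1e-8)
})

test_that("validation reports bundle the metrics and write to disk", {
  tab <- reference_score_table()
  set.seed(86)
  s <- sample(0:20, 4000, replace = TRUE)
  y <- stats::rbinom(4000, 1, stats::plogis(-5 + 0.3 * s))
  rep <- validate_score(s, y, tab)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$optimal_cutoff, optimal_cutoff(rep$cutoffs))
  dir <- tempfile()
  write_validation_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("report.json", "cutoff_table.csv",
                                               "risk_groups.csv")))))
  p1 <- plot_roc(s, y)
  p2 <- plot_calibration(s, y, tab)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
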