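test_that("zero variance gives exactly zero intercepts; config is validated", {
  cfg <- sim_config(n_births = 100, n_municipalities = 10, random_intercept_var = 0)
  set.seed(1)
  m <- generate_municipalities(cfg)
  expect_true(all(m$latent$u == 0))
  expect_error(sim_config(random_intercept_var = -0.1), "random_intercept_var")
  expect_error(sim_config(n_municipalities = 1), "n_municipalities")
  expect_error(sim_config(covariate_prevalences = list(male = 1.2)), "male")
})

test_that("intercept variance is near its configured value at 500 municipalities", {
  cfg <- sim_config(n_births = 100, n_municipalities = 500,
                    random_intercept_var = 0.0560)
  set.seed(101)
  m <- generate_municipalities(cfg)
  v <- stats::var(m$latent$u)
  expect_gte(v, 0.04)
  expect_lte(v, 0.075)
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_births = 2000, n_municipalities = 12)
  s1 <- simulate_cohort(cfg, seed = 77)
  s2 <- simulate_cohort(cfg, seed = 77)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$indicators, s2$indicators)
  expect_identical(s1$truth$baseline_log_odds, s2$truth$baseline_log_odds)
})

test_that("covariate marginals match their configured prevalences", {
  sim <- simulate_cohort(sim_config(n_births = 10000, n_municipalities = 30), seed = 55)
  # male share within +-1.5 percentage points of 48.8%
  expect_lt(abs(mean(sim$cohort$sex == "male", na.rm = TRUE) - 0.488), 0.015)
  expect_lt(abs(mean(sim$cohort$gestational_weeks < 37, na.rm = TRUE) - 0.105), 0.015)
  expect_lt(abs(mean(sim$cohort$anomaly_flag == "yes", na.rm = TRUE) - 0.010), 0.005)
  # the delivery x gestational-age joint structure is respected
  lat <- sim$truth$latent
  expect_lt(abs(mean(lat$cesarean[lat$preterm == 1]) - 0.065 / 0.105), 0.05)
})

test_that("the dependence cross-terms induce positive association", {
  sim <- simulate_cohort(sim_config(n_births = 50000, n_municipalities = 10), seed = 56)
  lat <- sim$truth$latent
  tab <- table(lat$low_bw, lat$preterm)
  or_bw_pt <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or_bw_pt, 4)
  expect_lt(or_bw_pt, 40)
})

test_that("zero missingness gives complete records; zero anomalies give none", {
  cfg <- sim_config(n_births = 3000, n_municipalities = 10,
                    missingness_rates = c(birthweight_g = 0))
  sim <- simulate_cohort(cfg, seed = 57)
  st <- build_severity_table(parse_anomaly_codes(sim$cohort$anomaly_codes),
                             sim$cohort$neonatal_death)
  mf <- municipal_flags(sim$indicators)
  pr <- derive_predictors(sim$cohort, st, mf$flags)
  expect_true(all(pr$complete))

  prev <- sim_config(n_births = 3000, n_municipalities = 10)$covariate_prevalences
  prev$anomaly <- 0
  sim0 <- simulate_cohort(sim_config(n_births = 3000, n_municipalities = 10,
                                     covariate_prevalences = prev), seed = 58)
  expect_false(any(sim0$cohort$anomaly_flag == "yes", na.rm = TRUE))
})

test_that("a symmetric null model yields a death rate near 50%", {
  lo <- default_condition_log_odds()
  lo[] <- 0
  cfg <- sim_config(n_births = 20000, n_municipalities = 5,
                    random_intercept_var = 0,
                    baseline_log_odds = 0, condition_log_odds = lo)
  sim <- simulate_cohort(cfg, seed = 59)
  expect_lt(abs(mean(sim$cohort$neonatal_death) - 0.5), 0.02)
})

test_that("the default generating process lands in the plausible mortality band", {
  sim <- simulate_cohort(sim_config(n_births = 50000, n_municipalities = 100), seed = 60)
  rate <- 1000 * mean(sim$cohort$neonatal_death)
  expect_gte(rate, 5)
  expect_lte(rate, 11)
})

test_that("a grade-3 anomaly shifts the linear predictor by exactly its ln(OR)", {
  lo <- default_condition_log_odds()
  base <- tibble::tibble(
    male = 1L, low_bw = 0L, extreme_maternal_age = 0L, few_prenatal = 1L,
    multiple_preg = 0L, spring_summer = 0L, preterm = 0L, cesarean = 1L,
    severity_grade = c(0L, 3L), anomaly_lethality = NA_real_,
    low_nurse_density = 1L, low_insurance = 0L, muni_idx = 1L
  )
  eta <- neorisk:::build_linear_predictor(base, u = 0, lo = lo)
  # odds ratio between the two fitted probabilities, at any baseline
  b0 <- -5
  odds <- stats::plogis(b0 + eta) / (1 - stats::plogis(b0 + eta))
  expect_equal(odds[2] / odds[1], exp(lo[["severity_3"]]), tolerance = 1e-12)
  expect_equal(unname(odds[2] / odds[1]), 284.78, tolerance = 1e-10)
})

test_that("raising a condition ln(OR) weakly increases deaths under common random numbers", {
  cfg_lo <- sim_config(n_births = 20000, n_municipalities = 10)
  lo <- cfg_lo$condition_log_odds
  lo[["low_bw"]] <- lo[["low_bw"]] + 1
  cfg_hi <- sim_config(n_births = 20000, n_municipalities = 10,
                       baseline_log_odds = simulate_cohort(cfg_lo, seed = 61)$truth$baseline_log_odds,
                       condition_log_odds = lo)
  cfg_lo <- sim_config(n_births = 20000, n_municipalities = 10,
                       baseline_log_odds = simulate_cohort(cfg_lo, seed = 61)$truth$baseline_log_odds)
  s_lo <- simulate_cohort(cfg_lo, seed = 61)
  s_hi <- simulate_cohort(cfg_hi, seed = 61)
  # same seed, same covariate draws, higher probabilities: deaths are a superset
  expect_true(all(s_hi$cohort$neonatal_death >= s_lo$cohort$neonatal_death))
  expect_gte(sum(s_hi$cohort$neonatal_death), sum(s_lo$cohort$neonatal_death))
})

test_that("the empirical log-odds-ratio converges to the configured one", {
  lo <- default_condition_log_odds()
  lo[] <- 0
  lo[["low_bw"]] <- 1.2
  cfg <- sim_config(n_births = 150000, n_municipalities = 5,
                    random_intercept_var = 0, condition_log_odds = lo,
                    target_death_rate = 0.05,
                    missingness_rates = c(birthweight_g = 0))
  sim <- simulate_cohort(cfg, seed = 62)
  lat <- sim$truth$latent
  tab <- table(lat$low_bw, sim$cohort$neonatal_death)
  ln_or_hat <- log((tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1]))
  mc_se <- sqrt(sum(1 / tab))
  expect_lt(abs(ln_or_hat - 1.2), 3 * mc_se)
})

test_that("simulations write cohort, indicators and truth to disk", {
  sim <- simulate_cohort(sim_config(n_births = 300, n_municipalities = 5), seed = 63)
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("cohort.csv", "indicators.csv",
                                               "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$random_intercept_var, 0.0560)
  expect_equal(truth$baseline_log_odds, sim$truth$baseline_log_odds)
  back <- suppressMessages(read_cohort(file.path(dir, "cohort.csv")))
  expect_equal(nrow(back), 300)
})
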