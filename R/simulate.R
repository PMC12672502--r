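#' Default anomaly category specification
#'
#' Relative prevalence (among births with a specified anomaly) and per-category
#' lethality for 21 ICD-10 Chapter XVII categories. Lethalities span 1%-72% so
#' all three severity grades are exercised; the category labels are plausible
#' but the joint distribution is a synthetic assumption, not an estimate.
#'
#' @return tibble with columns `category`, `weight`, `lethality`.
#' @export
default_anomaly_spec <- function() {
  tibble::tibble(
    category = c("Q21", "Q69", "Q66", "Q35", "Q36", "Q37", "Q53", "Q54", "Q17",
                 "Q18", "Q25", "Q90", "Q02", "Q05",
                 "Q01", "Q39", "Q79", "Q91",
                 "Q00", "Q23", "Q77"),
    weight = c(0.18, 0.10, 0.08, 0.06, 0.05, 0.03, 0.06, 0.05, 0.04,
               0.03, 0.05, 0.06, 0.04, 0.03,
               0.03, 0.02, 0.025, 0.015,
               0.02, 0.015, 0.015),
    lethality = c(0.05, 0.01, 0.01, 0.03, 0.04, 0.08, 0.02, 0.02, 0.01,
                  0.02, 0.10, 0.06, 0.03, 0.12,
                  0.28, 0.22, 0.30, 0.35,
                  0.72, 0.45, 0.50)
  )
}

#' Default municipal indicator specification
#'
#' Three indicators mirroring the ones retained by the ecological screen:
#' public-system nurse density and ultrasound-device density per 100,000
#' inhabitants, and private health insurance coverage (%). `effect` is a
#' direct per-SD shift of the municipality baseline log-odds (default 0: the
#' municipal influence flows through the dichotomized flags in the outcome
#' model plus the random intercept).
#'
#' @return tibble with columns `indicator`, `mean`, `sd`, `effect`.
#' @export
default_indicator_spec <- function() {
  tibble::tibble(
    indicator = c("nurse_density", "ultrasound_density", "insurance_coverage"),
    mean = c(150, 8, 25),
    sd = c(60, 4, 12),
    effect = c(0, 0, 0)
  )
}

#' Default condition log-odds-ratios of the outcome model
#'
#' The adjusted odds ratios of the final multilevel model for the Sao Paulo
#' 2009-2018 cohort (see [ref_model_or()]), on the log scale, used as the
#' generating truth of the simulator.
#'
#' @return named numeric vector of ln(OR)s.
#' @export
default_condition_log_odds <- function() {
  or <- ref_model_or()
  stats::setNames(log(or$or), or$condition)
}

#' Simulation configuration for a synthetic birth cohort
#'
#' Defines the generating process: covariate prevalences (defaults are the
#' published Sao Paulo 2009-2018 marginals), a logistic outcome model with
#' configurable condition ln(OR)s, municipality random intercepts with
#' variance `random_intercept_var` (default 0.0560), unequal municipality
#' sizes, anomaly codes with per-category lethality, and field-level
#' missingness (defaults are the published per-variable missingness rates).
#'
#' `baseline_log_odds = NULL` (the default) calibrates the intercept at
#' generation time, by root-finding on the realized linear predictors, so the
#' expected marginal death rate equals `target_death_rate` (default 7.69 per
#' 1,000 live births).
#'
#' `anomaly_effect` chooses how anomalies act on the outcome: `"grade"`
#' (default) enters the severity-grade ln(OR)s in the linear predictor;
#' `"lethality"` makes the death probability of births with a specified
#' anomaly equal the lethality of their most lethal category, so realized
#' per-category death proportions concentrate on the configured lethalities
#' (used when studying the empirical grading itself).
#'
#' @param n_births number of live births.
#' @param n_municipalities number of municipalities (>= 2).
#' @param years integer vector of calendar years covered.
#' @param random_intercept_var variance of the municipality random intercept
#'   on the log-odds scale (>= 0).
#' @param baseline_log_odds fixed intercept, or `NULL` to calibrate.
#' @param target_death_rate marginal neonatal death rate used for calibration.
#' @param condition_log_odds named ln(OR) vector; names as in
#'   [default_condition_log_odds()].
#' @param covariate_prevalences named list of marginal prevalences; see
#'   default.
#' @param dependence_log_odds log-odds cross-terms inducing positive
#'   association among multiple pregnancy, preterm birth and low birth weight
#'   (marginals are preserved by re-calibrating the intercepts).
#' @param anomaly_spec tibble as [default_anomaly_spec()].
#' @param anomaly_effect `"grade"` or `"lethality"`.
#' @param unspecified_anomaly_rate share of anomalies with no recorded
#'   category.
#' @param multi_category_probs distribution of the number of distinct
#'   categories per specified-anomaly birth.
#' @param indicator_spec tibble as [default_indicator_spec()].
#' @param missingness_rates named per-field missingness probabilities.
#' @param size_skew gamma shape of the Dirichlet-style municipality size
#'   weights (smaller = more skewed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_births = 200000,
                       n_municipalities = 200,
                       years = 2015L,
                       random_intercept_var = 0.0560,
                       baseline_log_odds = NULL,
                       target_death_rate = 7.69 / 1000,
                       condition_log_odds = default_condition_log_odds(),
                       covariate_prevalences = list(
                         male = 0.488, low_bw = 0.092,
                         extreme_maternal_age = 0.067, few_prenatal = 0.220,
                         multiple_preg = 0.024, preterm = 0.105,
                         cesarean_given_term = 0.529 / 0.895,
                         cesarean_given_preterm = 0.065 / 0.105,
                         spring_summer = 0.478, anomaly = 0.010
                       ),
                       dependence_log_odds = c(
                         preterm_multiple = log(8),
                         lowbw_preterm = log(15),
                         lowbw_multiple = log(4)
                       ),
                       anomaly_spec = default_anomaly_spec(),
                       anomaly_effect = c("grade", "lethality"),
                       unspecified_anomaly_rate = 0.087,
                       multi_category_probs = c(0.84, 0.13, 0.03),
                       indicator_spec = default_indicator_spec(),
                       missingness_rates = c(
                         birthweight_g = 0.009, maternal_age_y = 0.0002,
                         gestational_weeks = 0.036, prenatal_visits = 0.037,
                         delivery = 0.004, anomaly_flag = 0.027
                       ),
                       size_skew = 0.6) {
  anomaly_effect <- match.arg(anomaly_effect)
  if (n_municipalities < 2) stop("n_municipalities must be >= 2", call. = FALSE)
  if (!is.finite(random_intercept_var) || random_intercept_var < 0) {
    stop("random_intercept_var must be >= 0", call. = FALSE)
  }
  for (nm in names(covariate_prevalences)) assert_prob(covariate_prevalences[[nm]], nm)
  assert_prob(unlist(missingness_rates), "missingness_rates")
  assert_prob(anomaly_spec$lethality, "anomaly_spec$lethality")
  assert_prob(target_death_rate, "target_death_rate")
  cfg <- list(
    n_births = n_births, n_municipalities = n_municipalities, years = as.integer(years),
    random_intercept_var = random_intercept_var,
    baseline_log_odds = baseline_log_odds, target_death_rate = target_death_rate,
    condition_log_odds = condition_log_odds,
    covariate_prevalences = covariate_prevalences,
    dependence_log_odds = dependence_log_odds,
    anomaly_spec = anomaly_spec, anomaly_effect = anomaly_effect,
    unspecified_anomaly_rate = unspecified_anomaly_rate,
    multi_category_probs = multi_category_probs / sum(multi_category_probs),
    indicator_spec = indicator_spec,
    missingness_rates = missingness_rates, size_skew = size_skew
  )
  class(cfg) <- "sim_config"
  cfg
}

true_grade_from_lethality <- function(lethality) {
  ifelse(lethality < 0.20, 1L, ifelse(lethality < 0.40, 2L, 3L))
}

#' Generate municipalities with indicators and latent intercepts
#'
#' Each municipality gets a latent intercept `u ~ Normal(0, sigma^2)`, a
#' Dirichlet-style population share (unequal sizes), and per-year indicator
#' values drawn from the configured means/SDs (truncated at 0).
#'
#' @param cfg a [sim_config()].
#' @return list with `indicators` (tibble `municipality_code, year,
#'   <indicators>`) and `latent` (tibble `municipality_code, u, share`).
#' @export
generate_municipalities <- function(cfg) {
  m <- cfg$n_municipalities
  code <- sprintf("35%05d", seq_len(m))
  u <- if (cfg$random_intercept_var == 0) rep(0, m) else
    stats::rnorm(m, 0, sqrt(cfg$random_intercept_var))
  w <- stats::rgamma(m, shape = cfg$size_skew, rate = 1)
  w <- pmax(w, 1e-9)
  share <- w / sum(w)
  grid <- expand.grid(municipality_code = code, year = cfg$years,
                      stringsAsFactors = FALSE)
  ind <- tibble::as_tibble(grid)
  for (i in seq_len(nrow(cfg$indicator_spec))) {
    s <- cfg$indicator_spec[i, ]
    ind[[s$indicator]] <- pmax(stats::rnorm(nrow(ind), s$mean, s$sd), 0)
  }
  list(indicators = ind,
       latent = tibble::tibble(municipality_code = code, u = u, share = share))
}

# Solve the intercept of a conditional Bernoulli model so its marginal matches
# a target, given cell probabilities and cell log-odds shifts.
solve_marginal_intercept <- function(target, cell_prob, cell_shift) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) sum(cell_prob * stats::plogis(a + cell_shift)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}

sample_anomaly_codes <- function(n_yes, cfg) {
  spec <- cfg$anomaly_spec
  unspecified <- stats::runif(n_yes) < cfg$unspecified_anomaly_rate
  k <- sample.int(length(cfg$multi_category_probs), n_yes, replace = TRUE,
                  prob = cfg$multi_category_probs)
  k[unspecified] <- 0L
  codes <- character(n_yes)
  max_grade <- integer(n_yes)
  grade_of <- true_grade_from_lethality(spec$lethality)
  lethality_of <- stats::setNames(spec$lethality, spec$category)
  max_lethality <- numeric(n_yes)
  for (i in seq_len(n_yes)) {
    if (k[i] == 0L) {
      codes[i] <- ""
      max_grade[i] <- 1L  # unspecified type is graded 1 downstream
      max_lethality[i] <- NA_real_
      next
    }
    cats <- sample(spec$category, k[i], prob = spec$weight)
    # render some tokens with a subcategory digit, as certificates do
    sub <- stats::runif(k[i]) < 0.5
    tok <- ifelse(sub, paste0(cats, ".", sample(0:9, k[i], replace = TRUE)), cats)
    codes[i] <- paste(tok, collapse = ", ")
    max_grade[i] <- max(grade_of[match(cats, spec$category)])
    max_lethality[i] <- max(lethality_of[cats])
  }
  list(codes = codes, max_grade = max_grade, max_lethality = max_lethality)
}

#' Generate birth records (without outcome)
#'
#' Draws covariates to match the configured marginals, with positive
#' dependence among multiple pregnancy, preterm birth and low birth weight
#' induced by log-odds cross-terms whose intercepts are re-calibrated so the
#' marginals are preserved. Anomaly categories are drawn from
#' `cfg$anomaly_spec` and written as comma-separated ICD-10 strings (some with
#' subcategory digits). Configured missingness is injected into the raw
#' fields; the pre-missingness truth is kept in the `latent` attribute for
#' outcome simulation and recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param municipalities output of [generate_municipalities()].
#' @return tibble in the cohort schema (without `neonatal_death`), with a
#'   `latent` attribute holding the true flag matrix.
#' @export
generate_births <- function(cfg, municipalities) {
  n <- cfg$n_births
  p <- cfg$covariate_prevalences
  dep <- cfg$dependence_log_odds

  muni_idx <- sample.int(nrow(municipalities$latent), n, replace = TRUE,
                         prob = municipalities$latent$share)
  municipality_code <- municipalities$latent$municipality_code[muni_idx]
  year <- cfg$years[sample.int(length(cfg$years), n, replace = TRUE)]

  multiple <- as.integer(stats::runif(n) < p$multiple_preg)

  a_pt <- solve_marginal_intercept(
    p$preterm,
    cell_prob = c(1 - p$multiple_preg, p$multiple_preg),
    cell_shift = c(0, dep[["preterm_multiple"]])
  )
  preterm <- as.integer(stats::runif(n) <
                          stats::plogis(a_pt + dep[["preterm_multiple"]] * multiple))

  # joint cells of (multiple, preterm) implied by the two models above
  p_pt_m <- stats::plogis(a_pt + dep[["preterm_multiple"]])
  p_pt_s <- stats::plogis(a_pt)
  cell_prob <- c((1 - p$multiple_preg) * (1 - p_pt_s), (1 - p$multiple_preg) * p_pt_s,
                 p$multiple_preg * (1 - p_pt_m), p$multiple_preg * p_pt_m)
  cell_shift <- c(0, dep[["lowbw_preterm"]], dep[["lowbw_multiple"]],
                  dep[["lowbw_preterm"]] + dep[["lowbw_multiple"]])
  a_bw <- solve_marginal_intercept(p$low_bw, cell_prob, cell_shift)
  low_bw <- as.integer(stats::runif(n) < stats::plogis(
    a_bw + dep[["lowbw_preterm"]] * preterm + dep[["lowbw_multiple"]] * multiple))

  male <- as.integer(stats::runif(n) < p$male)
  extreme_age <- as.integer(stats::runif(n) < p$extreme_maternal_age)
  few_prenatal <- as.integer(stats::runif(n) < p$few_prenatal)
  spring <- as.integer(stats::runif(n) < p$spring_summer)
  p_ces <- ifelse(preterm == 1, p$cesarean_given_preterm, p$cesarean_given_term)
  cesarean <- as.integer(stats::runif(n) < p_ces)

  maternal_age_y <- integer(n)
  n_ext <- sum(extreme_age)
  maternal_age_y[extreme_age == 1] <- ifelse(
    stats::runif(n_ext) < 0.4,
    sample(13:16, n_ext, replace = TRUE),
    sample(40:48, n_ext, replace = TRUE)
  )
  maternal_age_y[extreme_age == 0] <- sample(17:39, n - n_ext, replace = TRUE)

  gestational_weeks <- integer(n)
  gestational_weeks[preterm == 1] <- sample(24:36, sum(preterm), replace = TRUE,
                                            prob = (1:13)^1.5)
  gestational_weeks[preterm == 0] <- sample(37:42, n - sum(preterm), replace = TRUE,
                                            prob = c(2, 4, 6, 6, 3, 1))
  birthweight_g <- integer(n)
  birthweight_g[low_bw == 1] <- sample(500:2499, sum(low_bw), replace = TRUE)
  birthweight_g[low_bw == 0] <- sample(2500:4500, n - sum(low_bw), replace = TRUE)
  prenatal_visits <- integer(n)
  prenatal_visits[few_prenatal == 1] <- sample(0:6, sum(few_prenatal), replace = TRUE)
  prenatal_visits[few_prenatal == 0] <- sample(7:14, n - sum(few_prenatal), replace = TRUE)

  birth_date <- draw_season_dates(year, spring)

  anomaly <- as.integer(stats::runif(n) < p$anomaly)
  anomaly_codes <- character(n)
  true_severity <- integer(n)
  anomaly_lethality <- rep(NA_real_, n)
  if (any(anomaly == 1)) {
    drawn <- sample_anomaly_codes(sum(anomaly), cfg)
    anomaly_codes[anomaly == 1] <- drawn$codes
    true_severity[anomaly == 1] <- drawn$max_grade
    anomaly_lethality[anomaly == 1] <- drawn$max_lethality
  }

  # municipal dichotomous truth flags: below the pooled indicator mean
  ind <- municipalities$indicators
  low_nurse_tab <- ind$nurse_density < mean(ind$nurse_density)
  low_insur_tab <- ind$insurance_coverage < mean(ind$insurance_coverage)
  row <- match(paste(municipality_code, year), paste(ind$municipality_code, ind$year))
  low_nurse <- as.integer(low_nurse_tab[row])
  low_insurance <- as.integer(low_insur_tab[row])

  latent <- tibble::tibble(
    male = male, low_bw = low_bw, extreme_maternal_age = extreme_age,
    few_prenatal = few_prenatal, multiple_preg = multiple,
    spring_summer = spring, preterm = preterm, cesarean = cesarean,
    severity_grade = true_severity, anomaly_lethality = anomaly_lethality,
    low_nurse_density = low_nurse, low_insurance = low_insurance,
    muni_idx = muni_idx
  )

  cohort <- tibble::tibble(
    record_id = sprintf("B%07d", seq_len(n)),
    sex = ifelse(male == 1, "male", "female"),
    birthweight_g = birthweight_g,
    maternal_age_y = maternal_age_y,
    gestational_weeks = gestational_weeks,
    delivery = ifelse(cesarean == 1, "cesarean", "vaginal"),
    prenatal_visits = prenatal_visits,
    pregnancy = ifelse(multiple == 1, "multiple", "singleton"),
    birth_date = birth_date,
    municipality_code = municipality_code,
    anomaly_flag = ifelse(anomaly == 1, "yes", "no"),
    anomaly_codes = anomaly_codes,
    neonatal_death = NA
  )

  mr <- cfg$missingness_rates
  for (field in names(mr)) {
    if (mr[[field]] <= 0) next
    gone <- stats::runif(n) < mr[[field]]
    cohort[[field]][gone] <- NA
    if (field == "anomaly_flag") cohort$anomaly_codes[gone] <- ""
  }

  attr(cohort, "latent") <- latent
  cohort
}

draw_season_dates <- function(year, spring_flag) {
  n <- length(year)
  # day-of-year pools for each season under the default Sep 23 - Mar 20 window
  # (non-leap reference year; Feb 29 never emitted)
  doy <- seq_len(365)
  ref <- as.Date("2015-01-01") + doy - 1
  ss <- is_spring_summer(ref) == 1L
  pool_ss <- doy[ss]
  pool_aw <- doy[!ss]
  pick <- integer(n)
  pick[spring_flag == 1] <- sample(pool_ss, sum(spring_flag), replace = TRUE)
  pick[spring_flag == 0] <- sample(pool_aw, n - sum(spring_flag), replace = TRUE)
  as.Date(sprintf("%d-01-01", year)) + (pick - 1)
}

build_linear_predictor <- function(latent, u, lo) {
  eta <- u[latent$muni_idx] +
    lo[["male"]] * latent$male +
    lo[["low_bw"]] * latent$low_bw +
    lo[["extreme_maternal_age"]] * latent$extreme_maternal_age +
    lo[["few_prenatal"]] * latent$few_prenatal +
    lo[["multiple_preg"]] * latent$multiple_preg +
    lo[["spring_summer"]] * latent$spring_summer +
    lo[["low_nurse_density"]] * latent$low_nurse_density +
    lo[["low_insurance"]] * latent$low_insurance
  eta <- eta +
    ifelse(latent$preterm == 1,
           ifelse(latent$cesarean == 1, lo[["cesarean_preterm"]], lo[["vaginal_preterm"]]),
           ifelse(latent$cesarean == 1, lo[["cesarean_term"]], 0))
  eta <- eta +
    ifelse(latent$severity_grade == 1, lo[["severity_1"]],
           ifelse(latent$severity_grade == 2, lo[["severity_2"]],
                  ifelse(latent$severity_grade == 3, lo[["severity_3"]], 0)))
  eta
}

#' Simulate neonatal-death outcomes
#'
#' Computes `P(death) = logistic(baseline + sum(ln(OR) * flag) +
#' u[municipality])` from the latent truth flags and draws deaths
#' independently. When `cfg$baseline_log_odds` is `NULL` the baseline is
#' solved so the expected marginal death rate equals `cfg$target_death_rate`.
#' In `"lethality"` mode, births with a specified anomaly instead die with
#' probability equal to their most lethal category's configured lethality.
#'
#' @param cohort output of [generate_births()] (carries the `latent`
#'   attribute).
#' @param municipalities output of [generate_municipalities()].
#' @param cfg the [sim_config()].
#' @return list: `cohort` with `neonatal_death` filled, `baseline_log_odds`,
#'   and the per-record death probabilities `p`.
#' @export
simulate_outcomes <- function(cohort, municipalities, cfg) {
  latent <- attr(cohort, "latent")
  if (is.null(latent)) stop("cohort lacks the 'latent' attribute from generate_births()",
                            call. = FALSE)
  u <- municipalities$latent$u
  effect <- cfg$indicator_spec$effect
  if (any(effect != 0)) {
    # direct indicator effects on the municipality intercept (per SD units)
    ind <- municipalities$indicators
    first_year <- ind[ind$year == cfg$years[1], ]
    ord <- match(municipalities$latent$municipality_code, first_year$municipality_code)
    for (i in seq_len(nrow(cfg$indicator_spec))) {
      s <- cfg$indicator_spec[i, ]
      if (s$effect != 0) {
        z <- (first_year[[s$indicator]][ord] - s$mean) / s$sd
        u <- u + s$effect * z
      }
    }
  }
  eta0 <- build_linear_predictor(latent, u, cfg$condition_log_odds)

  anomaly_direct <- cfg$anomaly_effect == "lethality" & !is.na(latent$anomaly_lethality)
  b0 <- cfg$baseline_log_odds
  if (is.null(b0)) {
    target <- cfg$target_death_rate
    f <- function(b) mean(stats::plogis(b + eta0[!anomaly_direct])) - target
    b0 <- stats::uniroot(f, c(-30, 5), tol = 1e-10)$root
  }
  prob <- stats::plogis(b0 + eta0)
  if (any(anomaly_direct)) prob[anomaly_direct] <- latent$anomaly_lethality[anomaly_direct]
  cohort$neonatal_death <- stats::runif(nrow(cohort)) < prob
  attr(cohort, "latent") <- latent
  list(cohort = cohort, baseline_log_odds = b0, p = prob)
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_municipalities()], [generate_births()] and
#' [simulate_outcomes()] under one seed and packages the result with a truth
#' record (all latent parameters) for recovery tests. Fixed seed gives
#' byte-identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `neorisk_simulation`: `cohort` (with outcome),
#'   `indicators`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  munis <- generate_municipalities(cfg)
  cohort <- generate_births(cfg, munis)
  sim <- simulate_outcomes(cohort, munis, cfg)
  spec <- cfg$anomaly_spec
  truth <- list(
    seed = seed,
    baseline_log_odds = sim$baseline_log_odds,
    condition_log_odds = as.list(cfg$condition_log_odds),
    random_intercept_var = cfg$random_intercept_var,
    municipality = munis$latent,
    true_category_grade = stats::setNames(true_grade_from_lethality(spec$lethality),
                                          spec$category),
    anomaly_effect = cfg$anomaly_effect,
    dependence_note = paste(
      "covariate dependence (multiple/preterm/low birth weight cross-terms)",
      "is a synthetic assumption; the published study reports marginals only"),
    latent = attr(sim$cohort, "latent")
  )
  structure(list(cohort = sim$cohort, indicators = munis$indicators, truth = truth),
            class = "neorisk_simulation")
}

#' Predictors from a simulation's latent truth
#'
#' Builds the derived-predictor tibble directly from the generator's truth
#' record (pre-missingness flags, true severity grades). Used for
#' parameter-recovery studies, where the question is estimation given the
#' true design, not the upstream derivation steps.
#'
#' @param sim a `neorisk_simulation`.
#' @return tibble with the model variable columns, `municipality_code`,
#'   `neonatal_death` and `complete = TRUE`.
#' @export
latent_predictors <- function(sim) {
  lat <- sim$truth$latent
  tibble::tibble(
    male = lat$male, low_bw = lat$low_bw,
    extreme_maternal_age = lat$extreme_maternal_age,
    severity_grade = lat$severity_grade,
    delivery_ga = factor(
      ifelse(lat$preterm == 1,
             ifelse(lat$cesarean == 1, "cesarean_preterm", "vaginal_preterm"),
             ifelse(lat$cesarean == 1, "cesarean_term", "vaginal_term")),
      levels = c("vaginal_term", "cesarean_term", "cesarean_preterm", "vaginal_preterm")
    ),
    few_prenatal = lat$few_prenatal, spring_summer = lat$spring_summer,
    multiple_preg = lat$multiple_preg,
    low_nurse_density = lat$low_nurse_density, low_insurance = lat$low_insurance,
    municipality_code = sim$truth$municipality$municipality_code[lat$muni_idx],
    neonatal_death = sim$cohort$neonatal_death,
    complete = TRUE
  )
}

#' Write a simulation to disk
#'
#' Writes `cohort.csv`, `indicators.csv` and `truth.json` (latent parameters;
#' scalar fields unboxed) into `dir`.
#'
#' @param sim a `neorisk_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(sim$indicators, file.path(dir, "indicators.csv"), progress = FALSE)
  truth <- sim$truth
  truth$latent <- NULL  # large per-record matrix; keep truth.json compact
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @export
print.neorisk_simulation <- function(x, ...) {
  cat(sprintf("Synthetic birth cohort: %d births, %d municipalities, %d death(s) (%.2f per 1,000)\n",
              nrow(x$cohort), nrow(x$truth$municipality),
              sum(x$cohort$neonatal_death), 1000 * mean(x$cohort$neonatal_death)))
  invisible(x)
}
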