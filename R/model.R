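condition_order <- c(
  "male", "low_bw", "extreme_maternal_age",
  "severity_1", "severity_2", "severity_3",
  "cesarean_term", "cesarean_preterm", "vaginal_preterm",
  "few_prenatal", "spring_summer", "multiple_preg",
  "low_nurse_density", "low_insurance"
)

variable_of_condition <- c(
  male = "male", low_bw = "low_bw", extreme_maternal_age = "extreme_maternal_age",
  severity_1 = "severity_grade", severity_2 = "severity_grade",
  severity_3 = "severity_grade",
  cesarean_term = "delivery_ga", cesarean_preterm = "delivery_ga",
  vaginal_preterm = "delivery_ga",
  few_prenatal = "few_prenatal", spring_summer = "spring_summer",
  multiple_preg = "multiple_preg",
  low_nurse_density = "low_nurse_density", low_insurance = "low_insurance"
)

#' Expand derived predictors into the 14 condition dummies
#'
#' One 0/1 column per non-reference condition (reference levels: female,
#' >=2,500 g, age 17-39, no anomaly, vaginal term, >=7 visits, autumn/winter,
#' singleton, >=mean nurse density, >=mean insurance coverage).
#'
#' @param predictors tibble from [derive_predictors()].
#' @return tibble of the condition dummy columns, in canonical order.
#' @export
condition_design <- function(predictors) {
  tibble::tibble(
    male = predictors$male,
    low_bw = predictors$low_bw,
    extreme_maternal_age = predictors$extreme_maternal_age,
    severity_1 = as.integer(predictors$severity_grade == 1),
    severity_2 = as.integer(predictors$severity_grade == 2),
    severity_3 = as.integer(predictors$severity_grade == 3),
    cesarean_term = as.integer(predictors$delivery_ga == "cesarean_term"),
    cesarean_preterm = as.integer(predictors$delivery_ga == "cesarean_preterm"),
    vaginal_preterm = as.integer(predictors$delivery_ga == "vaginal_preterm"),
    few_prenatal = predictors$few_prenatal,
    spring_summer = predictors$spring_summer,
    multiple_preg = predictors$multiple_preg,
    low_nurse_density = predictors$low_nurse_density,
    low_insurance = predictors$low_insurance
  )
}

#' Univariate logistic screening of individual predictors
#'
#' One maximum-likelihood logistic fit per variable (categorical variables,
#' i.e. the severity grade and the delivery x gestational-age combination,
#' enter with their reference level and contribute one term per non-reference
#' level). Reports per-term odds ratios with Wald CIs and p-values, a
#' per-variable likelihood-ratio p-value and McFadden pseudo-R-squared; a
#' variable passes when its p-value is below `alpha` (default 0.20).
#' Perfect separation is flagged and the variable excluded with a warning.
#'
#' @param predictors tibble from [derive_predictors()].
#' @param outcome logical/0-1 outcome vector.
#' @param alpha screening threshold.
#' @param variables which model variables to screen.
#' @return tibble `variable, term, or, ci_low, ci_high, p_term, p_variable,
#'   pseudo_r2, separation, pass`.
#' @export
univariate_screen <- function(predictors, outcome, alpha = 0.20,
                              variables = unique(variable_of_condition)) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2) {
    stop("outcome is constant; cannot screen", call. = FALSE)
  }
  design <- condition_design(predictors)
  rows <- lapply(variables, function(v) {
    terms <- names(variable_of_condition)[variable_of_condition == v]
    cc <- stats::complete.cases(design[terms]) & !is.na(outcome)
    constant <- vapply(design[cc, terms, drop = FALSE],
                       function(x) length(unique(x)) < 2, logical(1))
    if (all(constant)) {
      warning(sprintf("'%s' has no variation; variable excluded", v), call. = FALSE)
      return(tibble::tibble(variable = v, term = terms, or = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_term = NA_real_, p_variable = NA_real_,
                            pseudo_r2 = NA_real_, separation = FALSE, pass = FALSE))
    }
    terms <- terms[!constant]
    dat <- data.frame(.y = outcome[cc], design[cc, terms, drop = FALSE])
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
    null_ll <- as.numeric(stats::logLik(stats::glm(.y ~ 1, data = dat,
                                                   family = stats::binomial())))
    ll <- as.numeric(stats::logLik(fit))
    ct <- summary(fit)$coefficients
    idx <- match(terms, rownames(ct))
    beta <- ct[idx, "Estimate"]
    se <- ct[idx, "Std. Error"]
    separation <- any(abs(beta) > 15 | se > 100)
    if (separation) {
      warning(sprintf("possible perfect separation for '%s'; variable excluded", v),
              call. = FALSE)
    }
    lr_p <- stats::pchisq(2 * (ll - null_ll), df = length(terms), lower.tail = FALSE)
    tibble::tibble(
      variable = v, term = terms,
      or = ifelse(rep(separation, length(terms)) & abs(beta) > 15, Inf, exp(beta)),
      ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
      p_term = ct[idx, "Pr(>|z|)"],
      p_variable = lr_p,
      pseudo_r2 = 1 - ll / null_ll,
      separation = separation,
      pass = !separation & lr_p < alpha
    )
  })
  dplyr::bind_rows(rows)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor j
#' on the other predictors (optionally weighted, for aggregated designs).
#' Rank-deficient designs error, naming the collinear columns.
#'
#' @param X data frame or matrix of at least two predictor columns.
#' @param weights optional observation weights.
#' @return named numeric vector of VIFs.
#' @export
check_vif <- function(X, weights = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least 2 predictors for VIF", call. = FALSE)
  M <- cbind(1, as.matrix(X))
  qr_rank <- qr(M)$rank
  if (qr_rank < ncol(M)) {
    piv <- qr(M)$pivot
    dropped <- colnames(M)[piv[(qr_rank + 1):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  vapply(names(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[setdiff(names(X), j)], weights = weights)
    r2 <- summary(fit)$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

aggregate_design <- function(design, outcome, group) {
  dat <- data.frame(design, .g = group, .y = as.integer(outcome), check.names = FALSE)
  agg <- dplyr::summarise(
    dplyr::group_by(dat, dplyr::across(dplyr::all_of(c(names(design), ".g")))),
    .deaths = sum(.data$.y), .n = dplyr::n(), .groups = "drop"
  )
  agg
}

#' Fit the two-level random-intercept logistic model
#'
#' Complete-case records only; municipalities enter as a random intercept.
#' The likelihood is maximized by adaptive Gauss-Hermite quadrature
#' (`nAGQ` points, default 11; 1 gives the Laplace approximation).
#' Identical covariate patterns within a municipality are aggregated into
#' binomial counts first, which leaves the likelihood unchanged. After the
#' ENTER fit, variables whose terms are all non-significant (p >=
#' `p_drop`) are dropped and the model refitted, until every retained
#' variable is significant.
#'
#' @param predictors tibble from [derive_predictors()] (its incomplete rows
#'   are excluded here).
#' @param outcome logical outcome vector aligned with `predictors`.
#' @param group municipality identifier vector aligned with `predictors`.
#' @param conditions which condition dummies to include (ENTER set).
#' @param nAGQ quadrature points (>= 1).
#' @param p_drop significance threshold for the post-fit pruning (0.05); set
#'   `drop_nonsig = FALSE` to keep the ENTER model as-is.
#' @param drop_nonsig prune non-significant variables and refit.
#' @return object of class `model_fit`: `conditions` tibble (`ln_or`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p_value`), `intercept_odds`, `sigma2_u`,
#'   `wald_chi2`, `wald_df`, `lr_vs_pooled` (boundary-halved chi-squared
#'   p-value), `n_used`, `n_groups`, `vif`, `nAGQ`, `messages`.
#' @export
fit_multilevel_logistic <- function(predictors, outcome, group,
                                    conditions = condition_order,
                                    nAGQ = 11, p_drop = 0.05,
                                    drop_nonsig = TRUE) {
  design <- condition_design(predictors)[conditions]
  cc <- stats::complete.cases(design) & !is.na(outcome) & !is.na(group)
  design <- design[cc, , drop = FALSE]
  constant <- vapply(design, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    nr_log("condition(s) without variation dropped: ",
           paste(conditions[constant], collapse = ", "), level = "WARN")
    conditions <- conditions[!constant]
  }
  outcome <- as.integer(outcome[cc])
  group <- as.character(group[cc])

  n_groups <- length(unique(group))
  if (n_groups < 2) stop("need at least 2 municipalities to fit a multilevel model",
                         call. = FALSE)
  if (n_groups == length(group)) {
    stop("one record per municipality: the random-intercept variance is not identifiable",
         call. = FALSE)
  }

  msgs <- character(0)
  current <- conditions
  repeat {
    agg <- aggregate_design(design[current], outcome, group)
    fml <- stats::as.formula(paste(
      "cbind(.deaths, .n - .deaths) ~",
      paste(current, collapse = " + "), "+ (1 | .g)"
    ))
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = agg, family = stats::binomial(), nAGQ = nAGQ),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    ct <- stats::coef(summary(fit))
    p <- ct[current, "Pr(>|z|)"]
    if (!drop_nonsig) break
    # drop variables whose every term is non-significant
    by_var <- split(p, variable_of_condition[current])
    drop_vars <- names(by_var)[vapply(by_var, function(pp) all(pp >= p_drop), logical(1))]
    if (length(drop_vars) == 0) break
    nr_log("dropping non-significant variable(s): ", paste(drop_vars, collapse = ", "))
    current <- current[!(variable_of_condition[current] %in% drop_vars)]
    if (length(current) == 0) stop("no condition remains significant", call. = FALSE)
  }

  beta <- ct[current, "Estimate"]
  se <- ct[current, "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_u <- vc$vcov[1]

  # joint Wald test on the condition coefficients
  V <- as.matrix(stats::vcov(fit))[current, current, drop = FALSE]
  wald <- as.numeric(t(beta) %*% solve(V, beta))

  # LR against the pooled model, on the boundary-corrected (halved) chi-sq(1)
  pooled <- stats::glm(
    stats::as.formula(paste("cbind(.deaths, .n - .deaths) ~",
                            paste(current, collapse = " + "))),
    data = agg, family = stats::binomial()
  )
  ll_ml <- as.numeric(stats::logLik(fit))
  ll_pooled <- as.numeric(stats::logLik(pooled))
  lr_stat <- max(0, 2 * (ll_ml - ll_pooled))
  lr_p <- 0.5 * stats::pchisq(lr_stat, df = 1, lower.tail = FALSE)

  vif <- if (length(current) >= 2) check_vif(agg[current], weights = agg$.n) else
    stats::setNames(1, current)

  out <- list(
    conditions = tibble::tibble(
      condition = current,
      ln_or = unname(beta), se = unname(se), or = unname(exp(beta)),
      ci_low = unname(exp(beta - 1.96 * se)), ci_high = unname(exp(beta + 1.96 * se)),
      p_value = unname(ct[current, "Pr(>|z|)"])
    ),
    intercept_odds = unname(exp(ct["(Intercept)", "Estimate"])),
    sigma2_u = sigma2_u,
    wald_chi2 = wald, wald_df = length(current),
    lr_vs_pooled = list(statistic = lr_stat, p_value = lr_p),
    n_used = length(outcome), n_groups = n_groups,
    vif = as.list(vif), nAGQ = nAGQ, messages = msgs
  )
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "Multilevel logistic fit: %d condition(s), n = %d in %d municipalities\n",
    nrow(x$conditions), x$n_used, x$n_groups))
  cat(sprintf("  sigma^2(municipality) = %.4f; Wald chi2(%d) = %.2f; LR vs pooled p = %.3g\n",
              x$sigma2_u, x$wald_df, x$wald_chi2, x$lr_vs_pooled$p_value))
  print(x$conditions)
  invisible(x)
}

#' Serialize / read a model fit as JSON
#'
#' Full-precision floats, so `ln_or` survives a round-trip bit-for-bit.
#'
#' @param fit a `model_fit`.
#' @param path JSON path.
#' @return `path` (write) or the `model_fit` (read).
#' @export
write_model_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_fit
#' @export
read_model_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$conditions <- tibble::as_tibble(x$conditions)
  class(x) <- "model_fit"
  x
}
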