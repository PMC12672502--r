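#' Proxy municipal neonatal mortality rate
#'
#' Aggregates the cohort by (municipality, birth year) and computes
#' `NMR = 1000 * deaths / births`. Death attribution follows the birth year
#' (deaths among same-calendar-year births), the stated proxy approximation;
#' cells with zero births are omitted.
#'
#' @param cohort tibble with `municipality_code`, `birth_date` (or `year`)
#'   and `neonatal_death`.
#' @return tibble `municipality_code, year, births, deaths, nmr`.
#' @export
compute_municipal_nmr <- function(cohort) {
  if (!"year" %in% names(cohort)) {
    cohort$year <- as.integer(format(cohort$birth_date, "%Y"))
  }
  out <- dplyr::summarise(
    dplyr::group_by(cohort, .data$municipality_code, .data$year),
    births = dplyr::n(),
    deaths = sum(.data$neonatal_death, na.rm = TRUE),
    .groups = "drop"
  )
  out$nmr <- 1000 * out$deaths / out$births
  out
}

#' z-score standardization
#'
#' Centers and scales to mean 0, SD 1. A constant input is a degenerate
#' indicator and errors.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return standardized numeric vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("degenerate indicator: zero variance", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Pearson screen of indicators against the standardized NMR
#'
#' Per indicator: Pearson r against the (standardized) NMR with the two-sided
#' p-value from the t-distribution of r; an indicator passes when p < `alpha`
#' (default 0.20).
#'
#' @param indicators data frame of indicator columns, rows aligned with `nmr`.
#' @param nmr numeric outcome vector (standardized or not; r is scale-free).
#' @param alpha screening threshold on the p-value.
#' @return tibble `indicator, r, p_value, pass`.
#' @export
pearson_screen <- function(indicators, nmr, alpha = 0.20) {
  if (length(nmr) < 3) stop("need at least 3 (municipality, year) pairs", call. = FALSE)
  rows <- lapply(names(indicators), function(nm) {
    ct <- stats::cor.test(indicators[[nm]], nmr, method = "pearson")
    tibble::tibble(indicator = nm, r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$pass <- out$p_value < alpha
  out
}

# connected components of an undirected adjacency matrix (single linkage)
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  current <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    current <- current + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- current
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Group correlated indicators and retain one per group
#'
#' Single-linkage grouping on |r| >= `r_threshold` between passing
#' indicators (a chain A-B, B-C joins all three even if A and C are weakly
#' correlated). Within each group the indicator with the largest |r| against
#' the NMR is retained; ties break by lexicographic name.
#'
#' @param indicators data frame of the passing indicators.
#' @param nmr outcome vector aligned with rows.
#' @param r_threshold absolute pairwise correlation that links two indicators.
#' @return tibble `indicator, group, r_with_nmr, retained`.
#' @export
group_and_retain <- function(indicators, nmr, r_threshold = 0.50) {
  nms <- names(indicators)
  if (length(nms) == 0) {
    return(tibble::tibble(indicator = character(0), group = integer(0),
                          r_with_nmr = numeric(0), retained = logical(0)))
  }
  cm <- abs(stats::cor(as.data.frame(indicators)))
  adj <- cm >= r_threshold
  diag(adj) <- FALSE
  comp <- adjacency_components(adj)
  r_nmr <- vapply(nms, function(nm) stats::cor(indicators[[nm]], nmr), numeric(1))
  out <- tibble::tibble(indicator = nms, group = comp, r_with_nmr = r_nmr)
  out <- out[order(out$group, -abs(out$r_with_nmr), out$indicator), ]
  out$retained <- !duplicated(out$group)
  out[order(match(out$indicator, nms)), ]
}

lm_term_pvalues <- function(fit) {
  ct <- summary(fit)$coefficients
  p <- ct[, "Pr(>|t|)"]
  names(p) <- gsub("`", "", rownames(ct), fixed = TRUE)
  p[setdiff(names(p), "(Intercept)")]
}

#' Stepwise OLS with p-value thresholds and VIF control
#'
#' Bidirectional stepwise selection on p-values (entry when p < `p_enter`,
#' removal when p >= `p_remove`), followed by iterative removal of any
#' variable with VIF > `vif_max` (largest first, refit). Among all valid
#' models visited (all terms significant, VIFs within bounds) the one with
#' the highest adjusted R-squared is returned. An empty model (no variable
#' qualifies) is reported with adjusted R-squared 0, not an error.
#'
#' @param nmr_std standardized outcome vector.
#' @param candidates data frame of candidate predictor columns (standardized).
#' @param p_enter,p_remove entry/removal thresholds (default 0.05 both).
#' @param vif_max maximum tolerated VIF (default 2).
#' @return list of class `screen_model`: `terms` (tibble with `beta`,
#'   `ci_low`, `ci_high`, `p_value`, `vif`), `adj_r2`, `n`.
#' @export
stepwise_ols <- function(nmr_std, candidates, p_enter = 0.05, p_remove = 0.05,
                         vif_max = 2) {
  stopifnot(ncol(candidates) >= 1)
  dat <- data.frame(.nmr = nmr_std, candidates, check.names = FALSE)
  all_vars <- names(candidates)
  in_model <- character(0)
  visited <- list()

  fit_with <- function(vars) {
    fml <- if (length(vars) == 0) ".nmr ~ 1" else
      paste(".nmr ~", paste(sprintf("`%s`", vars), collapse = " + "))
    stats::lm(stats::as.formula(fml), data = dat)
  }
  note_visit <- function(vars, fit) {
    ok <- TRUE
    if (length(vars) > 0) {
      p <- lm_term_pvalues(fit)
      v <- if (length(vars) >= 2) check_vif(as.data.frame(candidates[vars])) else
        stats::setNames(1, vars)
      ok <- all(p < p_remove) && all(v <= vif_max)
    }
    visited[[length(visited) + 1]] <<- list(vars = vars, ok = ok,
                                            adj_r2 = summary(fit)$adj.r.squared)
  }

  repeat {
    changed <- FALSE
    # forward: best p among candidates not in the model
    out_vars <- setdiff(all_vars, in_model)
    if (length(out_vars) > 0) {
      trial_p <- vapply(out_vars, function(v) {
        unname(lm_term_pvalues(fit_with(c(in_model, v)))[v])
      }, numeric(1))
      trial_p[is.na(trial_p)] <- Inf  # aliased with the current model
      best <- which.min(trial_p)
      if (trial_p[best] < p_enter) {
        in_model <- c(in_model, out_vars[best])
        note_visit(in_model, fit_with(in_model))
        changed <- TRUE
      }
    }
    # backward: drop the worst term at/above the removal threshold
    if (length(in_model) > 0) {
      f <- fit_with(in_model)
      p <- lm_term_pvalues(f)
      worst <- which.max(p)
      if (p[worst] >= p_remove) {
        in_model <- setdiff(in_model, names(p)[worst])
        note_visit(in_model, fit_with(in_model))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # VIF pruning on the converged model
  while (length(in_model) >= 2) {
    v <- check_vif(as.data.frame(candidates[in_model]))
    if (max(v) <= vif_max) break
    in_model <- setdiff(in_model, names(which.max(v)))
    note_visit(in_model, fit_with(in_model))
  }
  note_visit(in_model, fit_with(in_model))

  valid <- Filter(function(m) m$ok, visited)
  if (length(valid) == 0 || all(vapply(valid, function(m) length(m$vars), integer(1)) == 0)) {
    return(structure(list(
      terms = tibble::tibble(indicator = character(0), beta = numeric(0),
                             ci_low = numeric(0), ci_high = numeric(0),
                             p_value = numeric(0), vif = numeric(0)),
      adj_r2 = 0, n = length(nmr_std)), class = "screen_model"))
  }
  best <- valid[[which.max(vapply(valid, function(m) m$adj_r2, numeric(1)))]]
  fit <- fit_with(best$vars)
  ci <- stats::confint(fit)
  ct <- summary(fit)$coefficients
  rownames(ct) <- gsub("`", "", rownames(ct), fixed = TRUE)
  rownames(ci) <- gsub("`", "", rownames(ci), fixed = TRUE)
  keep <- best$vars
  vifs <- if (length(best$vars) >= 2) check_vif(as.data.frame(candidates[best$vars])) else
    stats::setNames(1, best$vars)
  structure(list(
    terms = tibble::tibble(
      indicator = best$vars,
      beta = unname(ct[keep, "Estimate"]),
      ci_low = unname(ci[keep, 1]), ci_high = unname(ci[keep, 2]),
      p_value = unname(ct[keep, "Pr(>|t|)"]),
      vif = unname(vifs[best$vars])
    ),
    adj_r2 = summary(fit)$adj.r.squared, n = length(nmr_std)
  ), class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf("Ecological indicator model: %d term(s), adjusted R^2 = %.4f, n = %d\n",
              nrow(x$terms), x$adj_r2, x$n))
  if (nrow(x$terms) > 0) print(x$terms)
  invisible(x)
}

#' Dichotomize indicators at the pooled mean
#'
#' For each indicator, the risk flag is 1 when the value is below the mean
#' (lower nurse density / lower coverage is the risk condition) and 0 at or
#' above it. The means are stored so validation data are dichotomized with
#' the development means, never recomputed ones.
#'
#' @param indicators data frame of indicator columns over all
#'   municipality-years of the development data.
#' @param means optional named vector of stored development means to reuse.
#' @return list: `flags` (tibble of 0/1 columns), `means` (named vector).
#' @export
dichotomize_by_mean <- function(indicators, means = NULL) {
  if (is.null(means)) {
    means <- vapply(indicators, function(x) mean(x, na.rm = TRUE), numeric(1))
  }
  flags <- tibble::as_tibble(lapply(names(indicators), function(nm) {
    as.integer(indicators[[nm]] < means[[nm]])
  }), .name_repair = "minimal")
  names(flags) <- names(indicators)
  list(flags = flags, means = means)
}

#' Run the full ecological screening stage
#'
#' Computes the proxy NMR, standardizes it and the indicators, screens by
#' Pearson correlation (p < 0.20), groups correlated indicators (|r| >= 0.50,
#' single linkage) retaining one per group, fits the stepwise OLS with VIF
#' control, and dichotomizes the final indicators at their pooled means.
#'
#' @param cohort birth cohort tibble (with outcome).
#' @param indicators indicator tibble from [read_indicators()]; columns
#'   flagged in its `excluded_indicators` attribute are dropped.
#' @return list of class `screen_result`: `screen`, `groups`, `model`,
#'   `means`, `muni_flags` (per municipality-year flags of the final
#'   indicators, named `low_<indicator>`).
#' @export
municipal_screen <- function(cohort, indicators) {
  excluded <- attr(indicators, "excluded_indicators") %||% character(0)
  ind_cols <- setdiff(names(indicators), c("municipality_code", "year", excluded))
  nmr <- compute_municipal_nmr(cohort)
  merged <- dplyr::inner_join(nmr, indicators, by = c("municipality_code", "year"))
  nmr_std <- zscore(merged$nmr)
  std <- tibble::as_tibble(lapply(merged[ind_cols], zscore))

  screen <- pearson_screen(std, nmr_std)
  passing <- screen$indicator[screen$pass]
  groups <- group_and_retain(std[passing], nmr_std)
  retained <- groups$indicator[groups$retained]
  model <- if (length(retained) > 0) stepwise_ols(nmr_std, std[retained]) else
    stepwise_ols(nmr_std, std[passing][0])
  final_ind <- model$terms$indicator
  dich <- dichotomize_by_mean(merged[final_ind])
  muni_flags <- merged[, c("municipality_code", "year")]
  for (nm in final_ind) muni_flags[[paste0("low_", nm)]] <- dich$flags[[nm]]
  structure(list(screen = screen, groups = groups, model = model,
                 means = dich$means, muni_flags = muni_flags),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Municipal indicator screen: %d/%d passed p<0.20; %d retained after grouping\n",
              sum(x$screen$pass), nrow(x$screen), sum(x$groups$retained)))
  print(x$model)
  invisible(x)
}
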