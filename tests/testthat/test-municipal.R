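test_that("municipal NMR is deaths per 1,000 births by municipality-year", {
  cohort <- tibble::tibble(
    municipality_code = rep(c("3500001", "3500002"), c(250, 100)),
    year = 2015L,
    neonatal_death = c(rep(c(TRUE, FALSE), c(2, 248)), rep(FALSE, 100))
  )
  nmr <- compute_municipal_nmr(cohort)
  expect_equal(nmr$nmr[nmr$municipality_code == "3500001"], 8.0)
  expect_equal(nmr$nmr[nmr$municipality_code == "3500002"], 0.0)
})

test_that("cell totals conserve the cohort-level death rate", {
  sim <- simulate_cohort(sim_config(n_births = 20000, n_municipalities = 30), seed = 2)
  nmr <- compute_municipal_nmr(sim$cohort)
  expect_equal(sum(nmr$births), nrow(sim$cohort))
  expect_equal(sum(nmr$deaths) / sum(nmr$births),
               mean(sim$cohort$neonatal_death))
})

test_that("zscore standardizes, is idempotent, and rejects constants", {
  z <- zscore(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(c(5, 5)), "zero variance")
})

test_that("pearson screen matches the closed-form r and applies p < 0.20", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(0.8, 2.9, 2.6, 4.2, 4.4)
  # sum-of-products formula as an independent oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_screen(tibble::tibble(a = x, b = y), y)
  expect_equal(res$r[res$indicator == "a"], r_oracle, tolerance = 1e-12)
  expect_equal(res$r[res$indicator == "b"], 1)
  expect_true(res$pass[res$indicator == "b"])
  expect_error(pearson_screen(tibble::tibble(a = x[1:2]), y[1:2]), "at least 3")
})

test_that("an independent indicator fails the screen about 80% of the time", {
  set.seed(41)
  fails <- replicate(200, {
    y <- stats::rnorm(1000)
    x <- stats::rnorm(1000)
    !pearson_screen(tibble::tibble(x = x), y)$pass
  })
  # under the null, P(fail) = 0.80 by construction of the p < 0.20 rule
  expect_gt(mean(fails), 0.72)
  expect_lt(mean(fails), 0.88)
})

test_that("grouping is single-linkage on |r| >= 0.50 and keeps the best per group", {
  set.seed(10)
  n <- 4000
  base <- stats::rnorm(n)
  ind <- tibble::tibble(
    a = base + stats::rnorm(n, sd = 0.4),      # a,b,c mutually correlated
    b = base + stats::rnorm(n, sd = 0.4),
    c = base + stats::rnorm(n, sd = 0.4),
    d = stats::rnorm(n)                        # independent
  )
  nmr <- base + stats::rnorm(n, sd = 0.8)
  g <- group_and_retain(ind, nmr)
  expect_equal(length(unique(g$group[g$indicator %in% c("a", "b", "c")])), 1L)
  expect_true(g$retained[g$indicator == "d"])
  expect_equal(sum(g$retained), 2L)

  # chain A-B (0.6), B-C (0.6), A-C weak: one group of three under single linkage
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
  chain <- tibble::tibble(
    A = z1 + 0.3 * z2,
    B = 0.9 * z2 + 0.35 * z1 + 0.35 * z3,
    C = z3 + 0.3 * z2
  )
  cm <- abs(stats::cor(as.data.frame(chain)))
  expect_true(cm["A", "B"] >= 0.5 && cm["B", "C"] >= 0.5 && cm["A", "C"] < 0.5)
  gc <- group_and_retain(chain, nmr)
  expect_equal(length(unique(gc$group)), 1L)
  expect_equal(sum(gc$retained), 1L)
})

test_that("stepwise OLS recovers a known slope and controls VIF", {
  set.seed(12)
  n <- 6450
  x <- stats::rnorm(n)
  y <- -0.03 * x + stats::rnorm(n, sd = 1)
  fit <- stepwise_ols(y, tibble::tibble(x = x))
  if (nrow(fit$terms) == 1) {
    se <- (fit$terms$ci_high - fit$terms$ci_low) / (2 * stats::qt(0.975, n - 2))
    expect_lt(abs(fit$terms$beta - (-0.03)), 3 * se)
  }

  # two orthogonal predictors: both VIF exactly 1 at the design level
  x1 <- rep(c(1, -1), 50); x2 <- rep(c(1, 1, -1, -1), 25)
  expect_equal(unname(check_vif(data.frame(x1, x2))), c(1, 1))

  # duplicated predictor pair: only one survives
  set.seed(13)
  x3 <- stats::rnorm(500)
  y3 <- x3 + stats::rnorm(500, sd = 0.5)
  fit3 <- stepwise_ols(y3, tibble::tibble(p = x3, q = x3))
  expect_equal(nrow(fit3$terms), 1L)
})

test_that("stepwise OLS recovers a sparse support among many candidates", {
  set.seed(14)
  n <- 6450
  X <- as.data.frame(matrix(stats::rnorm(n * 20), n, 20))
  names(X) <- sprintf("ind%02d", 1:20)
  y <- 0.30 * X$ind01 + 0.25 * X$ind05 + 0.20 * X$ind17 + stats::rnorm(n)
  fit <- stepwise_ols(zscore(y), as.data.frame(lapply(X, zscore)))
  expect_true(all(c("ind01", "ind05", "ind17") %in% fit$terms$indicator))
  expect_lte(nrow(fit$terms), 5)
  expect_true(all(fit$terms$vif <= 2))
  expect_true(all(fit$terms$p_value < 0.05))
})

test_that("no qualifying variable yields an empty model, not an error", {
  set.seed(15)
  fit <- stepwise_ols(stats::rnorm(50), tibble::tibble(x = stats::rnorm(50)))
  expect_equal(nrow(fit$terms), 0L)
  expect_equal(fit$adj_r2, 0)
})

test_that("dichotomization cuts below the mean and stores it for reuse", {
  d <- dichotomize_by_mean(tibble::tibble(x = c(1, 2, 3)))
  expect_equal(d$flags$x, c(1L, 0L, 0L))
  expect_equal(d$means[["x"]], 2)
  # all equal: nothing is below the mean
  expect_equal(dichotomize_by_mean(tibble::tibble(x = c(4, 4)))$flags$x, c(0L, 0L))
  # affine rescaling leaves the flags unchanged
  x <- c(3.2, 1.1, 5.6, 2.2, 9.0)
  f1 <- dichotomize_by_mean(tibble::tibble(x = x))$flags$x
  f2 <- dichotomize_by_mean(tibble::tibble(x = 10 + 2.5 * x))$flags$x
  expect_equal(f1, f2)
  # validation data use the stored development mean, not their own
  dev_mean <- d$means
  val <- dichotomize_by_mean(tibble::tibble(x = c(2.5, 1.5)), means = dev_mean)
  expect_equal(val$flags$x, c(0L, 1L))
  expect_equal(val$means, dev_mean)
})

test_that("the full ecological stage runs and reports a coherent result", {
  sim <- simulate_cohort(sim_config(n_births = 30000, n_municipalities = 100,
                                    years = 2014:2015), seed = 21)
  res <- suppressMessages(municipal_screen(sim$cohort, sim$indicators))
  expect_s3_class(res, "screen_result")
  expect_true(all(res$groups$indicator %in% res$screen$indicator[res$screen$pass]))
  # groups partition the passing indicators
  expect_setequal(res$groups$indicator, res$screen$indicator[res$screen$pass])
  if (nrow(res$model$terms) > 0) {
    expect_true(all(res$model$terms$p_value < 0.05))
    expect_true(all(res$model$terms$vif >= 1 & res$model$terms$vif <= 2))
  }
})
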