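test_that("standardization is location-invariant and per-SD scaled", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))           # sample SD of {1,2,3} is 1
  expect_equal(standardize(c(1, 2, 3) + 100), z)
  expect_equal(standardize(c(1, 2, 3), flip = TRUE), -z)
  expect_error(standardize(rep(5, 10)), class = "qct_data_error")
})

test_that("logistic coefficients match a likelihood grid search", {
  y <- c(0, 0, 0, 1, 1, 1)
  z <- c(-1.2, -0.3, 0.5, -0.1, 0.8, 1.4)
  df <- tibble::tibble(y = y == 1, z = z)
  fit <- fracture_or(df, y, z, flip = FALSE)
  b_grid <- grid_logistic(y, standardize(z))
  expect_equal(log(fit$estimate), b_grid[2], tolerance = 1e-3)
})

test_that("a predictor independent of outcome gives OR near 1", {
  co <- withr::with_seed(21, tibble::tibble(
    y = rep(c(TRUE, FALSE), each = 2000),
    x = rnorm(4000)
  ))
  g <- glance(fracture_or(co, y, x))
  expect_equal(g$or, 1, tolerance = 0.15)
  expect_true(g$ci_low < 1 && g$ci_high > 1)
})

test_that("Wald CIs achieve nominal coverage on simulated cohorts", {
  beta <- log(2)
  hits <- withr::with_seed(77, vapply(1:500, function(i) {
    x <- rnorm(150)
    y <- rbinom(150, 1, plogis(-0.5 + beta * x))
    if (length(unique(y)) < 2) return(NA)
    g <- glance(fracture_or(tibble::tibble(y = y == 1, x = x), y, x,
                            flip = FALSE))
    if (g$separable) return(NA)
    g$ci_low <= exp(beta) && exp(beta) <= g$ci_high
  }, logical(1)))
  coverage <- mean(hits, na.rm = TRUE)
  # binomial 3-sigma band around 0.95 at 500 replicates
  expect_gt(coverage, 0.92)
  expect_lt(coverage, 0.98)
})

test_that("risk orientation makes protective measures yield OR above 1", {
  co <- generate_cohort(cohort_spec(seed = 11L))
  g <- glance(fracture_or(co, fracture, trabecular_vbmd))
  expect_gt(g$or, 1)   # lower vBMD in fractured group, flipped predictor
  gadj <- glance(fracture_or(co, fracture, trabecular_vbmd,
                             adjust = c("age", "sex")))
  expect_true(is.finite(gadj$or))
})

test_that("perfect separation is flagged instead of estimated", {
  df <- tibble::tibble(y = rep(c(TRUE, FALSE), each = 10),
                       x = c(1:10, 21:30))
  fit <- fracture_or(df, y, x, flip = FALSE)
  expect_true(fit$separable)
  expect_true(is.na(fit$estimate))
})

test_that("group comparison reports Welch t and chi-squared results", {
  co <- generate_cohort(cohort_spec(seed = 14L))
  tab <- group_compare(co, fracture)
  expect_true(all(c("age", "trabecular_vbmd", "sex") %in% tab$variable))
  expect_lt(tab$p_value[tab$variable == "trabecular_vbmd"], 1e-6)

  # identical groups: t exactly 0
  same <- tibble::tibble(g = rep(c(TRUE, FALSE), each = 4),
                         v = rep(c(1, 2, 3, 4), 2))
  t0 <- group_compare(same, g, vars = "v")
  expect_equal(t0$statistic, 0)

  # equal sex margins: chi-squared exactly 0
  bal <- tibble::tibble(g = rep(c(TRUE, FALSE), each = 4),
                        sex = rep(c("F", "F", "M", "M"), 2),
                        v = rnorm(8))
  c0 <- group_compare(bal, g, vars = "v")
  expect_equal(c0$statistic[c0$variable == "sex"], 0)
})

test_that("summary-statistic Welch t test flags the age difference", {
  res <- welch_t_summary(64.3, 8.6, 44, 72.0, 9.3, 148)
  expect_lt(res$p_value, 0.001)
  # oracle: the same test from reconstructed raw data with exact moments
  x1 <- scale(seq_len(44)) * 8.6 + 64.3
  x2 <- scale(seq_len(148)) * 9.3 + 72.0
  tt <- t.test(x1, x2)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("pooled group summaries reproduce exact whole-sample moments", {
  withr::with_seed(3, {
    x1 <- rnorm(40, 10, 2)
    x2 <- rnorm(60, 14, 3)
  })
  p <- pool_groups(mean(x1), sd(x1), 40, mean(x2), sd(x2), 60)
  expect_equal(p$mean, mean(c(x1, x2)), tolerance = 1e-12)
  expect_equal(p$sd, sd(c(x1, x2)), tolerance = 1e-12)
})

test_that("agreement analyses: bias, limits, and R-squared", {
  a <- c(1.0, 1.1, 0.9, 1.2, 1.05)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(r_squared(a, a), 1)
  ba <- bland_altman(a + 0.05, a)
  expect_equal(ba$bias, 0.05, tolerance = 1e-12)
  b <- c(0.95, 1.18, 0.88, 1.15, 1.09)
  expect_equal(bland_altman(a, b)$bias, mean(a - b), tolerance = 1e-12)
  expect_error(bland_altman(a, b[1:3]), class = "qct_data_error")
})

test_that("simulated cohorts track the closed-form binormal AUC", {
  spec <- cohort_spec(n_nonfractured = 4000L, n_fractured = 4000L,
                      seed = 19L)
  co <- generate_cohort(spec)
  for (msr in c("trabecular_vbmd", "dxa_abmd")) {
    m <- spec$measures[spec$measures$measure == msr, ]
    expected <- pnorm((m$mean_nonfractured - m$mean_fractured) /
                        sqrt(m$sd_nonfractured^2 + m$sd_fractured^2))
    auc <- roc_curve(co, fracture, !!rlang::sym(msr))$auc
    expect_equal(auc, expected, tolerance = 0.02)
  }
})
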