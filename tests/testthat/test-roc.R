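test_that("AUC equals the exhaustive concordance-pair count", {
  set.seed(12)
  for (rep in 1:8) {
    n1 <- sample(3:25, 1)
    n0 <- sample(3:25, 1)
    # discretized scores force ties
    x <- c(round(rnorm(n1, 60, 20)), round(rnorm(n0, 100, 20)))
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    df <- tibble::tibble(y = y, x = x)
    r <- roc_curve(df, y, x, direction = "<")
    expect_equal(r$auc, pairwise_auc(-x[y], -x[!y]), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC, including the DeLong variance", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_spec(seed = 2L))
  r <- roc_curve(co, fracture, trabecular_vbmd)
  pr <- pROC::roc(co$fracture, co$trabecular_vbmd, direction = ">",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$auc_var, pROC::var(pr), tolerance = 1e-10)
})

test_that("orientation and separation behave as expected", {
  df <- tibble::tibble(y = c(TRUE, TRUE, FALSE, FALSE), x = c(1, 2, 3, 4))
  expect_equal(roc_curve(df, y, x, direction = "<")$auc, 1)
  expect_equal(roc_curve(df, y, x, direction = ">")$auc, 0)
  one_class <- tibble::tibble(y = c(TRUE, TRUE), x = c(1, 2))
  expect_error(roc_curve(one_class, y, x), class = "qct_data_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  co <- generate_cohort(cohort_spec(seed = 9L))
  r1 <- roc_curve(co, fracture, trabecular_vbmd)$auc
  co$t1 <- exp(co$trabecular_vbmd / 50)
  co$t2 <- co$trabecular_vbmd^3
  expect_equal(roc_curve(co, fracture, t1)$auc, r1, tolerance = 1e-12)
  expect_equal(roc_curve(co, fracture, t2)$auc, r1, tolerance = 1e-12)
})

test_that("the ROC curve is a valid staircase", {
  co <- generate_cohort(cohort_spec(seed = 4L))
  curve <- tidy(roc_curve(co, fracture, integral_vbmd))
  # along decreasing specificity, sensitivity never decreases
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$specificity) <= 0))
  expect_true(all(curve$sensitivity >= 0 & curve$sensitivity <= 1))
})

test_that("DeLong self-comparison and rank-transform comparisons are null", {
  co <- generate_cohort(cohort_spec(seed = 6L))
  self <- delong_test(co, fracture, trabecular_vbmd, trabecular_vbmd)
  expect_equal(self$auc_diff, 0)
  expect_equal(self$p_value, 1)
  co$mono <- log(co$trabecular_vbmd - min(co$trabecular_vbmd) + 1)
  mono <- delong_test(co, fracture, trabecular_vbmd, mono)
  expect_equal(mono$auc_diff, 0, tolerance = 1e-12)
  expect_equal(mono$p_value, 1)
  # symmetry in the pair
  ab <- delong_test(co, fracture, trabecular_vbmd, dxa_abmd)
  ba <- delong_test(co, fracture, dxa_abmd, trabecular_vbmd)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$auc_diff, -ba$auc_diff, tolerance = 1e-12)
})

test_that("DeLong matches pROC's paired test and a bootstrap variance", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_spec(seed = 2L))
  dl <- delong_test(co, fracture, trabecular_vbmd, dxa_abmd)
  pa <- pROC::roc(co$fracture, co$trabecular_vbmd, direction = ">",
                  quiet = TRUE)
  pb <- pROC::roc(co$fracture, co$dxa_abmd, direction = ">", quiet = TRUE)
  pt <- pROC::roc.test(pa, pb, method = "delong")
  expect_equal(dl$p_value, pt$p.value, tolerance = 1e-10)

  # single-curve DeLong variance against a resampling oracle on a small set
  small <- generate_cohort(cohort_spec(n_nonfractured = 25L,
                                       n_fractured = 20L, seed = 13L))
  r <- roc_curve(small, fracture, trabecular_vbmd)
  vb <- bootstrap_auc_var(small$fracture, -small$trabecular_vbmd,
                          n_boot = 10000, seed = 5)
  expect_lt(abs(r$auc_var - vb) / vb, 0.10)
})

test_that("sensitivity and specificity at cutoffs count correctly", {
  df <- tibble::tibble(
    y = rep(c(TRUE, FALSE), c(4, 4)),
    x = c(70, 75, 90, 150, 85, 95, 130, 160)
  )
  ss <- sens_spec_at(df, y, x, 80)
  expect_equal(ss$sensitivity, 50)     # 2 of 4 fractured below 80
  expect_equal(ss$specificity, 100)
  low <- sens_spec_at(df, y, x, 60)
  expect_equal(low$sensitivity, 0)
  expect_equal(low$specificity, 100)
  high <- sens_spec_at(df, y, x, 1000)
  expect_equal(high$sensitivity, 100)
  expect_equal(high$specificity, 0)
})
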