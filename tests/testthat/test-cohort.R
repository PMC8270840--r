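test_that("large simulated cohorts reproduce the specified group moments", {
  spec <- cohort_spec(n_nonfractured = 10000L, n_fractured = 10000L,
                      seed = 42L)
  co <- generate_cohort(spec)
  for (i in seq_len(nrow(spec$measures))) {
    m <- spec$measures[i, ]
    x0 <- co[[m$measure]][!co$fracture]
    x1 <- co[[m$measure]][co$fracture]
    # 3 standard errors of the mean at n = 1e4
    expect_lt(abs(mean(x0) - m$mean_nonfractured),
              3 * m$sd_nonfractured / 100)
    expect_lt(abs(mean(x1) - m$mean_fractured),
              3 * m$sd_fractured / 100)
    expect_equal(sd(x0), m$sd_nonfractured, tolerance = 0.05)
  }
})

test_that("latent-factor correlation is honoured at both extremes", {
  big0 <- generate_cohort(cohort_spec(n_nonfractured = 10000L,
                                      n_fractured = 100L,
                                      correlation = 0, seed = 7L))
  g0 <- big0[!big0$fracture, ]
  c0 <- cor(g0$trabecular_vbmd, g0$integral_vbmd)
  expect_lt(abs(c0), 0.05)

  big5 <- generate_cohort(cohort_spec(n_nonfractured = 10000L,
                                      n_fractured = 100L,
                                      correlation = 0.5, seed = 7L))
  g5 <- big5[!big5$fracture, ]
  expect_equal(cor(g5$trabecular_vbmd, g5$bmc), 0.5, tolerance = 0.05)
  expect_equal(cor(g5$dxa_abmd, g5$integral_vbmd), 0.5, tolerance = 0.05)
})

test_that("near-zero SDs collapse every subject onto the group mean", {
  m <- reference_cohort_measures()
  m$sd_nonfractured[] <- 1e-9
  m$sd_fractured[] <- 1e-9
  co <- generate_cohort(cohort_spec(n_nonfractured = 10L, n_fractured = 10L,
                                    measures = m, seed = 1L))
  expect_equal(co$trabecular_vbmd[!co$fracture], rep(113.5, 10),
               tolerance = 1e-6)
  expect_equal(co$trabecular_vbmd[co$fracture], rep(62.8, 10),
               tolerance = 1e-6)
})

test_that("cohort generation is seed-deterministic and spec-validated", {
  expect_identical(generate_cohort(cohort_spec(seed = 5L)),
                   generate_cohort(cohort_spec(seed = 5L)))
  expect_error(cohort_spec(n_fractured = 0), class = "qct_data_error")
  expect_error(cohort_spec(correlation = 1), class = "qct_data_error")
})

test_that("the exclusion roster reproduces the screening cascade", {
  roster <- build_exclusion_roster()
  expect_equal(nrow(roster), 360)
  res <- apply_exclusions(roster)
  expect_equal(res$audit$n_removed, c(18, 34, 15, 35, 66))
  expect_equal(res$audit$n_remaining, c(342, 308, 293, 258, 192))
  expect_equal(nrow(res$analyzed), 192)
  expect_equal(sum(res$analyzed$fracture), 148)
  # audit conservation
  expect_equal(nrow(res$analyzed) + sum(res$audit$n_removed), nrow(roster))
})

test_that("empty cascades and clean rosters pass through unchanged", {
  zero <- build_exclusion_roster(counts = c(metastasis_hematologic = 0),
                                 n_initial = 50, n_fractured_analyzed = 20)
  expect_true(all(is.na(zero$exclusion)))
  res <- apply_exclusions(zero)
  expect_equal(res$audit$n_removed, rep(0L, 5))
  expect_equal(nrow(res$analyzed), 50)
})

test_that("inconsistent exclusion counts are rejected", {
  expect_error(
    build_exclusion_roster(counts = c(metastasis_hematologic = 400)),
    class = "qct_data_error"
  )
  expect_error(
    build_exclusion_roster(n_initial = 100, n_fractured_analyzed = 101),
    class = "qct_data_error"
  )
  bad <- tibble::tibble(patient_id = 1:3,
                        exclusion = c(NA, "nonsense", NA))
  expect_error(apply_exclusions(bad), class = "qct_data_error")
})
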