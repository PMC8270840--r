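test_that("body separation passes through explicit subregion labels", {
  ph <- generate_phantom(small_phantom_spec())
  body <- separate_body(ph$mask, "L2")
  expect_identical(array(body, dim(body)),
                   array(ph$mask$labels == 1L, dim(ph$mask$labels)))
  expect_equal(attr(body, "body_source"), "labels")
  expect_error(separate_body(ph$mask, "T5"), class = "qct_data_error")
})

test_that("heuristic separation of an unpartitioned vertebra is accurate", {
  ph <- generate_phantom(small_phantom_spec(body_extent_mm = c(30, 26, 22)))
  truth_body <- ph$mask$labels == 1L
  merged <- ph$mask$labels
  merged[merged > 0L] <- 1L
  unpart <- vertebra_mask(
    merged, tibble::tibble(label = 1L, level = "L2",
                           subregion = NA_character_),
    ph$mask$spacing_mm
  )
  est <- separate_body(unpart, "L2")
  expect_equal(attr(est, "body_source"), "heuristic")
  dice <- 2 * sum(est & truth_body) / (sum(est) + sum(truth_body))
  expect_gte(dice, 0.95)
})

test_that("noiseless phantom measures equal ground truth exactly", {
  cfg <- identity_config()
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  m <- measure_scan(ph$volume, ph$mask, cfg)
  expect_equal(m$trabecular_vbmd, 100, tolerance = 1e-12)
  expect_equal(m$integral_vbmd, ph$truth$integral_vbmd, tolerance = 1e-12)
  expect_equal(m$bmc, ph$truth$bmc_g, tolerance = 1e-12)
  expect_equal(m$body_volume_cm3, ph$truth$body_volume_cm3)
  # two-compartment closed form for the integral density
  n_body <- sum(ph$mask$labels == 1L)
  core <- erode_metric(ph$mask$labels == 1L, 3, ph$mask$spacing_mm)
  n_core <- sum(core)
  expect_equal(m$integral_vbmd,
               (n_core * 100 + (n_body - n_core) * 400) / n_body,
               tolerance = 1e-12)
})

test_that("uniform-density arithmetic: mean and BMC closed forms", {
  d <- array(100, c(20, 20, 20))
  m <- array(TRUE, c(20, 20, 20))
  expect_equal(trabecular_vbmd(d, m), 100)
  expect_equal(integral_vbmd(d, m), 100)
  expect_equal(bmc(d, m, c(1, 1, 1)), 0.8)  # 100 mg/cm^3 over 8 cm^3
  expect_true(is.na(bmc(d, array(FALSE, dim(m)), c(1, 1, 1))))
})

test_that("BMC identity and compartment ordering hold on varied phantoms", {
  cfg <- identity_config()
  for (s in 1:4) {
    ph <- generate_phantom(small_phantom_spec(
      trabecular_density = 60 + 20 * s, cortical_density = 300 + 30 * s,
      noise_sd = 5 * s, seed = s,
      spacing_mm = if (s %% 2) c(1, 1, 1) else c(1.2, 0.9, 1.5)
    ))
    m <- measure_scan(ph$volume, ph$mask, cfg)
    expect_equal(m$bmc, m$integral_vbmd * m$body_volume_cm3 / 1000,
                 tolerance = 1e-10)
    expect_gte(m$integral_vbmd, m$trabecular_vbmd)
  }
})

test_that("noisy trabecular recovery stays within the CLT bound", {
  cfg <- identity_config()
  noise_sd <- 15
  errs <- vapply(1:100, function(s) {
    ph <- generate_phantom(small_phantom_spec(noise_sd = noise_sd, seed = s))
    m <- measure_scan(ph$volume, ph$mask, cfg)
    c(m$trabecular_vbmd - 100, m$n_trabecular_voxels)
  }, numeric(2))
  n_vox <- errs[2, 1]
  bound <- 3 * noise_sd / sqrt(n_vox)  # identity calibration: slope 1
  # each seed's deviation is N(0, sd/sqrt(N)); all within 3 SE up to rare tails
  expect_lt(mean(abs(errs[1, ]) > bound), 0.05)
  expect_lt(abs(mean(errs[1, ])), bound / 3)
})

test_that("trabecular vBMD is spacing-invariant for the same geometry", {
  cfg <- identity_config()
  iso <- generate_phantom(small_phantom_spec(noise_sd = 10, seed = 3))
  aniso <- generate_phantom(small_phantom_spec(
    noise_sd = 10, seed = 3, spacing_mm = c(1, 1, 3)))
  mi <- measure_scan(iso$volume, iso$mask, cfg)
  ma <- measure_scan(aniso$volume, aniso$mask, cfg)
  tol <- 3 * 10 * sqrt(1 / mi$n_trabecular_voxels + 1 / ma$n_trabecular_voxels)
  expect_lt(abs(mi$trabecular_vbmd - ma$trabecular_vbmd), max(tol, 1))
})

test_that("levels whose trabecular compartment vanishes are non-evaluable", {
  cfg <- identity_config()
  ph <- generate_phantom(small_phantom_spec())
  m <- measure_scan(ph$volume, ph$mask, cfg, erosion_mm = 50)
  expect_false(m$evaluable)
  expect_true(is.na(m$trabecular_vbmd))
  expect_false(is.na(m$integral_vbmd))  # body still measurable
})

test_that("patient aggregation averages evaluable eligible levels only", {
  lm <- tibble::tibble(
    level = c("L1", "L2", "L3", "T4"),
    trabecular_vbmd = c(90, 110, 70, 500),
    integral_vbmd = c(150, 170, 120, 600),
    bmc = c(5, 6, 4, 9),
    body_volume_cm3 = c(30, 32, 28, 20),
    evaluable = TRUE,
    excluded = c(FALSE, FALSE, TRUE, FALSE),
    exclusion_reason = c(NA, NA, "fracture", NA)
  )
  agg <- aggregate_patient(lm)
  expect_equal(agg$trabecular_vbmd, 100)  # T4 ineligible, L3 excluded
  expect_equal(agg$n_levels, 2L)
  one <- aggregate_patient(lm[1, ])
  expect_equal(one$trabecular_vbmd, 90)
  none <- aggregate_patient(dplyr::mutate(lm, excluded = TRUE))
  expect_false(none$evaluable)
  expect_true(is.na(none$trabecular_vbmd))
})

test_that("level exclusions for quality reasons are recorded", {
  cfg <- identity_config()
  ph <- generate_phantom(small_phantom_spec(levels = c("L1", "L2")))
  m <- measure_scan(ph$volume, ph$mask, cfg,
                    excluded = tibble::tibble(level = "L1",
                                              reason = "degeneration"))
  expect_true(m$excluded[m$level == "L1"])
  expect_equal(m$exclusion_reason[m$level == "L1"], "degeneration")
  expect_error(
    measure_scan(ph$volume, ph$mask, cfg,
                 excluded = tibble::tibble(level = "L1", reason = "bad")),
    class = "qct_data_error"
  )
})
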