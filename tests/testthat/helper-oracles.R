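# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# all-pairs Euclidean distance transform (inside voxels to nearest background
# voxel centre, array boundary treated as background via a padding ring)
brute_force_edt <- function(mask, spacing_mm) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  bg <- which(!pm, arr.ind = TRUE)
  bgx <- sweep(bg, 2, spacing_mm, `*`)
  out <- array(0, pd)
  fg <- which(pm, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ] * spacing_mm
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <-
      sqrt(min(colSums((t(bgx) - p)^2)))
  }
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# exhaustive concordance-pair AUC: lower score = event, risk-oriented
pairwise_auc <- function(cases, controls) {
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(controls))
}

# two-parameter logistic log-likelihood, maximized by nested grid refinement
grid_logistic <- function(y, z, span = 8, steps = 5) {
  b <- c(0, 0)
  width <- span
  ll <- function(b0, b1) {
    eta <- b0 + b1 * z
    sum(y * eta - log1p(exp(eta)))
  }
  for (s in seq_len(steps)) {
    g0 <- seq(b[1] - width, b[1] + width, length.out = 81)
    g1 <- seq(b[2] - width, b[2] + width, length.out = 81)
    vals <- outer(g0, g1, Vectorize(ll))
    idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    b <- c(g0[idx[1]], g1[idx[2]])
    # the likelihood is concave, so the optimum sits within one grid cell
    # of the argmax; shrink the window to a few cells around it
    width <- width / 10
  }
  b
}

# nonparametric bootstrap variance of the risk-oriented AUC
bootstrap_auc_var <- function(y, s, n_boot = 10000, seed = 1) {
  withr::with_seed(seed, {
    cases <- s[y]
    controls <- s[!y]
    aucs <- replicate(n_boot, {
      a <- sample(cases, replace = TRUE)
      b <- sample(controls, replace = TRUE)
      r <- rank(c(a, b))
      m <- length(a)
      (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(b))
    })
    var(aucs)
  })
}

# small fast phantom used throughout
small_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    levels = "L2", body_extent_mm = c(26, 22, 20), shell_thickness_mm = 3,
    trabecular_density = 100, cortical_density = 400,
    posterior_density = 300, background_density = 30,
    noise_sd = 0, spacing_mm = c(1, 1, 1), seed = 1L
  )
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

identity_config <- function() {
  list(
    scanners = list(synthetic = calibration_model("synthetic", 1, 0)),
    contrast = list(
      arterial = contrast_correction("arterial", 0.88, -6),
      portal_venous = contrast_correction("portal_venous", 0.92, -9)
    )
  )
}
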