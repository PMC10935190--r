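test_that("wavelength grid grows linearly between the stated step sizes", {
  g <- makeWavelengthGrid(1350, 2550, 2.5, 8.8)
  expect_equal(length(g), 213L)
  expect_equal(g[1], 1350)
  expect_lte(max(g), 2550)
  d <- diff(g)
  expect_equal(d[1], 2.5)
  expect_equal(d[length(d)], 8.8, tolerance = 1e-6)
  expect_true(all(diff(d) > 0))          # strictly widening steps
  expect_true(!is.unsorted(g, strictly = TRUE))

  expect_equal(makeWavelengthGrid(0, 10, 1, 1), 0:10)
  g5 <- makeWavelengthGrid(1350, 2550, 5, 5)
  expect_equal(length(g5), 241L)
  expect_equal(unique(round(diff(g5), 9)), 5)

  expect_error(makeWavelengthGrid(1350, 2550, 0, 5), "step")
  expect_error(makeWavelengthGrid(1350, 2550, -1, 5), "step")
  expect_error(makeWavelengthGrid(2550, 1350, 2.5, 8.8), "start")
})

test_that("season sampling follows the quadratic curve and its noise model", {
  # degenerate season: every plant at WP 70, no noise anywhere
  cfg <- seasonConfig("x", 12L, wp_mean = 70, wp_sd = 0,
                      wp_min = 69, wp_max = 71,
                      em_residual_sd = 0, sel = 0)
  s <- sampleSeason(cfg, seed = 5)
  expect_equal(s$em_true, rep(58.7, 12), tolerance = 1e-12)
  expect_equal(s$em_oven, s$em_true)

  # determinism under a fixed seed
  cfg2 <- small_season()
  expect_identical(sampleSeason(cfg2, seed = 11),
                   sampleSeason(cfg2, seed = 11))

  # truncation bounds are hard
  wide <- seasonConfig("w", 2000L, wp_mean = 60, wp_sd = 25,
                       wp_min = 50, wp_max = 70)
  sw <- sampleSeason(wide, seed = 3)
  expect_true(all(sw$wp_true >= 50 & sw$wp_true <= 70))

  # calibration-season preset reproduces the ear-moisture spread
  big <- season2021()
  big@n_plants <- 10000L
  sb <- sampleSeason(big, seed = 42)
  expect_lt(abs(sd(sb$em_true) - 9.6) / 9.6, 0.05)
  expect_lt(abs(mean(sb$em_true) - 49), 1.5)
})

test_that("rendered spectra respond to moisture as constructed", {
  grid <- makeWavelengthGrid()
  scene <- noiseless_scene()
  prof <- instrumentProfile("1", noise_sd = 0)

  r1 <- renderSpectrum(55, scene, prof, grid)
  r2 <- renderSpectrum(55, scene, prof, grid)
  expect_identical(r1, r2)
  expect_true(all(r1 > 0 & r1 <= 1))

  # with dry bands silenced and em near saturation, absorbance peaks at the
  # strongest water band center
  wet <- sceneConfig(dry_amplitudes = c(0, 0, 0), baseline_slope = 0,
                     scatter_mult_sd = 0, scatter_add_sd = 0)
  a <- log10(1 / renderSpectrum(99.9, wet, prof, grid))
  expect_equal(grid[which.max(a)], grid[which.min(abs(grid - 1950))])

  # absorbance at the 1950 nm band center rises monotonically with moisture
  i1950 <- which.min(abs(grid - 1950))
  a1950 <- vapply(seq(30, 80, by = 5), function(em) {
    log10(1 / renderSpectrum(em, scene, prof, grid))[i1950]
  }, numeric(1))
  expect_true(all(diff(a1950) > 0))

  expect_error(renderSpectrum(0, scene, prof, grid), "moisture")
  expect_error(renderSpectrum(120, scene, prof, grid), "moisture")
})

test_that("campaigns have the full crossed design and are reproducible", {
  cfg <- small_season(n = 4L, reps = 3L)
  profs <- identity_profiles(3L)
  camp <- simulateCampaign(list(cfg), profs, noiseless_scene(), seed = 2L)
  expect_equal(ncol(camp$spectra), 4L * 3L * 3L)

  one <- simulateCampaign(
    list(small_season(n = 1L, reps = 1L)),
    identity_profiles(1L), noiseless_scene(), seed = 2L)
  expect_equal(ncol(one$spectra), 1L)

  expect_error(
    simulateCampaign(list(cfg), list(instrumentProfile("1"),
                                     instrumentProfile("1")),
                     seed = 1L),
    "duplicate")

  # bit-reproducible under a fixed seed
  again <- simulateCampaign(list(cfg), profs, noiseless_scene(), seed = 2L)
  expect_identical(
    SummarizedExperiment::assay(camp$spectra, "signal"),
    SummarizedExperiment::assay(again$spectra, "signal"))

  # identity instruments, noise off: a given ear is identical on every
  # instrument, and replicates are identical too
  m <- spectraMatrix(camp$spectra)
  info <- scanInfo(camp$spectra)
  rows <- split(seq_len(nrow(m)), info$ear_id)
  for (idx in rows)
    expect_lt(max(abs(sweep(m[idx, ], 2, m[idx[1], ]))), 1e-14)
})

test_that("replicate averaging shrinks noise like the square root of n", {
  cfg <- small_season(n = 200L, reps = 3L, em_residual_sd = 0, sel = 0)
  prof <- list(instrumentProfile("1", noise_sd = 0.01))
  camp <- simulateCampaign(list(cfg), prof, noiseless_scene(), seed = 9L)
  # work in absorbance, where instrument noise is additive Gaussian
  A <- spectraMatrix(toAbsorbance(camp$spectra))
  info <- scanInfo(camp$spectra)
  # noiseless re-render of the same ears gives the true signal
  clean <- simulateCampaign(list(cfg), identity_profiles(1L),
                            noiseless_scene(), seed = 9L)
  A0 <- spectraMatrix(toAbsorbance(clean$spectra))
  scan_sd <- sd(A - A0)
  expect_equal(scan_sd, 0.01, tolerance = 0.03)
  A_avg <- spectraMatrix(averageReplicates(toAbsorbance(camp$spectra),
                                           "ear_instrument"))
  A0_avg <- spectraMatrix(averageReplicates(toAbsorbance(clean$spectra),
                                            "ear_instrument"))
  expect_equal(sd(A_avg - A0_avg) / scan_sd, 1 / sqrt(3),
               tolerance = 0.02)
})

test_that("noise-free spectra are exactly affine in moisture", {
  cfg <- small_season(n = 30L, reps = 1L, em_residual_sd = 0, sel = 0)
  camp <- simulateCampaign(list(cfg), identity_profiles(1L),
                           noiseless_scene(), seed = 4L)
  abs_set <- toAbsorbance(camp$spectra)
  A <- spectraMatrix(abs_set)
  em <- camp$truth$em_true
  # every column is an affine function of em
  for (j in c(1L, 50L, 150L)) {
    fit <- lm(A[, j] ~ em)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
  # hence a 1-LV PLS recovers moisture essentially exactly
  core <- fitPLS(A, em, maxLV = 1L)
  pred <- drop(sweep(A, 2, core$xMean) %*% core$B[, 1]) + core$yMean
  expect_lt(rmse(pred, em), 1e-8)
})
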