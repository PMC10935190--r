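test_that("autoscaling uses the sample SD and is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  s <- autoscale(X)
  expect_equal(unname(s$X[, 1]), c(-1, 0, 1))
  expect_equal(unname(s$center), c(2, 4))
  expect_equal(unname(s$scale), c(1, 2))
  again <- autoscale(s$X)
  expect_lt(max(abs(again$X - s$X)), 1e-10)

  Xc <- cbind(`1400.0` = c(1, 2, 3), `1500.0` = c(5, 5, 5))
  expect_error(autoscale(Xc), "1500.0")
  expect_error(autoscale(X[1, , drop = FALSE]), "2 rows")
})

test_that("MSC removes affine scatter relative to the reference", {
  set.seed(21)
  wl <- seq_len(60)
  ref <- 0.5 + 0.3 * sin(wl / 8) + 0.1 * cos(wl / 3)
  X <- rbind(2 * ref + 3,       # pure affine distortion
             ref,               # the reference itself
             1.3 * ref - 0.2)
  out <- msc(X, reference = ref)$X
  expect_equal(unname(out[1, ]), ref, tolerance = 1e-10)
  expect_equal(unname(out[2, ]), ref, tolerance = 1e-10)

  # after correction every row regresses on the reference with slope 1,
  # intercept 0
  Xr <- t(replicate(8, ref * (1 + rnorm(1, 0, 0.2)) + rnorm(1, 0, 0.1) +
                      rnorm(60, 0, 0.01)))
  corr <- msc(Xr, reference = ref)$X
  for (i in seq_len(nrow(corr))) {
    fit <- lm(corr[i, ] ~ ref)
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-8)
  }

  # idempotence against the same reference
  twice <- msc(corr, reference = ref)$X
  expect_lt(max(abs(twice - corr)), 1e-10)

  expect_error(msc(Xr, reference = rep(1, 60)), "zero-variance")
})

test_that("SG derivatives are exact on polynomials and near-exact on sines", {
  i <- 1:80
  X2 <- matrix(i^2, 1)
  d2 <- sgDerivative(X2, window = 11, poly_order = 2, derivative_order = 2)
  expect_equal(as.numeric(d2)[6:75], rep(2, 70), tolerance = 1e-9)

  X1 <- matrix(3 * i + 1, 1)
  for (w in c(9, 15, 27))
    expect_equal(
      as.numeric(sgDerivative(X1, w, 2, 1))[15:60], rep(3, 46),
      tolerance = 1e-9)

  # second derivative of a sine tracks a central finite-difference oracle
  y <- sin(i / 8)
  d <- as.numeric(sgDerivative(matrix(y, 1), 11, 3, 2))
  fd <- (y[1:78] - 2 * y[2:79] + y[3:80])          # h = 1
  expect_lt(max(abs(d[10:70] - fd[9:69])), 1e-3)

  # derivative order 0 is smoothing: constants pass through unchanged
  cst <- matrix(5, 1, 40)
  expect_equal(sgDerivative(cst, 11, 2, 0), cst)

  expect_error(sgDerivative(matrix(1, 1, 5), 11, 2, 2), "exceeds")
  expect_error(preprocessSpec("sg_derivative", window = 10), "odd")
  expect_error(preprocessSpec("sg_derivative", derivative_order = 3,
                              poly_order = 2), "derivative_order")
})

test_that("pretreatment shorthand parses and formats symmetrically", {
  sp <- parsePretreatment("D-2,2,11")
  expect_equal(sp@method, "sg_derivative")
  expect_equal(sp@derivative_order, 2L)
  expect_equal(sp@poly_order, 2L)
  expect_equal(sp@window, 11L)
  expect_equal(formatPretreatment(sp), "D-2,2,11")
  expect_equal(formatPretreatment(parsePretreatment("msc")), "msc")
  expect_error(parsePretreatment("D-2,2"), "parse")
})

test_that("pretreatments are train/apply separable", {
  set.seed(8)
  Xtr <- matrix(rnorm(300, 10), 15, 20)
  Xte <- matrix(rnorm(100, 10), 5, 20)
  for (m in c("autoscale", "mean_center", "msc")) {
    fit <- fitPretreatment(Xtr, preprocessSpec(m))
    a <- applyPretreatment(fit, Xte)
    b <- applyPretreatment(fit, Xte[c(2, 1, 3:5), ])[c(2, 1, 3:5), ]
    expect_equal(a, b)   # no dependence on the batch being transformed
  }
  # autoscale statistics come from the training rows only
  fit <- fitPretreatment(Xtr, preprocessSpec("autoscale"))
  expect_equal(applyPretreatment(fit, Xtr[3, , drop = FALSE]),
               (Xtr[3, , drop = FALSE] -
                  matrix(colMeans(Xtr), 1)) / matrix(apply(Xtr, 2, sd), 1))
})

test_that("the survey grid enumerates 43 candidates and ranks sensibly", {
  survey <- defaultPretreatmentSurvey()
  expect_length(survey, 43L)
  expect_equal(sum(vapply(survey, function(s) s@method, "") ==
                     "sg_derivative"), 40L)

  # noiseless affine data: plain and derivative candidates all succeed
  cfg <- small_season(n = 40L, reps = 1L, em_residual_sd = 0, sel = 0)
  camp <- simulateCampaign(list(cfg), identity_profiles(1L),
                           noiseless_scene(), seed = 6L)
  A <- spectraMatrix(toAbsorbance(camp$spectra))[, seq(1, 213, by = 4)]
  em <- camp$truth$em_true
  cands <- list(preprocessSpec("none"),
                preprocessSpec("sg_derivative", 2, 11, 2),
                preprocessSpec("sg_derivative", 1, 9, 2))
  tab <- suppressWarnings(optimizePreprocessing(A, em, cands, maxLV = 4L))
  expect_equal(nrow(tab), 3L)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$rmsecv < 1e-6))

  # a failing candidate is recorded without aborting the survey
  small <- A[, 1:9]
  tab2 <- suppressWarnings(optimizePreprocessing(
    small, em,
    list(preprocessSpec("none"), preprocessSpec("sg_derivative", 2, 11, 2)),
    maxLV = 3L))
  expect_equal(sum(!is.na(tab2$error)), 1L)
  expect_true(any(is.na(tab2$error)))
})

test_that("scatter correction pays off once scatter dominates", {
  survey_at <- function(mult_sd) {
    cfg <- seasonConfig("t", 120L, 63.5, 7.3, 42, 79,
                        em_residual_sd = 0, sel = 0, n_replicates = 1L)
    scene <- sceneConfig(scatter_mult_sd = mult_sd, scatter_add_sd = 0.05)
    camp <- simulateCampaign(list(cfg),
                             list(instrumentProfile("1", noise_sd = 0.01)),
                             scene, seed = 13L)
    A <- spectraMatrix(toAbsorbance(camp$spectra))
    cands <- list(preprocessSpec("none"), preprocessSpec("msc"),
                  preprocessSpec("sg_derivative", 2, 11, 2))
    suppressWarnings(
      optimizePreprocessing(A, camp$truth$em_true, cands, maxLV = 8L))
  }
  lo <- survey_at(0.02)
  hi <- survey_at(0.15)
  err_of <- function(tab, m) tab$rmsecv[tab$pretreatment == m]
  # MSC is nearly immune to multiplicative scatter; the raw model degrades
  expect_lt(err_of(hi, "msc") / err_of(lo, "msc"), 2.5)
  expect_gt(err_of(hi, "none") / err_of(lo, "none"), 2.5)
  # and under heavy scatter a scatter-corrective candidate ranks first
  expect_true(hi$pretreatment[1] %in% c("msc", "D-2,2,11"))
  expect_gt(err_of(hi, "none"), min(err_of(hi, "msc"),
                                    err_of(hi, "D-2,2,11")))
})
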