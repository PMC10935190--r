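test_that("venetian blinds assign every k-th row to the same split", {
  s <- venetianBlindsSplits(20, 10, 1)
  expect_length(s, 10L)
  expect_equal(s[[1]], c(1L, 11L))
  expect_equal(s[[10]], c(10L, 20L))

  singletons <- venetianBlindsSplits(10, 10, 1)
  expect_true(all(lengths(singletons) == 1L))
  expect_setequal(unlist(singletons), 1:10)

  thick <- venetianBlindsSplits(12, 3, 2)
  expect_equal(thick[[1]], c(1L, 2L, 7L, 8L))
  expect_setequal(unlist(thick), 1:12)
  expect_equal(sum(lengths(thick)), 12L)   # disjoint and exhaustive

  expect_error(venetianBlindsSplits(5, 10, 1), ">=")
})

test_that("PLS matches an OLS oracle at full rank", {
  set.seed(31)
  for (rep in 1:4) {
    X <- matrix(rnorm(30 * 8), 30, 8)
    y <- drop(X %*% rnorm(8)) + rnorm(30, 0, 0.3)
    core <- fitPLS(X, y, maxLV = 8L)
    pls_pred <- drop(sweep(X, 2, core$xMean) %*% core$B[, 8]) + core$yMean
    ols <- lm(y ~ X)
    expect_lt(max(abs(pls_pred - fitted(ols))), 1e-6)
  }
})

test_that("PLS is deterministic, order-invariant and orthogonal in scores", {
  set.seed(32)
  X <- matrix(rnorm(40 * 25), 40, 25)
  y <- drop(X[, 1:5] %*% runif(5)) + rnorm(40, 0, 0.1)
  core <- fitPLS(X, y, maxLV = 6L)
  perm <- sample(40)
  core_p <- fitPLS(X[perm, ], y[perm], maxLV = 6L)
  expect_lt(max(abs(core$B - core_p$B)), 1e-10)

  G <- crossprod(core$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  # single spectral direction, noise-free: one LV suffices
  v <- rnorm(25)
  X1 <- outer(rnorm(30), v)
  y1 <- X1 %*% v / sum(v^2)
  expect_warning(c1 <- fitPLS(X1, drop(y1), maxLV = 3L),
                 "rank")
  p1 <- drop(sweep(X1, 2, c1$xMean) %*% c1$B[, 1]) + c1$yMean
  expect_lt(rmse(p1, drop(y1)), 1e-8)
})

test_that("NIPALS agrees with a SIMPLS oracle at every LV count", {
  # independent single-response SIMPLS (projected-covariance form)
  simpls <- function(X, y, A) {
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm); yc <- y - ym
    s <- drop(crossprod(Xc, yc))
    R <- matrix(0, ncol(X), A); V <- matrix(0, ncol(X), A)
    B <- matrix(0, ncol(X), A); q <- numeric(A)
    for (a in seq_len(A)) {
      r <- s / sqrt(sum((Xc %*% s)^2))   # scale so the score has unit norm
      t <- drop(Xc %*% r)
      p <- drop(crossprod(Xc, t))
      v <- p
      if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
          crossprod(V[, 1:(a - 1), drop = FALSE], p)
      v <- v / sqrt(sum(v^2))
      s <- s - v * sum(v * s)
      R[, a] <- r; V[, a] <- v; q[a] <- sum(yc * t)
      B[, a] <- R[, 1:a, drop = FALSE] %*% q[1:a]
    }
    list(xm = xm, ym = ym, B = B)
  }
  set.seed(35)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- drop(X[, 1:4] %*% runif(4)) + rnorm(25, 0, 0.2)
  core <- fitPLS(X, y, maxLV = 5L)
  orc <- simpls(X, y, 5L)
  for (k in 1:5) {
    p_nip <- drop(sweep(X, 2, core$xMean) %*% core$B[, k]) + core$yMean
    p_sim <- drop(sweep(X, 2, orc$xm) %*% orc$B[, k]) + orc$ym
    expect_lt(max(abs(p_nip - p_sim)), 1e-6)
  }
})

test_that("RMSEC decreases with latent variables from the 0-LV baseline", {
  set.seed(33)
  X <- matrix(rnorm(35 * 15), 35, 15)
  y <- drop(X %*% rnorm(15)) + rnorm(35)
  core <- fitPLS(X, y, maxLV = 10L)
  rmsec <- vapply(0:core$maxLV, function(k) {
    pred <- if (k == 0) rep(core$yMean, 35) else
      drop(sweep(X, 2, core$xMean) %*% core$B[, k]) + core$yMean
    rmse(pred, y)
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
  # the 0-LV model predicts the mean, with RMSE = SD(y) * sqrt((n-1)/n)
  expect_equal(rmsec[1], sd(y) * sqrt(34 / 35))
})

test_that("cross-validation pools held-out predictions per LV", {
  set.seed(34)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(12, 0, 0.2)
  cv <- cvScheme(n_splits = 4L)
  res <- crossValidate(X, y, preprocessSpec("none"), cv, maxLV = 3L)

  # hand-rolled oracle: same splits, refit, pool
  pred <- numeric(12)
  for (held in venetianBlindsSplits(12, 4, 1)) {
    tr <- setdiff(1:12, held)
    core <- fitPLS(X[tr, ], y[tr], maxLV = 1L)
    pred[held] <- drop(sweep(X[held, , drop = FALSE], 2,
                             core$xMean) %*% core$B[, 1]) + core$yMean
  }
  expect_equal(res$table$rmsecv[1], rmse(pred, y), tolerance = 1e-12)

  # duplicated rows with thickness 1: every held-out row has its twin in
  # training, so RMSECV cannot exceed RMSEC
  X2 <- X[rep(1:12, each = 2), ]
  y2 <- y[rep(1:12, each = 2)]
  core2 <- fitPLS(X2, y2, maxLV = 3L)
  rmsec2 <- rmse(drop(sweep(X2, 2, core2$xMean) %*% core2$B[, 3]) +
                   core2$yMean, y2)
  res2 <- crossValidate(X2, y2, preprocessSpec("none"),
                        cvScheme(n_splits = 2L), maxLV = 3L)
  expect_lte(res2$table$rmsecv[3], rmsec2 + 1e-6)

  # noiseless 1-LV structure cross-validates to ~0 error
  v <- rnorm(6)
  Xn <- outer(seq(1, 4, length.out = 12), v)
  yn <- drop(Xn %*% v)
  resn <- crossValidate(Xn, yn, preprocessSpec("none"), cvScheme(4L), 1L)
  expect_lt(resn$table$rmsecv[1], 1e-6)
})

test_that("latent-variable selection takes the first honest local minimum", {
  rmsec <- c(4, 3, 2.8, 1.8, 1)
  expect_equal(selectNumLV(rmsec, c(5, 4, 3, 3.5, 2)), 3L)
  # strictly decreasing curve: global-minimum fallback picks the end
  expect_equal(selectNumLV(c(5, 4, 3, 2, 1) * 0.9, c(5, 4, 3, 2, 1)), 5L)
  # a divergent local minimum is skipped
  expect_equal(selectNumLV(c(5, 4, 1.5, 1.7, 1.9),
                           c(5, 4, 3, 3.5, 2),
                           divergence_ratio_max = 1.25),
               5L)
  # first position can qualify
  expect_equal(selectNumLV(c(2, 2, 2), c(1, 2, 3)), 1L)
  # nothing satisfies the guard: minimal-ratio fallback with a warning
  expect_warning(k <- selectNumLV(c(1, 1, 1), c(2, 1.9, 1.8),
                                  divergence_ratio_max = 1.25))
  expect_equal(k, 3L)
  expect_error(selectNumLV(numeric(0), numeric(0)), "empty")
})

test_that("fitCalibration recovers moisture on the default campaign", {
  f <- default_fits()
  m <- f$m_all
  expect_gte(m@nLV, 1L)
  expect_lte(m@nLV, 12L)
  r2c <- rSquared(predict(m, f$cal_avg), f$y)
  expect_gte(r2c, 0.85)
  # grid fingerprint is enforced
  expect_error(predict(m, matrix(0, 2, 10)), "fingerprint")
})

test_that("models survive JSON serialization", {
  f <- default_fits()
  js <- modelToJSON(f$m_all)
  back <- modelFromJSON(js)
  expect_equal(back@nLV, f$m_all@nLV)
  expect_equal(predict(back, f$cal_avg), predict(f$m_all, f$cal_avg),
               tolerance = 1e-12)
})
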