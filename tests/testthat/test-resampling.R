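test_that("iid bootstrap resamples whole columns, reproducibly", {
  y <- rstd(3, 20, seed = 51)
  b1 <- iidBootstrap(y, seed = 9)
  b2 <- iidBootstrap(y, seed = 9)
  expect_identical(values(b1), values(b2))
  expect_true(isStandardized(b1))

  # raw draws (no re-standardization) are exact columns of the source
  raw <- iidBootstrap(values(y), seed = 10, restandardize = FALSE)
  for (j in seq_len(ncol(raw))) {
    match <- apply(values(y), 2, function(col) max(abs(col - raw[, j])))
    expect_equal(min(match), 0)
  }

  # T = 2: both columns drawn, each resample one of the 4 equally likely pairs
  m <- matrix(c(1, 2, 10, 20), 2, 2)
  seen <- replicate(200, paste(iidBootstrap(m, restandardize = FALSE)[1, ], collapse = ","))
  expect_setequal(unique(seen), c("1,1", "1,10", "10,1", "10,10"))

  # uniform column frequencies over many draws of a 3-column matrix
  m3 <- matrix(rnorm(9), 3, 3)
  set.seed(13)
  counts <- table(replicate(10000, iidBootstrap(m3, restandardize = FALSE)[1, 1]))
  p <- as.numeric(counts) / 10000
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(p - 1 / 3) < 3 * se + 1e-9))
})

test_that("Yule-Walker fits recover AR structure", {
  # white noise: coefficients near zero
  y <- rstd(4, 1000, seed = 61)
  fit <- fitARYuleWalker(y, 2)
  expect_lt(max(abs(fit@coefficients)), 3 / sqrt(1000))
  expect_equal(ncol(fit@residuals), 998L)

  # AR(1) with phi = 0.5 at T = 5000
  ya <- rar1(2, 5000, 0.5, seed = 62)
  f1 <- fitARYuleWalker(ya, 1)
  expect_true(all(abs(f1@coefficients[, 1] - 0.5) < 0.05))

  # s = 1 closed form: phi-hat equals the lag-1 autocorrelation exactly
  v <- values(y)
  r1 <- vapply(seq_len(4), function(i) lag1Autocor(v[i, ]), 0)
  expect_equal(unname(fitARYuleWalker(y, 1)@coefficients[, 1]), r1, tolerance = 1e-12)

  # cross-check against the standard Yule-Walker implementation
  ref <- stats::ar.yw(v[1, ], aic = FALSE, order.max = 2, demean = FALSE)
  expect_equal(unname(fit@coefficients[1, ]), unname(ref$ar), tolerance = 1e-8)

  # residual identity: eps_j = y_j - phi y_{j-1}
  f <- fitARYuleWalker(y, 1)
  expect_equal(f@residuals,
               v[, 2:1000] - f@coefficients[, 1] * v[, 1:999], tolerance = 1e-12)
})

test_that("sieve bootstrap with s = 0 is the iid bootstrap, bit for bit", {
  y <- rstd(3, 40, seed = 71)
  fit0 <- fitARYuleWalker(y, 0)
  a <- sieveBootstrap(y, fit0, seed = 5)
  b <- iidBootstrap(y, seed = 5)
  expect_identical(values(a), values(b))
})

test_that("sieve bootstrap preserves temporal and cross-node dependence", {
  Sigma <- matrix(c(1, 0.7, 0.7, 1), 2)
  y <- rar1(2, 600, 0.6, seed = 72, Sigma = Sigma)
  fit <- fitARYuleWalker(y, 1)
  acs <- numeric(100); ccs <- numeric(100)
  set.seed(73)
  for (b in 1:100) {
    yb <- values(sieveBootstrap(y, fit))
    acs[b] <- mean(c(lag1Autocor(yb[1, ]), lag1Autocor(yb[2, ])))
    ccs[b] <- cor(yb[1, ], yb[2, ])
  }
  obsAc <- mean(c(lag1Autocor(values(y)[1, ]), lag1Autocor(values(y)[2, ])))
  obsCc <- cor(values(y)[1, ], values(y)[2, ])
  expect_lt(abs(mean(acs) - obsAc), 0.06)
  expect_lt(abs(mean(ccs) - obsCc), 0.06)
  # standardized output contract for both modes
  expect_lt(max(abs(rowMeans(values(sieveBootstrap(y, fit, seed = 1))))), 1e-10)
  expect_lt(max(abs(rowMeans(values(iidBootstrap(y, seed = 1))^2) - 1)), 1e-10)
})

test_that("Durbin-Watson diagnostic behaves classically", {
  y <- rstd(4, 500, seed = 81)
  dw <- durbinWatson(y, nperm = 499, seed = 1)
  expect_true(all(abs(dw$statistic - 2) < 0.3))
  expect_gt(dw$p.value, 0.05)

  # time reversal leaves the statistic unchanged
  yr <- standardizeRows(values(y)[, 500:1])
  expect_equal(unname(durbinWatson(yr, nperm = 9, seed = 1)$statistic),
               unname(dw$statistic), tolerance = 1e-12)

  ya <- rar1(4, 500, 0.8, seed = 82)
  dwa <- durbinWatson(ya, nperm = 499, seed = 2)
  expect_true(all(dwa$statistic < 2))
  expect_lt(dwa$p.value, 0.05)

  expect_error(durbinWatson(rstd(2, 8, seed = 1)), "T >= 10")
})

test_that("cross-validated AR order selection picks the generating order", {
  pick <- function(gen, maxOrder = 3) {
    vapply(1:8, function(s) selectAROrder(gen(s), maxOrder), 0L)
  }
  white <- pick(function(s) rstd(4, 400, seed = 100 + s))
  expect_gte(sum(white == 0L), 6)

  ar1 <- pick(function(s) rar1(4, 400, 0.6, seed = 200 + s))
  expect_gte(sum(ar1 == 1L), 6)

  # AR(2) with both lags strong
  gen2 <- function(s) {
    set.seed(300 + s)
    x <- matrix(0, 3, 500)
    e <- matrix(rnorm(3 * 500), 3, 500)
    x[, 1:2] <- e[, 1:2]
    for (j in 3:500) x[, j] <- 0.5 * x[, j - 1] + 0.35 * x[, j - 2] + e[, j]
    standardizeRows(x[, 101:500])
  }
  ar2 <- pick(gen2)
  expect_gt(sum(ar2 == 2L), max(sum(ar2 == 0L), sum(ar2 == 1L)))
})

test_that("bootstrap null distribution tracks the sampling distribution of d(k)", {
  # conditional (one dataset) bootstrap law of d(T/2) vs fresh H0 draws:
  # close but not identical at finite T; require the median KS p-value over
  # five seeded datasets to clear 0.01
  n <- 5; T <- 100; k <- 50
  dmid <- function(y) frobeniusDistance(segmentCovariance(y, 1, k),
                                        segmentCovariance(y, k + 1, T))
  kp <- vapply(1:5, function(s) {
    set.seed(s)
    fresh <- replicate(400, dmid(standardizeRows(matrix(rnorm(n * T), n, T))))
    y0 <- standardizeRows(matrix(rnorm(n * T), n, T))
    boot <- replicate(400, dmid(iidBootstrap(y0)))
    suppressWarnings(stats::ks.test(fresh, boot)$p.value)
  }, 0)
  expect_gt(median(kp), 0.01)
})

test_that("bootstrapConfig validates its fields", {
  expect_warning(bootstrapConfig(B = 50), "coarse")
  cfg <- bootstrapConfig(B = 200, mode = "sieve", arOrder = 2, seed = 7)
  expect_equal(cfg@arOrder, 2L)
  expect_equal(bootstrapConfig(B = 200, mode = "iid", arOrder = 5)@arOrder, 0L)
  expect_error(bootstrapConfig(B = 0), "positive")
})
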