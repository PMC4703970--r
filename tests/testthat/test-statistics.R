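test_that("frobeniusDistance is the squared Frobenius norm of the difference", {
  expect_equal(frobeniusDistance(diag(2), matrix(0, 2, 2)), 2)
  S <- covMatrix(segmentCovariance(rstd(6, 50, seed = 2), 1, 25))
  expect_equal(frobeniusDistance(S, S), 0)

  set.seed(4)
  A <- matrix(rnorm(36), 6); A <- (A + t(A)) / 2
  B <- matrix(rnorm(36), 6); B <- (B + t(B)) / 2
  brute <- 0
  for (i in 1:6) for (j in 1:6) brute <- brute + (A[i, j] - B[i, j])^2
  expect_equal(frobeniusDistance(A, B), brute, tolerance = 1e-12)
  expect_equal(frobeniusDistance(B, A), frobeniusDistance(A, B))
  expect_error(frobeniusDistance(diag(3), diag(4)), "mismatch")
})

test_that("maximumDistance takes the largest absolute entry, diagonal included", {
  D <- matrix(0, 3, 3); D[2, 2] <- -0.7
  expect_equal(maximumDistance(D, matrix(0, 3, 3)), 0.7)
  set.seed(5)
  A <- matrix(rnorm(25), 5); A <- (A + t(A)) / 2
  B <- matrix(rnorm(25), 5); B <- (B + t(B)) / 2
  expect_equal(maximumDistance(A, B), max(abs(A - B)), tolerance = 1e-12)
  expect_equal(maximumDistance(A, A), 0)
  # sum of squares dominates its largest term
  expect_gte(frobeniusDistance(A, B), maximumDistance(A, B)^2)
})

test_that("vech stacks the strict lower triangle column-major and round-trips", {
  expect_equal(vech(matrix(c(1, 2, 2, 3), 2)), 2)
  M <- matrix(0, 3, 3)
  M[2, 1] <- M[1, 2] <- 21
  M[3, 1] <- M[1, 3] <- 31
  M[3, 2] <- M[2, 3] <- 32
  expect_equal(vech(M), c(21, 31, 32))

  set.seed(6)
  S <- matrix(rnorm(49), 7); S <- S + t(S); diag(S) <- 0
  expect_identical(unvech(vech(S)), S)
  expect_length(vech(S), 21L)

  bad <- matrix(rnorm(9), 3)
  expect_error(vech(bad), "symmetric")
})

test_that("lrtDistance reduces to the scalar variance LRT and a determinant oracle", {
  # scalar series, centered by hand (plain matrices skip the class n >= 2 floor)
  y <- c(1.2, -0.4, 0.7, -1.1, 0.3, -0.7)
  y <- y - mean(y)
  m <- matrix(y, 1, 6)
  k <- 3
  s2 <- function(x) mean(x^2)
  hand <- 6 * log(s2(y)) - 3 * log(s2(y[1:3])) - 3 * log(s2(y[4:6]))
  expect_equal(lrtDistance(m, k), hand, tolerance = 1e-12)

  # determinant oracle on a 3 x 60 series
  ys <- rstd(3, 60, seed = 31)
  v <- values(ys)
  oracle <- 60 * determinant(bruteSegCov(v, 1, 60))$modulus -
    30 * determinant(bruteSegCov(v, 1, 30))$modulus -
    30 * determinant(bruteSegCov(v, 31, 60))$modulus
  expect_equal(lrtDistance(ys, 30), as.numeric(oracle), tolerance = 1e-10)

  # equality case: both segments from one covariance -> near zero, nonnegative
  yb <- rstd(3, 400, seed = 32)
  val <- lrtDistance(yb, 200)
  expect_gte(val, -1e-8)
  expect_lt(val, 25)

  # swapping equal-length segments (time reversal) leaves the value unchanged
  yr <- standardizeRows(values(ys)[, 60:1])
  expect_equal(lrtDistance(yr, 30), lrtDistance(ys, 30), tolerance = 1e-8)
})

test_that("quadformStatistic matches a hand-summed cumulative vech oracle", {
  y <- rstd(2, 8, seed = 7)
  v <- values(y)
  T <- 8; k <- 3
  w <- v[1, ] * v[2, ]                 # the single strict-vech entry per column
  vk <- (sum(w[1:k]) - (k / T) * sum(w)) / sqrt(T)
  sig <- mean((w - mean(w))^2) + 1e-8
  expect_equal(quadformStatistic(y, k), vk^2 / sig, tolerance = 1e-10)

  # omnibus variant equals the sum of per-k values
  total <- sum(vapply(1:(T - 1), function(kk) quadformStatistic(y, kk), 0))
  expect_equal(quadformSum(y), total, tolerance = 1e-10)
})

test_that("all four statistics are invariant under node relabeling", {
  y <- rstd(5, 80, seed = 41)
  perm <- c(3, 5, 1, 4, 2)
  yp <- standardizeRows(values(y)[perm, ])
  k <- 40
  S1 <- segmentCovariance(y, 1, k);  S2 <- segmentCovariance(y, k + 1, 80)
  P1 <- segmentCovariance(yp, 1, k); P2 <- segmentCovariance(yp, k + 1, 80)
  expect_equal(frobeniusDistance(P1, P2), frobeniusDistance(S1, S2), tolerance = 1e-10)
  expect_equal(maximumDistance(P1, P2), maximumDistance(S1, S2), tolerance = 1e-10)
  expect_equal(lrtDistance(yp, k), lrtDistance(y, k), tolerance = 1e-8)
  expect_equal(quadformStatistic(yp, k), quadformStatistic(y, k), tolerance = 1e-6)
})
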