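test_that("standardizeRows centers and scales with the population convention", {
  y <- standardizeRows(matrix(c(1, 2, 3, 4, 5, 5, 8, 9), 2, 4, byrow = TRUE))
  # (x - mean)/sd with the population sd: sd(1:4) = sqrt(5/4)
  expect_equal(values(y)[1, ], c(-1.5, -0.5, 0.5, 1.5) / sqrt(1.25), tolerance = 1e-12)
  expect_true(isStandardized(y))

  # idempotence
  y2 <- standardizeRows(values(y))
  expect_equal(values(y2), values(y), tolerance = 1e-12)

  # moments across many random rows
  set.seed(1)
  big <- standardizeRows(matrix(rnorm(100 * 30), 100, 30))
  expect_lt(max(abs(rowMeans(values(big)))), 1e-10)
  expect_lt(max(abs(rowMeans(values(big)^2) - 1)), 1e-10)
})

test_that("standardizeRows rejects degenerate input with informative errors", {
  m <- matrix(rnorm(20), 4, 5)
  m[3, ] <- 7
  expect_error(standardizeRows(m), "node3")
  m2 <- matrix(rnorm(20), 4, 5)
  m2[2, 4] <- NaN
  expect_error(standardizeRows(m2), "missing")
  expect_error(standardizeRows(matrix(rnorm(6), 2, 3)), "4 time points")
})

test_that("segmentCovariance matches its definition and a brute-force oracle", {
  y <- rstd(5, 40, seed = 11)
  v <- values(y)

  full <- segmentCovariance(y, 1, 40)
  expect_equal(unname(diag(covMatrix(full))), rep(1, 5), tolerance = 1e-10)
  expect_equal(segmentRange(full), c(start = 1, end = 40))

  sub <- segmentCovariance(y, 10, 30)
  expect_equal(covMatrix(sub), bruteSegCov(v, 10, 30), tolerance = 1e-12)

  # additivity of the unnormalized cross-product at any split
  for (k in c(7, 20, 33)) {
    lhs <- k * covMatrix(segmentCovariance(y, 1, k)) +
      (40 - k) * covMatrix(segmentCovariance(y, k + 1, 40))
    expect_equal(lhs, 40 * covMatrix(full), tolerance = 1e-10)
  }

  # two identical rows give perfect correlation
  m <- matrix(rnorm(30), 3, 10)
  m[2, ] <- m[1, ]
  ys <- standardizeRows(m)
  S <- covMatrix(segmentCovariance(ys, 1, 10))
  expect_equal(S[1, 2], S[1, 1], tolerance = 1e-12)

  expect_error(segmentCovariance(y, 5, 3), "i <= j")
  expect_error(segmentCovariance(y, 0, 10), "i <= j")
  expect_error(segmentCovariance(y, 1, 41), "i <= j")

  # sample-divisor switch
  s2 <- segmentCovariance(y, 10, 30, divisor = "sample")
  expect_equal(covMatrix(s2), bruteSegCov(v, 10, 30) * 21 / 20, tolerance = 1e-12)
})

test_that("pooledCovariance is an order-invariant entrywise mean", {
  set.seed(3)
  mats <- replicate(48, { m <- matrix(rnorm(16), 4); (m + t(m)) / 2 },
                    simplify = FALSE)
  pc <- pooledCovariance(mats)
  manual <- matrix(0, 4, 4)
  for (m in mats) manual <- manual + m
  expect_equal(covMatrix(pc), manual / 48, tolerance = 1e-12)
  expect_equal(pc@nUnits, 48L)

  shuffled <- pooledCovariance(mats[sample(48)])
  expect_equal(covMatrix(shuffled), covMatrix(pc), tolerance = 1e-12)

  one <- pooledCovariance(mats[1])
  expect_equal(covMatrix(one), mats[[1]], tolerance = 1e-15)

  A <- mats[[1]]
  expect_equal(covMatrix(pooledCovariance(list(A, -A))), matrix(0, 4, 4))

  expect_error(pooledCovariance(list()), "non-empty")
  expect_error(pooledCovariance(list(diag(3), diag(4))), "common dimension")
})

test_that("thresholdNetwork keeps exactly the strictly-exceeding pairs", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.6
  C[1, 3] <- C[3, 1] <- 0.4
  C[2, 3] <- C[3, 2] <- -0.7
  net <- thresholdNetwork(C, 0.5)
  e <- networkEdges(net)
  expect_equal(nrow(e), 2L)
  expect_setequal(paste(e$node_i, e$node_j), c("node1 node2", "node2 node3"))
  expect_equal(sort(e$correlation), c(-0.7, 0.6))

  expect_equal(nrow(networkEdges(thresholdNetwork(diag(4), 0.1))), 0L)
  expect_error(thresholdNetwork(C, 1), "\\[0, 1\\)")

  # brute-force count on a random correlation matrix
  set.seed(8)
  S <- covMatrix(segmentCovariance(rstd(8, 60, seed = 9), 1, 60))
  thr <- 0.15
  cnt <- 0
  for (i in 1:7) for (j in (i + 1):8) if (abs(S[i, j]) > thr) cnt <- cnt + 1
  expect_equal(nrow(networkEdges(thresholdNetwork(S, thr))), cnt)
})

test_that("selectEdgeThreshold hits the requested edge count", {
  set.seed(21)
  S <- covMatrix(segmentCovariance(rstd(9, 40, seed = 5), 1, 40))
  offd <- abs(S[lower.tri(S)])
  t0 <- selectEdgeThreshold(S, 0)
  expect_gte(t0, max(offd))
  expect_equal(nrow(networkEdges(thresholdNetwork(S, min(t0, 1 - 1e-12)))), 0L)

  tAll <- selectEdgeThreshold(S, length(offd))
  expect_lt(tAll, min(offd))

  t20 <- selectEdgeThreshold(S, 20)
  expect_equal(nrow(networkEdges(thresholdNetwork(S, t20))), 20L)

  expect_error(selectEdgeThreshold(S, length(offd) + 1), "targetEdges")
})
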