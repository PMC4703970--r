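test_that("prefix-sum distance curves agree with direct recomputation", {
  y <- rstd(5, 40, seed = 91)
  ks <- 8:32
  # frobenius and maximum via segment covariances
  dF <- netcpd:::.curves(list(values(y)), ks, 1L, 0)
  dM <- netcpd:::.curves(list(values(y)), ks, 2L, 0)
  dL <- netcpd:::.curves(list(values(y)), ks, 3L, 0)
  dQ <- netcpd:::.curves(list(values(y)), ks, 4L, 1e-8)
  for (i in seq_along(ks)) {
    k <- ks[i]
    S1 <- segmentCovariance(y, 1, k)
    S2 <- segmentCovariance(y, k + 1, 40)
    expect_equal(dF[i], frobeniusDistance(S1, S2), tolerance = 1e-10)
    expect_equal(dM[i], maximumDistance(S1, S2), tolerance = 1e-10)
    expect_equal(dL[i], lrtDistance(y, k), tolerance = 1e-8)
    expect_equal(dQ[i], quadformStatistic(y, k), tolerance = 1e-6)
  }
})

test_that("pooled curves average the per-replicate segment covariances", {
  y1 <- rstd(4, 30, seed = 92)
  y2 <- rstd(4, 30, seed = 93)
  ks <- 7:23
  d <- netcpd:::.curves(list(values(y1), values(y2)), ks, 1L, 0)
  for (i in c(1, 9, 17)) {
    k <- ks[i]
    P1 <- pooledCovariance(list(segmentCovariance(y1, 1, k), segmentCovariance(y2, 1, k)))
    P2 <- pooledCovariance(list(segmentCovariance(y1, k + 1, 30), segmentCovariance(y2, k + 1, 30)))
    expect_equal(d[i], frobeniusDistance(P1, P2), tolerance = 1e-10)
  }
})

test_that("time reversal mirrors the distance curve", {
  y <- rstd(4, 50, seed = 94)
  yr <- standardizeRows(values(y)[, 50:1])
  ks <- 6:44
  d <- netcpd:::.curves(list(values(y)), ks, 1L, 0)
  dr <- netcpd:::.curves(list(values(yr)), ks, 1L, 0)
  expect_equal(dr, rev(d), tolerance = 1e-10)
})

test_that("scan results satisfy their own counting and argmax contracts", {
  y <- rstd(5, 60, seed = 95)
  sr <- scanChangePoints(y, "frobenius", bootstrapConfig(B = 150, seed = 5), delta = 6)
  expect_s4_class(sr, "ScanResult")
  expect_equal(candidates(sr), 7:54)
  z <- zScores(sr)
  expect_true(all(is.finite(z)))
  expect_equal(unname(z[as.character(estimatedChangePoint(sr))]), sr@Z)
  expect_equal(pValue(sr), mean(sr@ZBoot >= sr@Z))
  expect_gte(pValue(sr), 0)
  expect_lte(pValue(sr), 1)
  # reproducibility of the whole resample stream
  sr2 <- scanChangePoints(y, "frobenius", bootstrapConfig(B = 150, seed = 5), delta = 6)
  expect_identical(sr2@ZBoot, sr@ZBoot)
})

test_that("z-scores are location-scale equivariant in the distances", {
  set.seed(96)
  ks <- 5:20
  dObs <- runif(length(ks), 1, 3)
  dBoot <- matrix(runif(100 * length(ks), 1, 3), 100)
  a <- netcpd:::.assembleScan("frobenius", ks, dObs, dBoot, 4L, 100L, FALSE)
  b <- netcpd:::.assembleScan("frobenius", ks, 2.5 * dObs + 7, 2.5 * dBoot + 7,
                              4L, 100L, FALSE)
  expect_equal(b@z, a@z, tolerance = 1e-12)
  expect_equal(b@pValue, a@pValue)
  expect_equal(b@kHat, a@kHat)
})

test_that("argmax ties break toward the smallest candidate", {
  ks <- 5:12
  set.seed(7)
  dBoot <- matrix(rep(rnorm(60), times = length(ks)), ncol = length(ks))
  dObs <- rep(2, length(ks))
  a <- netcpd:::.assembleScan("frobenius", ks, dObs, dBoot, 4L, 60L, FALSE)
  expect_equal(a@kHat, 5L)
})

test_that("a strong midpoint covariance change is detected and located", {
  # whole-network correlation onset at t = 100
  des <- changePointDesign(c(100, 100), list(diag(4), makeBlockCovariance(4, 4, 0.9)))
  sig <- 0L; near <- 0L
  for (s in 1:20) {
    y <- simulateDesign(des, seed = 1000 + s)
    det <- detectSingle(y, "frobenius", bootstrapConfig(B = 200, seed = 2000 + s))
    if (det$significant) {
      sig <- sig + 1L
      if (abs(det$kHat - 100) <= 10) near <- near + 1L
    }
  }
  expect_gte(sig, 19L)
  expect_gte(near, 16L)
})

test_that("the bootstrap mean curve under H0 is U-shaped", {
  y <- rstd(5, 60, seed = 97)
  sr <- scanChangePoints(y, "frobenius", bootstrapConfig(B = 200, seed = 6), delta = 6)
  bm <- sr@bootMean
  mid <- which(candidates(sr) == 30)
  expect_gt(bm[1], bm[mid])
  expect_gt(bm[length(bm)], bm[mid])
  # analytic shape: boundary candidates have higher null expectation
  expect_gt(expectedNullDistance(diag(5), 60, 7), expectedNullDistance(diag(5), 60, 30))
})

test_that("scan input validation catches degenerate series", {
  y <- rstd(5, 20, seed = 98)
  expect_error(scanChangePoints(y, "frobenius", bootstrapConfig(B = 100, seed = 1),
                                delta = 9), "too short")
  # identical columns (plain matrix path used for low-level access)
  const <- matrix(rep(c(1, -1, 0.5, 2, -2), 30), 5, 30)
  expect_error(
    scanChangePoints(const, "frobenius", bootstrapConfig(B = 100, seed = 1)),
    "identical")
  expect_warning(
    scanChangePoints(rstd(5, 60, seed = 100), "frobenius",
                     bootstrapConfig(B = 100, seed = 1), delta = 4),
    "ill-conditioned")
})

test_that("detectMultiple recovers the four-block design and tiles segments", {
  des <- changePointDesign(
    c(100, 100, 100, 100),
    list(diag(10), makeBlockCovariance(10, 5, 0.9),
         diag(10), makeBlockCovariance(10, 5, 0.9)))
  y <- simulateDesign(des, seed = 12)
  cps <- detectMultiple(y, "frobenius", bootstrapConfig(B = 100, seed = 13))
  pts <- changePoints(cps)
  expect_gt(nrow(pts), 1L)
  expect_true(all(pts$p_value < 0.05))
  expect_false(is.unsorted(pts$k))
  # every split point lies strictly inside its segment, segments nest properly
  expect_true(all(pts$k >= pts$seg_start & pts$k < pts$seg_end))
  # at least two of the three true change points found within +/- 10
  found <- vapply(c(100, 200, 300), function(tk) any(abs(pts$k - tk) <= 10), TRUE)
  expect_gte(sum(found), 2L)
})

test_that("detectMultiple returns an empty set on null data", {
  empties <- vapply(1:3, function(s) {
    y <- rstd(5, 120, seed = 500 + s)
    nrow(changePoints(detectMultiple(y, "frobenius",
                                     bootstrapConfig(B = 100, seed = 600 + s))))
  }, 0L)
  expect_lte(sum(empties > 0), 1L)
})
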