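# Synthetic-data generators (block-exchangeable covariance designs, Gaussian
# or heavy-tailed t3 columns, optional AR temporal dependence) and the three
# simulation experiments: power scaling in (n, T), matrix-norm comparison,
# and multiple change points.

#' Block-exchangeable correlation matrix
#'
#' Unit diagonal, constant correlation rho within each diagonal block, zero
#' across blocks; nodes not covered by a block stay independent. The smallest
#' eigenvalue of such a matrix is at least 1 - rho > 0, so it is always a
#' valid (positive definite) correlation matrix for rho in [0, 1).
#'
#' @param n matrix dimension.
#' @param blockSizes integer block sizes, summing to at most n.
#' @param rho within-block correlation in [0, 1).
#' @return an n x n correlation matrix.
#' @examples
#' makeBlockCovariance(4, 2, 0.9)
#' @export
makeBlockCovariance <- function(n, blockSizes, rho) {
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1); rho = 1 would be singular")
  blockSizes <- as.integer(blockSizes)
  if (any(blockSizes < 1L) || sum(blockSizes) > n)
    stop("block sizes must be positive and sum to at most n")
  S <- diag(n)
  at <- 0L
  for (b in blockSizes) {
    idx <- at + seq_len(b)
    S[idx, idx] <- rho
    diag(S)[idx] <- 1
    at <- at + b
  }
  S
}

#' Describe a piecewise-stationary simulation design
#'
#' @param lengths segment lengths (their cumulative sums, minus the last, are
#'   the true change points).
#' @param sigmas list of covariance matrices, one per segment (a single
#'   matrix is recycled).
#' @param family "gaussian" or "student_t3" (multivariate t with 3 degrees of
#'   freedom; the covariance acts as the shape matrix, and since the pipeline
#'   standardizes rows only the correlation structure matters).
#' @return a [ChangePointDesign-class].
#' @export
changePointDesign <- function(lengths, sigmas, family = c("gaussian", "student_t3")) {
  family <- match.arg(family)
  if (is.matrix(sigmas)) sigmas <- list(sigmas)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, length(lengths))
  new("ChangePointDesign", lengths = as.integer(lengths), sigmas = sigmas,
      family = family)
}

#' Simulate a multivariate series from a change-point design
#'
#' Columns are drawn independently, segment by segment, from the segment's
#' family with the segment's covariance as shape matrix; rows are then
#' standardized globally (the pipeline's convention) unless
#' `standardize = FALSE`, in which case the raw draws are returned as a raw
#' [TimeSeriesMatrix-class]. Fixed seed gives a bitwise-reproducible matrix.
#'
#' @param design a [ChangePointDesign-class].
#' @param seed integer seed.
#' @param standardize standardize rows after generation (default TRUE).
#' @return a [TimeSeriesMatrix-class].
#' @export
simulateDesign <- function(design, seed = NULL, standardize = TRUE) {
  stopifnot(is(design, "ChangePointDesign"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design@sigmas[[1]])
  segs <- lapply(seq_along(design@lengths), function(s) {
    m <- design@lengths[s]
    x <- t(MASS::mvrnorm(m, rep(0, n), design@sigmas[[s]]))
    if (!is.matrix(x)) x <- matrix(x, n, m)
    if (design@family == "student_t3") {
      w <- stats::rchisq(m, df = 3) / 3
      x <- sweep(x, 2, sqrt(w), `/`)
    }
    x
  })
  raw <- do.call(cbind, segs)
  out <- if (standardize) standardizeRows(raw) else timeSeriesMatrix(raw)
  # provenance stamp: the design and seed fully determine the dataset
  attr(out, "provenance") <- list(
    lengths = design@lengths, family = design@family,
    true_change_points = trueChangePoints(design), seed = seed)
  out
}

# Draw experiment seeds deterministically from one master seed
.seedStream <- function(seed, k) {
  set.seed(seed)
  sample.int(2147483646L, k)
}

#' Power-scaling experiment: T(n) = n(n-1) + C
#'
#' For each system size n, sets T = n(n-1) + C and simulates a midpoint
#' change from the identity covariance to one with a single correlated
#' upper-left block (2 x 2 by default, the same local change at every n),
#' then runs the single-change-point bootstrap test `reps` times. Under this
#' quadratic growth of T in n the probability of detecting the correct
#' change point is stable across n: the covariance matrix has O(n^2) entries
#' whose estimation noise enters the Frobenius distance, and a fixed-size
#' change stays detectable only if T grows quadratically to offset that
#' noise.
#'
#' @param nValues system sizes.
#' @param C additive constant in T(n) = n(n-1) + C.
#' @param reps simulated datasets per n.
#' @param alpha per-test significance level.
#' @param statistic scan statistic (the Frobenius norm by default).
#' @param B bootstrap replicates per test.
#' @param rho within-block correlation after the change.
#' @param blockSize size of the altered upper-left block (fixed across n).
#' @param seed master seed.
#' @return data.frame with columns n, T, k_true, offset, prob: the fraction
#'   of runs declaring a significant change point at k_true + offset.
#'   Attribute "power_any" records the per-n probability of declaring a
#'   significant change point anywhere.
#' @export
powerExperiment <- function(nValues = c(4L, 8L, 12L), C = 30L, reps = 500L,
                            alpha = 0.05, statistic = "frobenius", B = 100L,
                            rho = 0.9, blockSize = 2L, seed = 1L) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be a positive integer")
  seeds <- .seedStream(seed, 2L * reps * length(nValues))
  out <- list()
  powerAny <- numeric(0)
  si <- 0L
  for (n in as.integer(nValues)) {
    T <- n * (n - 1L) + as.integer(C)
    kTrue <- T %/% 2L
    design <- changePointDesign(
      c(kTrue, T - kTrue),
      list(diag(n), makeBlockCovariance(n, as.integer(blockSize), rho)))
    hits <- integer(0)
    for (r in seq_len(reps)) {
      y <- simulateDesign(design, seed = seeds[si + 2L * r - 1L])
      det <- detectSingle(y, statistic,
                          bootstrapConfig(B = B, seed = seeds[si + 2L * r]),
                          alpha = alpha)
      if (det$significant) hits <- c(hits, det$kHat)
    }
    si <- si + 2L * reps
    powerAny <- c(powerAny, length(hits) / reps)
    offsets <- sort(unique(c(0L, hits - kTrue)))  # offset 0 always reported
    tab <- table(factor(hits - kTrue, levels = offsets))
    out[[length(out) + 1L]] <- data.frame(
      n = n, T = T, k_true = kTrue,
      offset = as.integer(names(tab)), prob = as.integer(tab) / reps)
  }
  res <- do.call(rbind, out)
  attr(res, "reps") <- reps
  attr(res, "power_any") <- stats::setNames(powerAny, as.integer(nValues))
  res
}

# Power (rejection probability) of each statistic on a two-segment design,
# sharing simulated data and bootstrap draws across statistics.
.rejectionPower <- function(n, T, blockSize, rho, family, statistics, reps,
                            B, alpha, seeds, delta = NULL) {
  design <- changePointDesign(
    c(T %/% 2L, T - T %/% 2L),
    list(diag(n), makeBlockCovariance(n, blockSize, rho)), family)
  rej <- matrix(0L, reps, length(statistics),
                dimnames = list(NULL, statistics))
  for (r in seq_len(reps)) {
    y <- simulateDesign(design, seed = seeds[2L * r - 1L])
    srs <- scanChangePoints(y, statistics,
                            bootstrapConfig(B = B, seed = seeds[2L * r]),
                            delta = delta)
    if (is(srs, "ScanResult")) srs <- setNames(list(srs), statistics)
    rej[r, ] <- vapply(statistics, function(s) as.integer(srs[[s]]@pValue < alpha), 1L)
  }
  colMeans(rej)
}

#' Matrix-norm power comparison at calibrated effect size
#'
#' Replays the norm-comparison design: T time points with a single midpoint
#' change from the identity to a block-exchangeable covariance whose
#' upper-left block covers a varying fraction of the network. For each
#' fraction, the within-block correlation rho is first calibrated by
#' bisection so that the Frobenius-norm test rejects with probability
#' `targetPower` (within `tol` at `calibReps` replicates); the power of all
#' requested statistics is then estimated at that rho on shared simulated
#' datasets and shared bootstrap draws. Small altered fractions favor the
#' maximum norm, large fractions the Frobenius norm, and the vech quadratic
#' form trails throughout because its n(n-1)/2-dimensional weight matrix is
#' poorly estimated at realistic T.
#'
#' @param fractions fractions of the network altered, in (0, 1]; each is
#'   rounded to a block of at least 2 nodes.
#' @param n,T system size and series length.
#' @param statistics statistics to compare.
#' @param reps power-estimation replicates per fraction.
#' @param calibReps replicates per bisection evaluation.
#' @param B bootstrap replicates per test.
#' @param alpha significance level.
#' @param targetPower calibration target for the Frobenius norm.
#' @param tol calibration tolerance on the power scale.
#' @param family "gaussian" or "student_t3".
#' @param seed master seed.
#' @param maxIter bisection iteration cap.
#' @param delta boundary buffer shared by all statistics; the default 2n + 1
#'   keeps even the shortest segments comfortably above n columns, which the
#'   determinant-based lrt statistic needs to stay full rank when bootstrap
#'   resamples repeat columns.
#' @return data.frame with columns fraction, block_size, rho, statistic,
#'   power.
#' @export
normComparisonExperiment <- function(fractions = c(0.1, 0.5, 1), n = 20L,
                                     T = 400L, statistics = c("frobenius", "max", "lrt", "quadform"),
                                     reps = 200L, calibReps = 150L, B = 100L,
                                     alpha = 0.05, targetPower = 0.5, tol = 0.03,
                                     family = "gaussian", seed = 1L, maxIter = 8L,
                                     delta = 2L * n + 1L) {
  if (any(fractions <= 0 | fractions > 1)) stop("`fractions` must lie in (0, 1]")
  statistics <- vapply(statistics, .statName, "")
  out <- list()
  for (fi in seq_along(fractions)) {
    blockSize <- max(2L, as.integer(round(fractions[fi] * n)))
    calSeeds <- .seedStream(seed + 1000L * fi, 2L * calibReps)
    evalPow <- function(rho) {
      .rejectionPower(n, T, blockSize, rho, family, "frobenius",
                      calibReps, B, alpha, calSeeds, delta = delta)
    }
    lo <- 0.05; hi <- 0.98
    plo <- evalPow(lo); phi <- evalPow(hi)
    if (plo > targetPower + tol || phi < targetPower - tol)
      stop(sprintf(
        "calibration failed to bracket %.2f power for fraction %.3g: power(%.2f) = %.2f, power(%.2f) = %.2f",
        targetPower, fractions[fi], lo, plo, hi, phi))
    rho <- (lo + hi) / 2
    for (it in seq_len(maxIter)) {
      p <- evalPow(rho)
      if (abs(p - targetPower) <= tol) break
      if (p > targetPower) hi <- rho else lo <- rho
      rho <- (lo + hi) / 2
    }
    powSeeds <- .seedStream(seed + 1000L * fi + 1L, 2L * reps)
    pow <- .rejectionPower(n, T, blockSize, rho, family, statistics,
                           reps, B, alpha, powSeeds, delta = delta)
    out[[fi]] <- data.frame(fraction = fractions[fi], block_size = blockSize,
                            rho = rho, statistic = statistics,
                            power = as.numeric(pow))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reps") <- reps
  res
}

#' Multiple-change-point experiment on the four-block design
#'
#' Simulates T = 400 observations of n = 10 nodes that alternate between the
#' identity covariance (segments 1-100 and 201-300) and a block-exchangeable
#' covariance with a 5 x 5 upper-left block (segments 101-200 and 301-400),
#' runs [detectMultiple()] on each of `reps` independent draws, and tabulates
#' where change points were declared. The middle change point (t = 200) is
#' intrinsically harder: splitting the full series there puts an equal
#' mixture of both covariances on each side, so the first-pass scan
#' concentrates on t = 100 and t = 300 instead.
#'
#' @param reps simulated datasets.
#' @param n,T,rho design parameters (defaults follow the reference design).
#' @param blockSize size of the altered upper-left block.
#' @param segLengths the four segment lengths.
#' @param B bootstrap replicates per test.
#' @param alpha significance level.
#' @param statistic scan statistic.
#' @param seed master seed.
#' @return data.frame with columns k and count over all detected change
#'   points (attribute "reps" records the number of datasets).
#' @export
multipleCPExperiment <- function(reps = 200L, n = 10L, T = 400L, rho = 0.9,
                                 blockSize = 5L, segLengths = c(100L, 100L, 100L, 100L),
                                 B = 100L, alpha = 0.05, statistic = "frobenius",
                                 seed = 1L) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be a positive integer")
  if (sum(segLengths) != T) stop("segment lengths must sum to T")
  S1 <- diag(n)
  S2 <- makeBlockCovariance(n, blockSize, rho)
  design <- changePointDesign(segLengths, list(S1, S2, S1, S2))
  seeds <- .seedStream(seed, 2L * reps)
  found <- integer(0)
  for (r in seq_len(reps)) {
    y <- simulateDesign(design, seed = seeds[2L * r - 1L])
    cps <- detectMultiple(y, statistic,
                          bootstrapConfig(B = B, seed = seeds[2L * r]),
                          alpha = alpha)
    found <- c(found, changePoints(cps)$k)
  }
  tab <- table(found)
  res <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
  attr(res, "reps") <- reps
  attr(res, "true_change_points") <- cumsum(segLengths)[-length(segLengths)]
  res
}

#' Sum detected-location mass near a target location
#'
#' Convenience for experiment summaries: total detection count within
#' `halfWidth` of `target` (a bin of 2*halfWidth + 1 adjacent time points),
#' normalized by the number of datasets.
#'
#' @param tab output of [multipleCPExperiment()].
#' @param target time index of interest.
#' @param halfWidth window half-width; the default 2 gives a bin of five
#'   adjacent time points.
#' @return detections per dataset near the target.
#' @export
locationMass <- function(tab, target, halfWidth = 2L) {
  reps <- attr(tab, "reps")
  sum(tab$count[abs(tab$k - target) <= halfWidth]) / reps
}
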