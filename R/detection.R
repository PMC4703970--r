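# The bootstrap z-score scan and recursive binary segmentation.

# Normalize Y to a list of standardized value matrices (pooled replicates
# share nodes and time axis); returns list(values = list of matrices, n, T).
.scanInput <- function(Y) {
  ys <- if (is.list(Y)) Y else list(Y)
  vals <- lapply(ys, .tsmValues)
  dims <- vapply(vals, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("all replicate matrices must share the same n x T shape")
  list(values = vals, n = dims[1, 1], T = dims[2, 1])
}

.curves <- function(vals, ks, code, ridge) {
  cube <- array(unlist(vals), dim = c(nrow(vals[[1]]), ncol(vals[[1]]), length(vals)))
  as.numeric(cpp_dist_curves(cube, as.integer(ks), as.integer(code), ridge))
}

# One bootstrap draw of every replicate, re-standardized
.nullDraw <- function(vals, mode, fits) {
  lapply(seq_along(vals), function(l) {
    v <- if (mode == "iid") .resampleValues(vals[[l]]) else .sieveValues(vals[[l]], fits[[l]])
    .stdValues(v)
  })
}

#' Bootstrap z-score scan for a single change point
#'
#' Computes the distance curve d(k) between S(1, k) and S(k+1, T) over the
#' candidate window k in [1 + delta, T - delta], simulates B bootstrap
#' replicates of the null (i.i.d. column bootstrap, or AR sieve), forms the
#' per-candidate z-score
#' \deqn{z(k) = (d(k) - \bar{d}^{(b)}(k)) / sd_b(d^{(b)}(k)),}
#' and calibrates the maximum \eqn{Z = \max_k z(k)} against the replicate
#' maxima \eqn{Z^{(b)}}, each standardized by the same per-k bootstrap
#' moments. The p-value is the paper-exact counting formula
#' \eqn{|\{b : Z^{(b)} \ge Z\}| / B}; `smoothPValue = TRUE` switches to
#' (1 + count)/(B + 1) to avoid exact zeros.
#'
#' Candidates whose bootstrap sd is zero are dropped with a warning. The d(k)
#' curve for all k is computed from prefix cumulative sums of column outer
#' products, so a full scan costs O(T n^2) per replicate for the Frobenius
#' and maximum norms.
#'
#' @param Y standardized [TimeSeriesMatrix-class], or a list of them
#'   (replicated trials sharing nodes and time axis; segment covariances are
#'   then pooled with equal weight per replicate).
#' @param statistic "frobenius" (default), "max", "lrt" or "quadform". The
#'   choice must be made before looking at results; trying several and
#'   keeping the best invalidates the p-value.
#' @param config a [BootstrapConfig-class]; see [bootstrapConfig()].
#' @param delta boundary buffer; `NULL` uses n + 1 (segment covariances
#'   estimated from fewer than ~n columns are too ill-conditioned to compare,
#'   and the null expectation of d(k) diverges toward the boundaries). Values
#'   <= n draw a warning; the hard floor is 2.
#' @param ridge diagonal stabilizer for the quadform weight matrix.
#' @param smoothPValue use the (1 + count)/(B + 1) p-value variant.
#' @return a [ScanResult-class] (or, if `statistic` has length > 1, a named
#'   list of them sharing the same data and the same bootstrap draws).
#' @examples
#' des <- changePointDesign(c(40, 40), list(diag(4), makeBlockCovariance(4, 2, 0.9)))
#' y <- simulateDesign(des, seed = 1)
#' scanChangePoints(y, "frobenius", bootstrapConfig(B = 100, seed = 1))
#' @export
scanChangePoints <- function(Y, statistic = "frobenius",
                             config = bootstrapConfig(),
                             delta = NULL, ridge = 1e-8, smoothPValue = FALSE) {
  si <- .scanInput(Y)
  n <- si$n; T <- si$T
  if (is.null(delta)) {
    delta <- n + 1L
  } else {
    delta <- as.integer(delta)
    if (delta <= n) warning("delta <= n: segment covariances may be ill-conditioned")
  }
  delta <- max(delta, 2L)
  ks <- seq.int(1L + delta, T - delta)
  if (length(ks) < 3L)
    stop("series too short: only ", max(length(ks), 0L),
         " candidate change points with delta = ", delta)
  if (all(vapply(si$values, function(v) max(abs(v - v[, 1])) == 0, TRUE)))
    stop("all columns identical; no covariance structure to scan")

  stats <- vapply(statistic, .statName, "")
  codes <- vapply(stats, .statCode, 1L)
  if (any(codes == 4L) && length(si$values) > 1L)
    stop("the quadform statistic is defined on raw columns of a single replicate")

  fits <- NULL
  if (config@mode == "sieve") {
    if (config@arOrder >= T / 4) stop("sieve order must satisfy s < T/4")
    fits <- lapply(si$values, function(v) fitARYuleWalker(standardizeRows(v), config@arOrder))
  }

  dObs <- lapply(codes, function(cd) .curves(si$values, ks, cd, ridge))
  B <- config@B
  dBoot <- lapply(codes, function(cd) matrix(NA_real_, B, length(ks)))

  set.seed(config@seed)
  repSeeds <- sample.int(2147483646L, B)
  for (b in seq_len(B)) {
    set.seed(repSeeds[b])
    vb <- .nullDraw(si$values, config@mode, fits)
    for (m in seq_along(codes)) dBoot[[m]][b, ] <- .curves(vb, ks, codes[m], ridge)
  }

  results <- lapply(seq_along(codes), function(m) {
    .assembleScan(stats[m], ks, dObs[[m]], dBoot[[m]], delta, B, smoothPValue)
  })
  names(results) <- stats
  if (length(results) == 1L) results[[1]] else results
}

.assembleScan <- function(statName, ks, dObs, dBoot, delta, B, smoothPValue) {
  bootMean <- colMeans(dBoot)
  bootSd <- apply(dBoot, 2, stats::sd)
  keep <- bootSd > 0
  if (!all(keep))
    warning(sum(!keep), " candidate(s) dropped for zero bootstrap sd")
  z <- rep(NA_real_, length(ks))
  z[keep] <- (dObs[keep] - bootMean[keep]) / bootSd[keep]
  kHat <- ks[keep][which.max(z[keep])]  # first max: ties go to smallest k
  Z <- max(z[keep])
  Zb <- apply(dBoot[, keep, drop = FALSE], 1, function(d) {
    max((d - bootMean[keep]) / bootSd[keep])
  })
  count <- sum(Zb >= Z)
  p <- if (smoothPValue) (1 + count) / (B + 1) else count / B
  new("ScanResult", statistic = statName, delta = as.integer(delta), B = as.integer(B),
      candidates = as.integer(ks), dObs = as.numeric(dObs),
      bootMean = bootMean, bootSd = bootSd, z = z,
      kHat = as.integer(kHat), Z = Z, ZBoot = Zb, pValue = p)
}

#' Test for a single change point
#'
#' Runs [scanChangePoints()] and declares a change point when the bootstrap
#' p-value falls below `alpha`; the estimated location is the argmax of the
#' z-score curve (ties broken toward the smallest k).
#'
#' @inheritParams scanChangePoints
#' @param alpha significance level (the per-test level; 0.05 by default).
#' @return list with elements `significant`, `kHat`, `pValue`, and `scan`
#'   (the full [ScanResult-class]).
#' @export
detectSingle <- function(Y, statistic = "frobenius", config = bootstrapConfig(),
                         delta = NULL, alpha = 0.05, ridge = 1e-8,
                         smoothPValue = FALSE) {
  sr <- scanChangePoints(Y, statistic, config, delta, ridge, smoothPValue)
  list(significant = sr@pValue < alpha, kHat = sr@kHat,
       pValue = sr@pValue, scan = sr)
}

#' Detect multiple change points by recursive binary segmentation
#'
#' Applies [detectSingle()] to the full series; if the test is significant the
#' series is split at the detected point and the procedure recurses on both
#' halves, each re-standardized and tested afresh (bootstrap replicates are
#' regenerated on the segment's own columns and, in sieve mode, the AR fit is
#' re-estimated per segment). Recursion stops when a segment offers fewer
#' than 3 candidate points or its test is non-significant. Every test uses
#' the same unadjusted `alpha`: each further test is performed only
#' conditional on its parent split being significant, which keeps the false
#' positive rate from inflating.
#'
#' @inheritParams detectSingle
#' @return a [ChangePointSet-class] with globally indexed change points.
#' @export
detectMultiple <- function(Y, statistic = "frobenius", config = bootstrapConfig(),
                           delta = NULL, alpha = 0.05, ridge = 1e-8,
                           smoothPValue = FALSE) {
  si <- .scanInput(Y)
  T <- si$T
  rows <- list()
  recurse <- function(a, b, depth) {
    Tseg <- b - a + 1L
    dseg <- if (is.null(delta)) si$n + 1L else as.integer(delta)
    dseg <- max(dseg, 2L)
    if (Tseg - 2L * dseg < 3L) return(invisible())
    segVals <- lapply(si$values, function(v) v[, a:b, drop = FALSE])
    segY <- tryCatch(lapply(segVals, standardizeRows),
                     error = function(e) NULL)
    if (is.null(segY)) {
      warning("segment [", a, ", ", b, "] could not be standardized; not split further")
      return(invisible())
    }
    segSeed <- (config@seed + 7919 * a + 104729 * b) %% 2147483647
    segConfig <- new("BootstrapConfig", B = config@B, mode = config@mode,
                     arOrder = config@arOrder, seed = as.integer(segSeed))
    det <- tryCatch(
      detectSingle(if (length(segY) == 1L) segY[[1]] else segY,
                   statistic, segConfig, delta, alpha, ridge, smoothPValue),
      error = function(e) NULL)
    if (is.null(det) || !det$significant) return(invisible())
    kGlobal <- a - 1L + det$kHat
    rows[[length(rows) + 1L]] <<- data.frame(
      k = kGlobal, p_value = det$pValue, seg_start = a, seg_end = b, depth = depth)
    recurse(a, kGlobal, depth + 1L)
    recurse(kGlobal + 1L, b, depth + 1L)
    invisible()
  }
  recurse(1L, T, 0L)
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k = integer(), p_value = numeric(), seg_start = integer(),
               seg_end = integer(), depth = integer())
  pts <- pts[order(pts$k), , drop = FALSE]
  rownames(pts) <- NULL
  new("ChangePointSet", points = pts, alpha = alpha, T = as.integer(T))
}
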