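# The four change-point distance statistics. Each maps (Y, k) to a single
# nonnegative-evidence value; larger means more evidence of a covariance
# change at k. All of them are calibrated by the bootstrap, never by an
# asymptotic reference distribution.

.STAT_CODES <- c(frobenius = 1L, max = 2L, maximum = 2L, lrt = 3L, quadform = 4L)

.statCode <- function(statistic) {
  statistic <- match.arg(tolower(statistic), names(.STAT_CODES))
  .STAT_CODES[[statistic]]
}

.statName <- function(statistic) {
  c("frobenius", "max", "lrt", "quadform")[.statCode(statistic)]
}

.distMatrix <- function(S1, S2) {
  A <- if (is(S1, "SegmentCovariance") || is(S1, "PooledCovariance")) covMatrix(S1) else as.matrix(S1)
  B <- if (is(S2, "SegmentCovariance") || is(S2, "PooledCovariance")) covMatrix(S2) else as.matrix(S2)
  if (!all(dim(A) == dim(B)))
    stop("matrices have mismatched dimensions: ", paste(dim(A), collapse = "x"),
         " vs ", paste(dim(B), collapse = "x"))
  A - B
}

#' Squared Frobenius distance between two covariance matrices
#'
#' \eqn{tr((S_1 - S_2)(S_1 - S_2)') = \sum_{ij} (S_{1,ij} - S_{2,ij})^2}: the
#' squared Frobenius norm of the difference, the framework's default distance.
#' It sums over every entry, so it is most sensitive to large-scale,
#' network-wide changes in correlation structure.
#'
#' @param S1,S2 [SegmentCovariance-class]/[PooledCovariance-class] objects or
#'   plain matrices of matching dimension.
#' @return a single nonnegative number.
#' @export
frobeniusDistance <- function(S1, S2) {
  D <- .distMatrix(S1, S2)
  sum(D * D)
}

#' Maximum-norm distance between two covariance matrices
#'
#' The largest absolute entry (diagonal included) of \eqn{S_1 - S_2}. Most
#' sensitive to a single large local change in the network.
#'
#' @inheritParams frobeniusDistance
#' @return a single nonnegative number.
#' @export
maximumDistance <- function(S1, S2) {
  max(abs(.distMatrix(S1, S2)))
}

#' Gaussian likelihood-ratio distance at a candidate change point
#'
#' The \eqn{-2 \log \Lambda_k} statistic for equality of two normal covariance
#' matrices with known (zero) mean:
#' \deqn{T \log\det S(1,T) - k \log\det S(1,k) - (T-k) \log\det S(k+1,T).}
#' Segment covariances use the population divisor. Only the ordering the
#' statistic induces over bootstrap replicates matters for inference, so any
#' strictly monotone variant would calibrate identically; this form is fixed
#' and documented. Requires both segments long enough for full-rank
#' covariances (generically k > n and T - k > n).
#'
#' @param Y standardized [TimeSeriesMatrix-class].
#' @param k candidate change point (split after column k).
#' @return a single number, nonnegative up to numerical tolerance.
#' @export
lrtDistance <- function(Y, k) {
  v <- .tsmValues(Y)
  T <- ncol(v); k <- as.integer(k)
  if (k < 1L || k >= T) stop("need 1 <= k <= T - 1")
  ld <- function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop("singular segment covariance in likelihood-ratio statistic; increase delta")
    as.numeric(d$modulus)
  }
  Sf <- covMatrix(segmentCovariance(Y, 1L, T))
  S1 <- covMatrix(segmentCovariance(Y, 1L, k))
  S2 <- covMatrix(segmentCovariance(Y, k + 1L, T))
  T * ld(Sf) - k * ld(S1) - (T - k) * ld(S2)
}

#' Strict half-vectorization
#'
#' Stacks the strictly-below-diagonal entries of a symmetric n x n matrix
#' column by column into a vector of length n(n-1)/2. Note this deliberately
#' EXCLUDES the diagonal, unlike the textbook vech operator which includes it.
#'
#' @param M symmetric matrix, n >= 2.
#' @param tol symmetry tolerance.
#' @return numeric vector of length n(n-1)/2.
#' @examples
#' vech(matrix(c(1, 2, 2, 3), 2))  # 2
#' @export
vech <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || nrow(M) < 2L) stop("`M` must be square with n >= 2")
  if (max(abs(M - t(M))) > tol) stop("`M` is not symmetric within tolerance ", tol)
  M[lower.tri(M)]
}

#' Inverse of the strict half-vectorization
#'
#' Rebuilds the symmetric matrix with zero diagonal whose strict lower
#' triangle is `v` (column-major).
#'
#' @param v vector of length n(n-1)/2.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
unvech <- function(v) {
  p <- length(v)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (n != round(n)) stop("length(v) is not n(n-1)/2 for integer n")
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- v
  M + t(M)
}

#' Quadratic-form change-point statistic on vech cumulative sums
#'
#' The nonparametric statistic that compares the empirical covariance before
#' the candidate point to that of the full data through the strict-vech
#' vector: with \eqn{w_j = vech(Y_j Y_j')},
#' \deqn{v_k = T^{-1/2} \left(\sum_{j \le k} w_j - \frac{k}{T} \sum_{j \le T} w_j\right),}
#' the statistic is \eqn{v_k' \hat\Sigma^{-1} v_k}, where \eqn{\hat\Sigma} is
#' the plug-in empirical covariance (divisor T) of the per-column vectors
#' \eqn{w_j}, shared across all k, with a small ridge (default 1e-8) on the
#' diagonal for numerical stability. A numerically singular \eqn{\hat\Sigma}
#' falls back to the Moore-Penrose pseudo-inverse with a warning. Reliable
#' estimation of the n(n-1)/2-dimensional \eqn{\hat\Sigma} needs T much larger
#' than n(n-1)/2.
#'
#' @param Y standardized [TimeSeriesMatrix-class].
#' @param k candidate change point.
#' @param ridge diagonal stabilizer added to \eqn{\hat\Sigma}.
#' @return a single nonnegative number.
#' @seealso [quadformSum()] for the omnibus sum-over-k variant.
#' @export
quadformStatistic <- function(Y, k, ridge = 1e-8) {
  v <- .tsmValues(Y)
  T <- ncol(v); k <- as.integer(k)
  if (k < 1L || k >= T) stop("need 1 <= k <= T - 1")
  W <- .vechColumns(v)
  Sig <- tcrossprod(W - rowMeans(W)) / T
  diag(Sig) <- diag(Sig) + ridge
  vk <- (rowSums(W[, seq_len(k), drop = FALSE]) - (k / T) * rowSums(W)) / sqrt(T)
  qf <- tryCatch(drop(crossprod(vk, solve(Sig, vk))), error = function(e) {
    warning("singular vech covariance estimate; using pseudo-inverse")
    drop(crossprod(vk, MASS::ginv(Sig) %*% vk))
  })
  qf
}

# p x T matrix whose j-th column is vech(Y_j Y_j') (strict lower triangle)
.vechColumns <- function(v) {
  n <- nrow(v)
  lo <- which(lower.tri(diag(n)), arr.ind = TRUE)
  v[lo[, 1], , drop = FALSE] * v[lo[, 2], , drop = FALSE]
}

#' Omnibus quadratic-form statistic summed over all k
#'
#' \eqn{\sum_{k=1}^{T-1} v_k' \hat\Sigma^{-1} v_k} with the shared weight
#' matrix of [quadformStatistic()].
#'
#' @inheritParams quadformStatistic
#' @return a single nonnegative number.
#' @export
quadformSum <- function(Y, ridge = 1e-8) {
  v <- .tsmValues(Y)
  T <- ncol(v)
  W <- .vechColumns(v)
  Sig <- tcrossprod(W - rowMeans(W)) / T
  diag(Sig) <- diag(Sig) + ridge
  cum <- t(apply(W, 1, cumsum))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  cT <- cum[, T]
  V <- (cum[, seq_len(T - 1), drop = FALSE] -
          outer(cT, seq_len(T - 1) / T)) / sqrt(T)
  Q <- tryCatch(solve(Sig, V), error = function(e) {
    warning("singular vech covariance estimate; using pseudo-inverse")
    MASS::ginv(Sig) %*% V
  })
  sum(colSums(V * Q))
}
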