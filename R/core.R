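#' Standardize each node's series to mean 0 and unit variance
#'
#' Centers every row to temporal mean 0 and scales it to variance 1 using the
#' population (divide-by-T) convention, so that the full-range segment
#' covariance \eqn{S(1, T)} is a true correlation matrix with unit diagonal.
#' Standardization is applied once, to the full series, before any scanning or
#' resampling; segments are never re-standardized.
#'
#' @param raw numeric matrix (rows = nodes, columns = time points), a
#'   data.frame coercible to one, or a raw [TimeSeriesMatrix-class].
#' @param nodeIds,timeIds optional labels; defaults taken from dimnames.
#' @return a standardized [TimeSeriesMatrix-class].
#' @examples
#' y <- standardizeRows(matrix(rnorm(40), 4, 10))
#' rowMeans(values(y))          # ~ 0
#' rowMeans(values(y)^2)        # ~ 1 (population variance)
#' @export
standardizeRows <- function(raw, nodeIds = NULL, timeIds = NULL) {
  if (is(raw, "TimeSeriesMatrix")) {
    if (is.null(nodeIds)) nodeIds <- raw@nodeIds
    if (is.null(timeIds) && length(raw@timeIds)) timeIds <- raw@timeIds
    raw <- raw@values
  }
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("`raw` must be a numeric matrix with rows = nodes, columns = time points")
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("input contains missing or non-finite values; netcpd requires complete data")
  if (is.null(nodeIds)) nodeIds <- rownames(raw)
  if (is.null(nodeIds)) nodeIds <- paste0("node", seq_len(nrow(raw)))
  if (is.null(timeIds)) timeIds <- colnames(raw)
  mu <- rowMeans(raw)
  s2 <- rowMeans(raw^2) - mu^2
  if (any(s2 <= 0)) {
    bad <- which(s2 <= 0)
    stop("constant row(s) cannot be standardized: ",
         paste(nodeIds[bad], collapse = ", "))
  }
  y <- (raw - mu) / sqrt(s2)
  dimnames(y) <- NULL
  new("TimeSeriesMatrix", values = y, nodeIds = as.character(nodeIds),
      timeIds = if (is.null(timeIds)) character() else as.character(timeIds),
      standardized = TRUE)
}

#' Construct a raw (unstandardized) TimeSeriesMatrix
#'
#' @param values numeric matrix, rows = nodes.
#' @param nodeIds,timeIds optional labels.
#' @return a [TimeSeriesMatrix-class] with `standardized = FALSE`.
#' @export
timeSeriesMatrix <- function(values, nodeIds = NULL, timeIds = NULL) {
  if (is.null(nodeIds)) nodeIds <- rownames(values)
  if (is.null(nodeIds)) nodeIds <- paste0("node", seq_len(nrow(values)))
  v <- as.matrix(values); dimnames(v) <- NULL
  new("TimeSeriesMatrix", values = v, nodeIds = as.character(nodeIds),
      timeIds = if (is.null(timeIds)) character() else as.character(timeIds),
      standardized = FALSE)
}

# bare-matrix standardization for inner loops (no S4 construction)
.stdValues <- function(v) {
  mu <- rowMeans(v)
  s2 <- rowMeans(v^2) - mu^2
  if (any(s2 <= 0)) stop("constant row(s) cannot be standardized")
  (v - mu) / sqrt(s2)
}

.tsmValues <- function(Y, requireStandardized = TRUE) {
  if (is(Y, "TimeSeriesMatrix")) {
    if (requireStandardized && !Y@standardized)
      stop("a standardized TimeSeriesMatrix is required; call standardizeRows() first")
    Y@values
  } else if (is.matrix(Y) && is.numeric(Y)) {
    # plain matrices are accepted for oracle computations and are taken as
    # already row-centered (zero known mean); no check is applied
    Y
  } else stop("expected a TimeSeriesMatrix or a numeric matrix")
}

#' Segment covariance S(i, j)
#'
#' Computes the empirical covariance over columns i..j of a standardized
#' series as the uncentered cross-product divided by the segment length
#' (population convention): \eqn{S(i,j) = Y D(i,j) Y' / (j - i + 1)}, where
#' D(i,j) selects the columns. Rows were centered globally, so there is no
#' per-segment re-centering. The `divisor = "sample"` switch divides by
#' \eqn{j - i} instead.
#'
#' @param Y standardized [TimeSeriesMatrix-class] (or a numeric matrix assumed
#'   row-centered, for oracle use).
#' @param i,j 1-based inclusive column range.
#' @param divisor "population" (default, divide by segment length) or "sample".
#' @return a [SegmentCovariance-class].
#' @examples
#' y <- standardizeRows(matrix(rnorm(100), 5, 20))
#' diag(covMatrix(segmentCovariance(y, 1, 20)))  # exactly 1
#' @export
segmentCovariance <- function(Y, i, j, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  v <- .tsmValues(Y)
  T <- ncol(v)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || j > T || i > j)
    stop("need 1 <= i <= j <= T (got i = ", i, ", j = ", j, ", T = ", T, ")")
  m <- j - i + 1L
  den <- if (divisor == "population") m else m - 1L
  if (den < 1L) stop("sample divisor requires a segment of length >= 2")
  x <- v[, i:j, drop = FALSE]
  S <- tcrossprod(x) / den
  S <- (S + t(S)) / 2
  new("SegmentCovariance", matrix = S, start = i, end = j)
}

#' Pooled covariance across replicate units
#'
#' Entrywise equal-weight arithmetic mean of segment covariances computed per
#' (individual, trial) unit at matched time offsets — the replicated-design
#' estimator \eqn{S^*} used when single trials are too short relative to the
#' number of nodes.
#'
#' @param segments list of [SegmentCovariance-class] (or plain symmetric
#'   matrices) sharing one dimension.
#' @return a [PooledCovariance-class].
#' @export
pooledCovariance <- function(segments) {
  if (!is.list(segments) || length(segments) == 0L)
    stop("`segments` must be a non-empty list")
  mats <- lapply(segments, function(s) if (is(s, "SegmentCovariance")) s@matrix else as.matrix(s))
  ns <- vapply(mats, nrow, 1L)
  if (length(unique(ns)) != 1L || any(vapply(mats, ncol, 1L) != ns))
    stop("all segment covariances must be square with a common dimension")
  S <- Reduce(`+`, mats) / length(mats)
  new("PooledCovariance", matrix = (S + t(S)) / 2, nUnits = length(mats))
}

.asCorrelation <- function(C, tol = 1e-6) {
  if (is(C, "SegmentCovariance") || is(C, "PooledCovariance")) C <- covMatrix(C)
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > tol)
    stop("a symmetric correlation matrix is required")
  if (max(abs(diag(C) - 1)) > tol) C <- stats::cov2cor(C)
  C
}

#' Threshold a correlation matrix into a network
#'
#' Retains the edge (i, j), i < j, iff |C_ij| strictly exceeds the threshold.
#'
#' @param C correlation matrix (unit diagonal within tolerance; covariances
#'   are converted via [stats::cov2cor()]), or a
#'   [SegmentCovariance-class]/[PooledCovariance-class].
#' @param threshold cutoff in [0, 1).
#' @param nodeIds optional node labels.
#' @return a [ThresholdedNetwork-class].
#' @examples
#' C <- diag(3); C[1, 2] <- C[2, 1] <- 0.6; C[2, 3] <- C[3, 2] <- -0.7
#' networkEdges(thresholdNetwork(C, 0.5))
#' @export
thresholdNetwork <- function(C, threshold, nodeIds = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 || threshold >= 1)
    stop("`threshold` must be a single value in [0, 1)")
  C <- .asCorrelation(C)
  n <- nrow(C)
  if (is.null(nodeIds)) nodeIds <- paste0("node", seq_len(n))
  idx <- which(lower.tri(C) & abs(C) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_i = nodeIds[idx[, 2]], node_j = nodeIds[idx[, 1]],
    correlation = C[idx], stringsAsFactors = FALSE
  )
  edges <- edges[order(match(edges$node_i, nodeIds), match(edges$node_j, nodeIds)), , drop = FALSE]
  rownames(edges) <- NULL
  new("ThresholdedNetwork", edges = edges, threshold = threshold,
      nodeIds = as.character(nodeIds))
}

#' Select the |correlation| threshold giving a target edge count
#'
#' Returns a threshold t such that [thresholdNetwork()] at t has exactly
#' `targetEdges` edges when the |C_ij| are distinct: the midpoint between the
#' targetEdges-th and (targetEdges+1)-th largest off-diagonal |correlation|
#' (the maximum |C_ij| for a target of 0; half the smallest |C_ij| when every
#' pair is requested).
#'
#' @param C correlation matrix (or segment/pooled covariance).
#' @param targetEdges requested number of edges, at most n(n-1)/2.
#' @return a single numeric threshold.
#' @export
selectEdgeThreshold <- function(C, targetEdges) {
  C <- .asCorrelation(C)
  a <- sort(abs(C[lower.tri(C)]), decreasing = TRUE)
  npair <- length(a)
  targetEdges <- as.integer(targetEdges)
  if (targetEdges < 0L || targetEdges > npair)
    stop("`targetEdges` must lie in [0, ", npair, "]")
  if (targetEdges == 0L) return(a[1])
  if (targetEdges == npair) return(a[npair] / 2)
  (a[targetEdges] + a[targetEdges + 1L]) / 2
}
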