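#' @import methods
NULL

#' TimeSeriesMatrix: node-by-time observation matrix
#'
#' The framework's sole raw input: an \eqn{n \times T} numeric matrix whose
#' rows are nodes (stocks, brain regions of interest, genes, ...) and whose
#' columns are time points. All detection machinery requires the rows to be
#' standardized to temporal mean 0 and unit (population) variance; use
#' [standardizeRows()] to construct a standardized object from raw data.
#'
#' @slot values numeric matrix, rows = nodes, columns = time points.
#' @slot nodeIds character vector of row labels.
#' @slot timeIds character vector of column labels (may be empty).
#' @slot standardized logical; `TRUE` once rows have been centered/scaled.
#'
#' @seealso [standardizeRows()], [segmentCovariance()], [scanChangePoints()]
#' @export
setClass("TimeSeriesMatrix",
  representation(
    values       = "matrix",
    nodeIds      = "character",
    timeIds      = "character",
    standardized = "logical"
  )
)

setValidity("TimeSeriesMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 nodes (rows)")
  if (ncol(v) < 4L) msg <- c(msg, "need at least 4 time points (columns)")
  if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "values contain missing or non-finite entries")
  if (length(object@nodeIds) != nrow(v)) msg <- c(msg, "nodeIds length must equal nrow(values)")
  if (length(object@timeIds) && length(object@timeIds) != ncol(v))
    msg <- c(msg, "timeIds length must equal ncol(values)")
  if (isTRUE(object@standardized) && length(msg) == 0L) {
    mu <- rowMeans(v)
    s2 <- rowMeans(v^2) - mu^2
    if (max(abs(mu)) > 1e-8 || max(abs(s2 - 1)) > 1e-8)
      msg <- c(msg, "standardized flag set but rows are not mean-0/variance-1")
  }
  if (length(msg)) msg else TRUE
})

#' SegmentCovariance: empirical covariance over a column range
#'
#' The \eqn{n \times n} matrix \eqn{S(i, j)} computed from columns
#' \eqn{i, \ldots, j} of a standardized [TimeSeriesMatrix-class] as the
#' uncentered cross-product divided by the segment length (rows are centered
#' globally, never per segment).
#'
#' @slot matrix symmetric numeric matrix.
#' @slot start,end 1-based inclusive column range.
#' @export
setClass("SegmentCovariance",
  representation(matrix = "matrix", start = "integer", end = "integer")
)

setValidity("SegmentCovariance", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else if (max(abs(m - t(m))) >= 1e-12) msg <- c(msg, "matrix must be symmetric (tolerance 1e-12)")
  if (object@start < 1L || object@end < object@start)
    msg <- c(msg, "need 1 <= start <= end")
  if (length(msg)) msg else TRUE
})

#' PooledCovariance: equal-weight average of segment covariances
#'
#' Used for replicated designs (e.g. repeated fMRI trials across individuals):
#' the segment covariance is computed per (individual, trial) unit at matched
#' time offsets and averaged entrywise with equal weight per unit.
#'
#' @slot matrix symmetric numeric matrix.
#' @slot nUnits number of (individual, trial) units averaged.
#' @export
setClass("PooledCovariance",
  representation(matrix = "matrix", nUnits = "integer")
)

setValidity("PooledCovariance", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (max(abs(m - t(m))) >= 1e-12) return("matrix must be symmetric")
  if (object@nUnits < 1L) return("nUnits must be positive")
  TRUE
})

#' ThresholdedNetwork: correlation network at a fixed |r| cutoff
#'
#' Edges (i, j), i < j, retained iff |correlation| strictly exceeds the
#' threshold; no self loops, no duplicates.
#'
#' @slot edges data.frame with columns node_i, node_j, correlation.
#' @slot threshold the |correlation| cutoff in [0, 1).
#' @slot nodeIds node labels of the underlying matrix.
#' @export
setClass("ThresholdedNetwork",
  representation(edges = "data.frame", threshold = "numeric", nodeIds = "character")
)

setValidity("ThresholdedNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("node_i", "node_j", "correlation") %in% names(e)))
    msg <- c(msg, "edges must have columns node_i, node_j, correlation")
  else {
    if (nrow(e) && any(abs(e$correlation) <= object@threshold))
      msg <- c(msg, "all stored |correlation| must exceed the threshold")
    if (nrow(e) && anyDuplicated(e[, c("node_i", "node_j")]))
      msg <- c(msg, "duplicate edges present")
  }
  if (object@threshold < 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' ARFit: per-node autoregressive fit for the sieve bootstrap
#'
#' Univariate AR(s) coefficients fitted per node from the Yule-Walker
#' equations, with the residual matrix used by [sieveBootstrap()].
#'
#' @slot order the AR order s (0 allowed; the sieve then degenerates to the
#'   i.i.d. column bootstrap).
#' @slot coefficients n x s matrix of per-node coefficients.
#' @slot residuals n x (T - s) residual matrix.
#' @slot nodeIds node labels.
#' @export
setClass("ARFit",
  representation(order = "integer", coefficients = "matrix",
                 residuals = "matrix", nodeIds = "character")
)

setValidity("ARFit", function(object) {
  if (object@order < 0L) return("order must be >= 0")
  if (object@order > 0L && ncol(object@coefficients) != object@order)
    return("coefficients must have `order` columns")
  TRUE
})

#' BootstrapConfig: null-distribution simulation settings
#'
#' @slot B number of bootstrap replicates.
#' @slot mode "iid" (column resampling) or "sieve" (AR residual resampling).
#' @slot arOrder AR order s for the sieve bootstrap (ignored for mode "iid").
#' @slot seed integer RNG seed governing the whole resample stream;
#'   per-replicate substreams are derived deterministically from (seed, b).
#' @export
setClass("BootstrapConfig",
  representation(B = "integer", mode = "character", arOrder = "integer", seed = "integer")
)

setValidity("BootstrapConfig", function(object) {
  msg <- character()
  if (object@B < 1L) msg <- c(msg, "B must be positive")
  if (!object@mode %in% c("iid", "sieve")) msg <- c(msg, "mode must be 'iid' or 'sieve'")
  if (object@arOrder < 0L) msg <- c(msg, "arOrder must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ScanResult: one bootstrap scan over candidate change points
#'
#' Holds the observed distance curve d(k), the per-k bootstrap moments, the
#' z-score curve, the maximizing candidate, the bootstrap maxima \eqn{Z^{(b)}}
#' and the bootstrap p-value for a single segment.
#'
#' @slot statistic statistic name ("frobenius", "max", "lrt", "quadform").
#' @slot delta boundary buffer.
#' @slot B number of bootstrap replicates.
#' @slot candidates candidate change points k (1-based, global to the scanned
#'   segment).
#' @slot dObs observed d(k) per candidate.
#' @slot bootMean,bootSd per-candidate bootstrap mean and (B-1 divisor) sd.
#' @slot z z-score curve (NA for candidates dropped for zero bootstrap sd).
#' @slot kHat argmax-z candidate (ties broken toward the smallest k).
#' @slot Z max z-score on the observed data.
#' @slot ZBoot per-replicate maxima, standardized by the same per-k moments.
#' @slot pValue bootstrap p-value |{b : Z^(b) >= Z}| / B.
#' @export
setClass("ScanResult",
  representation(
    statistic = "character", delta = "integer", B = "integer",
    candidates = "integer", dObs = "numeric",
    bootMean = "numeric", bootSd = "numeric", z = "numeric",
    kHat = "integer", Z = "numeric", ZBoot = "numeric", pValue = "numeric"
  )
)

setValidity("ScanResult", function(object) {
  msg <- character()
  K <- length(object@candidates)
  if (length(object@dObs) != K || length(object@z) != K ||
      length(object@bootMean) != K || length(object@bootSd) != K)
    msg <- c(msg, "per-candidate slots must share the candidate length")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(object@kHat) == 1L && !object@kHat %in% object@candidates)
    msg <- c(msg, "kHat must be a candidate")
  if (length(msg)) msg else TRUE
})

#' ChangePointSet: recursively detected change points
#'
#' Result of [detectMultiple()]: statistically significant change points with
#' global 1-based indices, per-split p-values, the segment bounds at detection
#' and the recursion depth.
#'
#' @slot points data.frame with columns k, p_value, seg_start, seg_end, depth,
#'   sorted by k.
#' @slot alpha per-test significance level (unadjusted by design: each split is
#'   tested conditional on its parent split being significant).
#' @slot T total series length.
#' @export
setClass("ChangePointSet",
  representation(points = "data.frame", alpha = "numeric", T = "integer")
)

setValidity("ChangePointSet", function(object) {
  p <- object@points
  msg <- character()
  need <- c("k", "p_value", "seg_start", "seg_end", "depth")
  if (!all(need %in% names(p))) return(paste("points needs columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (is.unsorted(p$k)) msg <- c(msg, "points must be sorted by k")
    if (any(p$p_value >= object@alpha)) msg <- c(msg, "recorded p-values must be < alpha")
    if (any(p$k < p$seg_start | p$k >= p$seg_end)) msg <- c(msg, "k must lie inside its segment")
  }
  if (length(msg)) msg else TRUE
})

#' ChangePointDesign: generative description for synthetic series
#'
#' A sequence of segments, each with a length and a covariance (shape) matrix;
#' the true change points are the cumulative segment boundaries. The
#' distribution family is multivariate normal or multivariate t with 3 degrees
#' of freedom (the covariance then acts as the shape matrix).
#'
#' @slot lengths integer segment lengths, summing to T.
#' @slot sigmas list of n x n covariance matrices, one per segment.
#' @slot family "gaussian" or "student_t3".
#' @export
setClass("ChangePointDesign",
  representation(lengths = "integer", sigmas = "list", family = "character")
)

setValidity("ChangePointDesign", function(object) {
  msg <- character()
  if (length(object@lengths) < 1L) msg <- c(msg, "need at least one segment")
  if (any(object@lengths < 1L)) msg <- c(msg, "segment lengths must be positive")
  if (length(object@sigmas) != length(object@lengths))
    msg <- c(msg, "one covariance matrix per segment required")
  if (!object@family %in% c("gaussian", "student_t3"))
    msg <- c(msg, "family must be 'gaussian' or 'student_t3'")
  ns <- vapply(object@sigmas, nrow, 1L)
  if (length(unique(ns)) > 1L) msg <- c(msg, "all covariance matrices must share one dimension")
  if (length(msg)) msg else TRUE
})

#' DetectionReport: end-to-end pipeline result
#'
#' @slot config echoed run configuration.
#' @slot input shape and checksum fingerprint of the input.
#' @slot diagnostics Durbin-Watson statistics, chosen bootstrap mode and AR
#'   order.
#' @slot changePoints data.frame of detected change points (global indices).
#' @slot scans the underlying [ScanResult-class] object(s).
#' @slot version package version string.
#' @export
setClass("DetectionReport",
  representation(config = "list", input = "list", diagnostics = "list",
                 changePoints = "data.frame", scans = "list", version = "character")
)
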