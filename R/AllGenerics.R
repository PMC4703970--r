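# Generics and accessors. Slots are never reached into by user code;
# everything goes through these.

#' @rdname TimeSeriesMatrix-class
#' @param x,object a netcpd S4 object
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname TimeSeriesMatrix-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname TimeSeriesMatrix-class
#' @export
setGeneric("timeIds", function(x) standardGeneric("timeIds"))
#' @rdname TimeSeriesMatrix-class
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))
#' @rdname SegmentCovariance-class
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))
#' @rdname SegmentCovariance-class
#' @export
setGeneric("segmentRange", function(x) standardGeneric("segmentRange"))
#' @rdname ThresholdedNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname ScanResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname ScanResult-class
#' @export
setGeneric("estimatedChangePoint", function(x) standardGeneric("estimatedChangePoint"))
#' @rdname ScanResult-class
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname ScanResult-class
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname ScanResult-class
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname ChangePointSet-class
#' @export
setGeneric("changePoints", function(x) standardGeneric("changePoints"))
#' @rdname ChangePointDesign-class
#' @export
setGeneric("trueChangePoints", function(x) standardGeneric("trueChangePoints"))

#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("values", "TimeSeriesMatrix", function(x) x@values)
#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("nodeIds", "TimeSeriesMatrix", function(x) x@nodeIds)
#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("timeIds", "TimeSeriesMatrix", function(x) x@timeIds)
#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("isStandardized", "TimeSeriesMatrix", function(x) x@standardized)
#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("dim", "TimeSeriesMatrix", function(x) dim(x@values))
#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("nrow", "TimeSeriesMatrix", function(x) nrow(x@values))
#' @rdname TimeSeriesMatrix-class
#' @export
setMethod("ncol", "TimeSeriesMatrix", function(x) ncol(x@values))

#' @rdname SegmentCovariance-class
#' @export
setMethod("covMatrix", "SegmentCovariance", function(x) x@matrix)
#' @rdname SegmentCovariance-class
#' @export
setMethod("covMatrix", "PooledCovariance", function(x) x@matrix)
#' @rdname SegmentCovariance-class
#' @export
setMethod("segmentRange", "SegmentCovariance", function(x) c(start = x@start, end = x@end))

#' @rdname ThresholdedNetwork-class
#' @export
setMethod("networkEdges", "ThresholdedNetwork", function(x) x@edges)

#' @rdname ScanResult-class
#' @export
setMethod("pValue", "ScanResult", function(x) x@pValue)
#' @rdname ScanResult-class
#' @export
setMethod("estimatedChangePoint", "ScanResult", function(x) x@kHat)
#' @rdname ScanResult-class
#' @export
setMethod("candidates", "ScanResult", function(x) x@candidates)
#' @rdname ScanResult-class
#' @export
setMethod("zScores", "ScanResult", function(x) setNames(x@z, x@candidates))
#' @rdname ScanResult-class
#' @export
setMethod("distances", "ScanResult", function(x) setNames(x@dObs, x@candidates))

#' @rdname ChangePointSet-class
#' @export
setMethod("changePoints", "ChangePointSet", function(x) x@points)
#' @rdname ChangePointSet-class
#' @export
setMethod("length", "ChangePointSet", function(x) nrow(x@points))

#' @rdname ChangePointDesign-class
#' @export
setMethod("trueChangePoints", "ChangePointDesign", function(x) {
  cs <- cumsum(x@lengths)
  cs[-length(cs)]
})

setMethod("show", "TimeSeriesMatrix", function(object) {
  d <- dim(object@values)
  cat("TimeSeriesMatrix:", d[1], "nodes x", d[2], "time points;",
      if (object@standardized) "standardized" else "raw (not standardized)", "\n")
  cat("  nodes:", paste(utils::head(object@nodeIds, 5), collapse = ", "),
      if (d[1] > 5) "..." else "", "\n")
})

setMethod("show", "SegmentCovariance", function(object) {
  cat(sprintf("SegmentCovariance S(%d, %d): %d x %d (segment length %d)\n",
              object@start, object@end, nrow(object@matrix), ncol(object@matrix),
              object@end - object@start + 1L))
})

setMethod("show", "PooledCovariance", function(object) {
  cat(sprintf("PooledCovariance: %d x %d, averaged over %d unit(s)\n",
              nrow(object@matrix), ncol(object@matrix), object@nUnits))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat(sprintf("ThresholdedNetwork: %d edge(s) at |correlation| > %.3g among %d node(s)\n",
              nrow(object@edges), object@threshold, length(object@nodeIds)))
})

setMethod("show", "ARFit", function(object) {
  cat(sprintf("ARFit: per-node AR(%d), %d node(s), %d residual column(s)\n",
              object@order, nrow(object@residuals), ncol(object@residuals)))
})

setMethod("show", "BootstrapConfig", function(object) {
  cat(sprintf("BootstrapConfig: mode=%s, B=%d%s, seed=%d\n", object@mode, object@B,
              if (object@mode == "sieve") sprintf(", s=%d", object@arOrder) else "",
              object@seed))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s): %d candidate(s) in [%d, %d], B=%d\n",
              object@statistic, length(object@candidates),
              min(object@candidates), max(object@candidates), object@B))
  cat(sprintf("  k_hat = %d, Z = %.3f, bootstrap p-value = %.4g\n",
              object@kHat, object@Z, object@pValue))
})

setMethod("show", "ChangePointSet", function(object) {
  cat(sprintf("ChangePointSet: %d change point(s) at alpha = %g (T = %d)\n",
              nrow(object@points), object@alpha, object@T))
  if (nrow(object@points)) print(object@points, row.names = FALSE)
})

setMethod("show", "ChangePointDesign", function(object) {
  cat(sprintf("ChangePointDesign: %d segment(s), T = %d, family = %s\n",
              length(object@lengths), sum(object@lengths), object@family))
  tcp <- trueChangePoints(object)
  if (length(tcp)) cat("  true change points:", paste(tcp, collapse = ", "), "\n")
})

setMethod("show", "DetectionReport", function(object) {
  cat("DetectionReport (netcpd", object@version, ")\n")
  cat("  input:", paste(unlist(object@input$shape), collapse = " x "), "\n")
  cat("  bootstrap:", object@diagnostics$mode, "\n")
  cat("  change points:", if (nrow(object@changePoints)) paste(object@changePoints$k, collapse = ", ") else "none", "\n")
})
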