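# Delimited-text readers/writers and the end-to-end pipeline with its JSON
# report. Rows are nodes; an optional header row and an optional leading ID
# column are auto-detected (both overridable).

.isNumericToken <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a node-by-time matrix from delimited text
#'
#' @param path CSV or TSV file; the separator defaults by extension (".tsv"
#'   or ".txt" means tab) and can be forced with `sep`.
#' @param sep field separator, or NULL to infer from the extension.
#' @param header "auto", TRUE or FALSE.
#' @param idColumn "auto", TRUE or FALSE — whether the first column holds
#'   node IDs.
#' @return a raw (unstandardized) [TimeSeriesMatrix-class]; pass it to
#'   [standardizeRows()] before any analysis.
#' @export
readTimeSeriesMatrix <- function(path, sep = NULL, header = "auto", idColumn = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  toks <- strsplit(lines, sep, fixed = TRUE)
  toks <- lapply(toks, trimws)
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged rows in ", path, ": line ", bad, " has ", widths[bad],
         " fields, line 1 has ", widths[1])
  }
  firstNumeric <- vapply(toks[[1]], .isNumericToken, TRUE)
  if (identical(header, "auto")) header <- !all(firstNumeric[-1])
  timeIds <- NULL
  if (header) {
    timeIds <- toks[[1]]
    toks <- toks[-1]
    if (!length(toks)) stop("file contains only a header row: ", path)
  }
  firstCol <- vapply(toks, `[[`, "", 1L)
  if (identical(idColumn, "auto")) idColumn <- !all(vapply(firstCol, .isNumericToken, TRUE))
  nodeIds <- NULL
  if (idColumn) {
    nodeIds <- firstCol
    if (anyDuplicated(nodeIds))
      stop("duplicate node IDs: ", paste(unique(nodeIds[duplicated(nodeIds)]), collapse = ", "))
    toks <- lapply(toks, `[`, -1L)
    if (!is.null(timeIds)) timeIds <- timeIds[-1L]
  }
  nT <- length(toks[[1]])
  headerOffset <- if (header) 1L else 0L
  vals <- matrix(NA_real_, length(toks), nT)
  for (i in seq_along(toks)) {
    x <- suppressWarnings(as.numeric(toks[[i]]))
    if (anyNA(x)) {
      j <- which(is.na(x))[1]
      stop("non-numeric value ", sQuote(toks[[i]][j]), " at line ",
           i + headerOffset, ", field ", j + as.integer(idColumn), " of ", path)
    }
    vals[i, ] <- x
  }
  timeSeriesMatrix(vals, nodeIds = nodeIds, timeIds = timeIds)
}

#' Write a thresholded network as a tab-separated edge list
#'
#' Columns: node_i, node_j, weight (the signed correlation).
#'
#' @param net a [ThresholdedNetwork-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "ThresholdedNetwork"))
  e <- networkEdges(net)
  names(e)[3] <- "weight"
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square matrix (adjacency or correlation) as CSV
#'
#' @param M matrix (or segment/pooled covariance).
#' @param path output path.
#' @param nodeIds optional labels used for both dimensions.
#' @return the path, invisibly.
#' @export
writeAdjacency <- function(M, path, nodeIds = NULL) {
  if (is(M, "SegmentCovariance") || is(M, "PooledCovariance")) M <- covMatrix(M)
  M <- as.matrix(M)
  if (is.null(nodeIds)) nodeIds <- paste0("node", seq_len(nrow(M)))
  dimnames(M) <- list(nodeIds, nodeIds)
  utils::write.csv(M, path, quote = FALSE)
  invisible(path)
}

#' Write a TimeSeriesMatrix as CSV (with node IDs)
#'
#' @param Y a [TimeSeriesMatrix-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTimeSeriesMatrix <- function(Y, path) {
  stopifnot(is(Y, "TimeSeriesMatrix"))
  df <- data.frame(id = nodeIds(Y), values(Y))
  tid <- timeIds(Y)
  names(df) <- c("id", if (length(tid)) tid else paste0("t", seq_len(ncol(Y))))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full detection pipeline
#'
#' Standardizes the input, runs the Durbin-Watson autocorrelation diagnostic
#' to gate the bootstrap mode (the i.i.d. column bootstrap when no
#' significant autocorrelation is found at `dwAlpha`, the sieve bootstrap
#' otherwise, with its order chosen by cross-validation when
#' `arOrder = "auto"`), performs single or recursive multiple change-point
#' detection, and assembles a reproducible [DetectionReport-class]. With the
#' same config and input, re-running reproduces every number bit-for-bit.
#'
#' @param input path(s) to delimited matrices, a [TimeSeriesMatrix-class], a
#'   numeric matrix, or a list of replicate matrices sharing nodes and time
#'   axis (replicates are pooled with equal weight).
#' @param statistic scan statistic name.
#' @param B bootstrap replicates.
#' @param delta boundary buffer, or "auto" for n + 1.
#' @param alpha significance level.
#' @param bootstrap "auto", "iid" or "sieve".
#' @param arOrder sieve AR order, or "auto" for cross-validated selection.
#' @param seed master seed.
#' @param multiple detect multiple change points by binary segmentation.
#' @param dwAlpha significance cutoff of the Durbin-Watson gate.
#' @param dwPerms permutations for the Durbin-Watson p-value.
#' @param networkThreshold if non-NULL, per-segment correlation networks at
#'   this |correlation| cutoff are attached to the report.
#' @return a [DetectionReport-class].
#' @export
runPipeline <- function(input, statistic = "frobenius", B = 500L, delta = "auto",
                        alpha = 0.05, bootstrap = c("auto", "iid", "sieve"),
                        arOrder = "auto", seed = 1L, multiple = FALSE,
                        dwAlpha = 0.05, dwPerms = 999L, networkThreshold = NULL) {
  bootstrap <- match.arg(bootstrap)
  statistic <- .statName(statistic)
  fingerprint <- list()
  loadOne <- function(x) {
    if (is.character(x)) {
      fingerprint$files <<- c(fingerprint$files, unname(tools::md5sum(x)))
      readTimeSeriesMatrix(x)
    } else x
  }
  raw <- if (is.character(input) && length(input) > 1L) lapply(input, loadOne)
         else if (is.list(input) && !is(input, "TimeSeriesMatrix")) lapply(input, loadOne)
         else list(loadOne(input))
  ys <- lapply(raw, standardizeRows)
  n <- nrow(ys[[1]]); T <- ncol(ys[[1]])
  fingerprint$shape <- c(n = n, T = T, replicates = length(ys))

  dw <- lapply(seq_along(ys), function(l)
    durbinWatson(ys[[l]], nperm = dwPerms, seed = seed + l))
  dwP <- min(vapply(dw, `[[`, 0, "p.value"))
  mode <- if (bootstrap == "auto") { if (dwP < dwAlpha) "sieve" else "iid" } else bootstrap
  s <- 0L
  if (mode == "sieve")
    s <- if (identical(arOrder, "auto"))
      max(vapply(ys, selectAROrder, 1L)) else as.integer(arOrder)
  if (mode == "sieve" && s == 0L) {
    # cross-validation found no autocorrelation worth modelling
    mode <- "iid"
  }
  config <- bootstrapConfig(B = B, mode = mode, arOrder = max(s, 1L), seed = seed)
  if (mode == "iid") config@arOrder <- 0L
  deltaVal <- if (identical(delta, "auto")) NULL else as.integer(delta)
  Yin <- if (length(ys) == 1L) ys[[1]] else ys

  if (multiple) {
    cps <- detectMultiple(Yin, statistic, config, deltaVal, alpha)
    cpdf <- changePoints(cps)
    scans <- list(multiple = cps)
  } else {
    det <- detectSingle(Yin, statistic, config, deltaVal, alpha)
    cpdf <- if (det$significant)
      data.frame(k = det$kHat, p_value = det$pValue, seg_start = 1L,
                 seg_end = T, depth = 0L)
    else
      data.frame(k = integer(), p_value = numeric(), seg_start = integer(),
                 seg_end = integer(), depth = integer())
    scans <- list(single = det$scan)
  }

  if (!is.null(networkThreshold)) {
    bounds <- sort(unique(c(0L, cpdf$k, T)))
    scans$networks <- lapply(seq_len(length(bounds) - 1L), function(i) {
      segC <- if (length(ys) == 1L)
        segmentCovariance(ys[[1]], bounds[i] + 1L, bounds[i + 1L])
      else
        pooledCovariance(lapply(ys, segmentCovariance, bounds[i] + 1L, bounds[i + 1L]))
      thresholdNetwork(segC, networkThreshold, nodeIds = nodeIds(ys[[1]]))
    })
  }

  new("DetectionReport",
      config = list(statistic = statistic, B = as.integer(B),
                    delta = if (is.null(deltaVal)) n + 1L else deltaVal,
                    alpha = alpha, bootstrap_requested = bootstrap,
                    bootstrap_used = mode, ar_order = if (mode == "sieve") s else 0L,
                    seed = as.integer(seed), multiple = multiple),
      input = fingerprint,
      diagnostics = list(mode = mode, dw_p_value = dwP,
                         dw_statistics = lapply(dw, `[[`, "statistic"),
                         ar_order = if (mode == "sieve") s else 0L),
      changePoints = cpdf,
      scans = scans,
      version = as.character(utils::packageVersion("netcpd")))
}

#' Serialize a DetectionReport to JSON
#'
#' @param report a [DetectionReport-class].
#' @param path optional output path; when NULL the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
reportJSON <- function(report, path = NULL) {
  stopifnot(is(report, "DetectionReport"))
  scans <- report@scans
  perK <- NULL
  sr <- if (!is.null(scans$single)) scans$single else NULL
  if (!is.null(sr))
    perK <- data.frame(k = candidates(sr), d = unname(distances(sr)),
                       z = unname(zScores(sr)))
  obj <- list(
    config = report@config,
    input = report@input,
    diagnostics = list(mode = report@diagnostics$mode,
                       dw_p_value = report@diagnostics$dw_p_value,
                       ar_order = report@diagnostics$ar_order),
    change_points = report@changePoints,
    per_k = perK,
    version = report@version
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
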