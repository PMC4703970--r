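# Null-distribution generators: i.i.d. column bootstrap and AR(s) sieve
# bootstrap, plus the Durbin-Watson diagnostic and cross-validated AR order
# selection that decide between them.

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (>= 100 recommended; a warning is
#'   issued below that).
#' @param mode "iid" resamples whole columns with replacement; "sieve" fits a
#'   per-node AR(s) model and resamples residual columns.
#' @param arOrder AR order s for the sieve (ignored for mode "iid").
#' @param seed integer seed governing the whole resample stream.
#' @return a [BootstrapConfig-class].
#' @export
bootstrapConfig <- function(B = 500L, mode = c("iid", "sieve"), arOrder = 1L, seed = 1L) {
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  if (B < 100L) warning("B < 100 bootstrap replicates gives coarse p-values")
  new("BootstrapConfig", B = B, mode = mode,
      arOrder = if (mode == "iid") 0L else as.integer(arOrder),
      seed = as.integer(seed))
}

.resampleValues <- function(v) {
  # columns move together: cross-sectional dependence is preserved
  v[, sample.int(ncol(v), ncol(v), replace = TRUE), drop = FALSE]
}

.restandardizeOrReturn <- function(v, template, restandardize) {
  if (restandardize) {
    out <- standardizeRows(v)
    if (is(template, "TimeSeriesMatrix")) out@nodeIds <- template@nodeIds
    out
  } else if (is(template, "TimeSeriesMatrix")) {
    new("TimeSeriesMatrix", values = v, nodeIds = template@nodeIds,
        timeIds = character(), standardized = FALSE)
  } else v
}

#' i.i.d. column bootstrap
#'
#' Draws T columns uniformly with replacement from the columns of Y — the
#' empirical-distribution approximation of the null in which all columns are
#' independent and identically distributed. Whole columns are moved, so the
#' contemporaneous cross-node correlation (the quantity under test) is
#' preserved. By default the resampled series is re-standardized rowwise to
#' mirror the treatment of the observed data.
#'
#' @param Y standardized [TimeSeriesMatrix-class] (a plain numeric matrix is
#'   accepted for low-level use).
#' @param seed optional seed for this single draw.
#' @param restandardize re-standardize rows of the resample (default TRUE).
#' @return an object of the same kind as `Y`.
#' @export
iidBootstrap <- function(Y, seed = NULL, restandardize = TRUE) {
  v <- if (is(Y, "TimeSeriesMatrix")) .tsmValues(Y) else .tsmValues(Y, FALSE)
  if (!is.null(seed)) set.seed(seed)
  .restandardizeOrReturn(.resampleValues(v), Y, restandardize)
}

.arCompanionRadius <- function(phi) {
  s <- length(phi)
  if (s == 0L) return(0)
  if (s == 1L) return(abs(phi))
  Cm <- rbind(phi, cbind(diag(s - 1L), 0))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

#' Fit per-node AR(s) models by Yule-Walker
#'
#' Each node's row is fitted with a univariate AR(s) model whose coefficients
#' solve the Yule-Walker system built from the divide-by-T autocovariances of
#' the (already centered) row. Residuals
#' \eqn{\hat\epsilon_j = Y_j - \sum_{r=1}^s \phi_r \circ Y_{j-r}} are computed
#' columnwise for j > s, where \eqn{\circ} applies each node's own
#' coefficient. For s = 1 the coefficient is exactly the lag-1
#' autocorrelation r(1).
#'
#' @param Y standardized [TimeSeriesMatrix-class].
#' @param s AR order (s = 0 is allowed and yields an empty fit whose sieve
#'   bootstrap degenerates to the i.i.d. column bootstrap).
#' @return an [ARFit-class]; a warning is raised if any node's fitted process
#'   is non-stationary (companion-matrix spectral radius >= 1).
#' @export
fitARYuleWalker <- function(Y, s) {
  v <- .tsmValues(Y)
  n <- nrow(v); T <- ncol(v)
  s <- as.integer(s)
  if (s < 0L) stop("`s` must be >= 0")
  ids <- if (is(Y, "TimeSeriesMatrix")) Y@nodeIds else paste0("node", seq_len(n))
  if (s == 0L)
    return(new("ARFit", order = 0L, coefficients = matrix(0, n, 0),
               residuals = v, nodeIds = ids))
  if (T <= 4L * s) stop("need T > 4s to fit AR(", s, ")")
  phi <- matrix(0, n, s)
  for (i in seq_len(n)) {
    y <- v[i, ]
    cc <- vapply(0:s, function(h) sum(y[seq_len(T - h)] * y[seq_len(T - h) + h]) / T, 0)
    phi[i, ] <- tryCatch(
      solve(stats::toeplitz(cc[seq_len(s)]), cc[2:(s + 1L)]),
      error = function(e) stop("near-singular Yule-Walker system for node ", ids[i])
    )
  }
  radii <- apply(phi, 1, .arCompanionRadius)
  if (any(radii >= 1))
    warning("fitted AR process non-stationary for node(s): ",
            paste(ids[radii >= 1], collapse = ", "))
  eps <- v[, (s + 1L):T, drop = FALSE]
  for (r in seq_len(s))
    eps <- eps - phi[, r] * v[, (s + 1L - r):(T - r), drop = FALSE]
  new("ARFit", order = s, coefficients = phi, residuals = eps, nodeIds = ids)
}

#' AR(s) sieve bootstrap
#'
#' Resamples the residual columns of a per-node AR(s) fit with replacement
#' (whole n-vectors, preserving contemporaneous cross-node correlation) and
#' replays the autoregressive recursion to produce a full n x T null series
#' that retains the temporal dependence of the data. The first s columns are
#' initialized from the observed first s columns; the output is
#' re-standardized rowwise by default. With s = 0 this reduces exactly to
#' [iidBootstrap()] (identical draws at identical seed).
#'
#' @param Y standardized [TimeSeriesMatrix-class] the fit was derived from.
#' @param fit an [ARFit-class] from [fitARYuleWalker()].
#' @param seed optional seed for this single draw.
#' @param restandardize re-standardize rows of the generated series.
#' @return an object of the same kind as `Y`.
#' @export
sieveBootstrap <- function(Y, fit, seed = NULL, restandardize = TRUE) {
  stopifnot(is(fit, "ARFit"))
  v <- if (is(Y, "TimeSeriesMatrix")) .tsmValues(Y) else .tsmValues(Y, FALSE)
  if (!is.null(seed)) set.seed(seed)
  .restandardizeOrReturn(.sieveValues(v, fit), Y, restandardize)
}

.sieveValues <- function(v, fit) {
  s <- fit@order
  T <- ncol(v)
  if (s == 0L) return(.resampleValues(v))
  phi <- fit@coefficients
  radii <- apply(phi, 1, .arCompanionRadius)
  if (any(radii >= 1))
    stop("explosive fitted AR process; sieve bootstrap would diverge")
  eps <- fit@residuals
  if (ncol(eps) != T - s) stop("fit is inconsistent with Y (residual length)")
  idx <- sample.int(T - s, T - s, replace = TRUE)
  epsb <- eps[, idx, drop = FALSE]
  out <- v
  for (j in (s + 1L):T) {
    acc <- epsb[, j - s]
    for (r in seq_len(s)) acc <- acc + phi[, r] * out[, j - r]
    out[, j] <- acc
  }
  out
}

#' Durbin-Watson autocorrelation diagnostic
#'
#' Per node, \eqn{DW = \sum_{j>1} (y_j - y_{j-1})^2 / \sum_j y_j^2}, which is
#' near 2 for serially uncorrelated data and below 2 under positive lag-1
#' autocorrelation. A single combined p-value is formed by a permutation null:
#' columns are shuffled (jointly across nodes), the minimum per-node DW is the
#' combined statistic, and the lower tail is evaluated with the add-one rule.
#'
#' @param Y standardized [TimeSeriesMatrix-class] (T >= 10).
#' @param nperm number of permutations (>= 999 recommended).
#' @param seed optional seed for the permutation draw.
#' @return list with `statistic` (per-node DW), `minStatistic`, and `p.value`.
#' @export
durbinWatson <- function(Y, nperm = 999L, seed = NULL) {
  v <- .tsmValues(Y)
  if (ncol(v) < 10L) stop("need T >= 10 for the Durbin-Watson diagnostic")
  dwRows <- function(m) {
    dif <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    rowSums(dif^2) / rowSums(m^2)
  }
  obs <- dwRows(v)
  names(obs) <- if (is(Y, "TimeSeriesMatrix")) Y@nodeIds else NULL
  if (!is.null(seed)) set.seed(seed)
  mobs <- min(obs)
  perm <- vapply(seq_len(nperm), function(b) {
    min(dwRows(v[, sample.int(ncol(v)), drop = FALSE]))
  }, 0)
  p <- (1 + sum(perm <= mobs)) / (nperm + 1)
  list(statistic = obs, minStatistic = mobs, p.value = p)
}

#' Select the sieve AR order by forward-chaining cross-validation
#'
#' For each s in 0..maxOrder, per-node AR(s) coefficients are fitted on a
#' growing prefix of the series and used for one-step-ahead prediction of the
#' next held-out block. The selected order is the smallest s whose prediction
#' mean squared error (averaged over nodes, times and folds) comes within one
#' standard error of the minimum (the usual cross-validation
#' one-standard-error rule, which keeps white noise at s = 0 instead of
#' chasing coin-flip improvements). s = 0 predicts the (zero) mean.
#'
#' @param Y standardized [TimeSeriesMatrix-class].
#' @param maxOrder largest order tried (must be < T/10).
#' @param nFolds validation blocks in the forward chain.
#' @return the selected integer order.
#' @export
selectAROrder <- function(Y, maxOrder = 5L, nFolds = 5L) {
  v <- .tsmValues(Y)
  T <- ncol(v)
  maxOrder <- as.integer(maxOrder)
  if (maxOrder >= T / 10) stop("`maxOrder` must be < T/10")
  bounds <- unique(round(seq(floor(T / 2), T, length.out = nFolds + 1L)))
  F <- length(bounds) - 1L
  foldMse <- matrix(NA_real_, F, maxOrder + 1L)
  for (f in seq_len(F)) {
    tr <- bounds[f]              # fit on columns 1..tr
    va <- (tr + 1L):bounds[f + 1L]
    fitY <- standardizeRows(v[, seq_len(tr), drop = FALSE])
    for (s in 0:maxOrder) {
      pred <- matrix(0, nrow(v), length(va))
      if (s > 0L) {
        phi <- fitARYuleWalker(fitY, s)@coefficients
        for (r in seq_len(s))
          pred <- pred + phi[, r] * v[, va - r, drop = FALSE]
      }
      foldMse[f, s + 1L] <- mean((v[, va, drop = FALSE] - pred)^2)
    }
  }
  mse <- colMeans(foldMse)
  best <- which.min(mse)
  se <- stats::sd(foldMse[, best]) / sqrt(F)
  if (!is.finite(se)) se <- 0
  min(which(mse <= mse[best] + se)) - 1L
}
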