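---
title: "Detecting change points in correlation networks with netcpd"
author: "netcpd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting change points in correlation networks with netcpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcpd)
```

## The problem and the model

Many systems — stocks in a market, brain regions in an fMRI session, genes
in a longitudinal expression study — are naturally summarized as
*correlation networks*: nodes are the observed units and edges encode the
correlation of their time series. When the system's regime shifts (a market
crash, a change of cognitive task), the correlation structure changes
abruptly, and a network estimated by pooling all the data misrepresents
both regimes. netcpd locates such *change points*: time indices $k$ at
which the column covariance of an $n \times T$ observation matrix $Y$
(rows = nodes, columns = time points) switches from $\Sigma_1$ to
$\Sigma_2$.

The data model is deliberately minimal. Columns $Y_j$ are identically
distributed with some (unknown) distribution between change points; rows
are standardized once, globally, to temporal mean 0 and unit population
variance, so the full-range covariance estimate is a correlation matrix.
Gradual drifts are outside the model: only abrupt changes are sought.

For a candidate split $k$ the segment covariance
$S(i,j) = \frac{1}{j-i+1} \sum_{l=i}^{j} Y_l Y_l^{\prime}$ (no per-segment
re-centering — rows were centered globally) summarizes each side, and a
distance $d(k)$ between $S(1,k)$ and $S(k+1,T)$ measures the evidence of a
change:

* **frobenius** (default): $\mathrm{tr}[(S_1-S_2)(S_1-S_2)'] = \sum_{ij}(S_{1,ij}-S_{2,ij})^2$,
  the squared Frobenius norm — sensitive to widespread changes;
* **max**: $\max_{ij} |S_{1,ij}-S_{2,ij}|$ — sensitive to a single large
  local change;
* **lrt**: the Gaussian likelihood-ratio form
  $T\log\det S(1,T) - k\log\det S(1,k) - (T-k)\log\det S(k+1,T)$ — uses
  determinants, robust to entrywise noise;
* **quadform**: a quadratic form in the cumulative strict half-vectorization
  $v_k = T^{-1/2}(\sum_{j\le k}\mathrm{vech}(Y_jY_j') - \frac{k}{T}\sum_{j\le T}\mathrm{vech}(Y_jY_j'))$,
  weighted by the inverse empirical covariance of the per-column vech
  vectors. Here $\mathrm{vech}$ stacks only the
  strictly-below-diagonal entries (length $n(n-1)/2$), *excluding* the
  diagonal — unlike the textbook operator.

The choice of distance must be made **before** looking at results; running
several and keeping the "best" invalidates the p-value.

## Bootstrap calibration and the scan

No reference distribution is assumed. Under the no-change null the columns
are exchangeable, so $B$ bootstrap pseudo-series are built by resampling
whole columns with replacement (preserving the cross-node dependence, which
is the quantity under test) and each is re-standardized exactly like the
observed data. For every candidate $k \in [1+\Delta,\, T-\Delta]$ the
per-$k$ bootstrap mean and standard deviation of $d^{(b)}(k)$ standardize
the observed curve into z-scores
$z(k) = (d(k) - \bar d^{(b)}(k))/\mathrm{sd}_b(k)$; the test statistic is
$Z = \max_k z(k)$, and its p-value is the fraction of replicate maxima
$Z^{(b)}$ (standardized by the same per-$k$ moments, all $B$ replicates
included) at or above $Z$. Ties in the argmax go to the smallest $k$, so
reports are deterministic.

The buffer $\Delta$ (default $n+1$, hard floor 2) keeps the scan away from
the boundaries, where segment covariances are estimated from very few
columns: the closed form below shows the null expectation of $d(k)$
*diverges* there. Candidates whose bootstrap sd is zero are dropped with a
warning.

For autocorrelated series, column resampling would break the temporal
dependence and bias the null. The **sieve bootstrap** instead fits a
per-node AR($s$) model by Yule–Walker (on divide-by-$T$ autocovariances of
the already-centered rows), resamples the *residual columns* as whole
$n$-vectors, and replays the recursion, initializing from the observed
first $s$ columns. Resampling residual columns jointly across nodes is the
single most consequential interpretation in the package: it preserves the
contemporaneous cross-node correlation while the AR recursion restores the
temporal dependence. With $s = 0$ the sieve reduces exactly to the i.i.d.
bootstrap. A Durbin–Watson diagnostic
($DW = \sum_j (y_j - y_{j-1})^2/\sum_j y_j^2 \approx 2$ under no lag-1
autocorrelation) gates the default choice in `runPipeline()`: the
permutation p-value of the minimum per-node DW below 0.05 selects the
sieve, with $s$ chosen by forward-chaining cross-validated one-step
prediction error. Both the min-DW combination and the forward-chaining
scheme are package conventions chosen here; the underlying diagnostic and
order-selection ideas are standard.

Multiple change points use recursive binary segmentation: split at the
first significant point, re-standardize each half, regenerate bootstrap
nulls on the half's own columns (re-estimating the sieve fit), and recurse
until a test is non-significant or fewer than 3 candidates remain. Every
test runs at the same unadjusted $\alpha$: later tests are performed only
conditional on earlier splits being significant, which keeps the false
positive rate from inflating.

## The null expectation of d(k)

For i.i.d. zero-mean Gaussian columns with covariance $\Sigma$ and no
change point,

$$E[d(k)] = \left(\frac{1}{k} + \frac{1}{T-k}\right)
           \left[(\mathrm{tr}\,\Sigma)^2 + \mathrm{tr}(\Sigma^2)\right],$$

because each entry of a length-$m$ segment covariance has variance
$(\sigma_{ii}\sigma_{jj} + \sigma_{ij}^2)/m$ and the two segments are
independent. The curve is U-shaped with minimum $4[(\mathrm{tr}\Sigma)^2 +
\mathrm{tr}(\Sigma^2)]/T$ at $k = T/2$ and diverges at the boundaries —
detection is only as strong as the weaker of the two covariance estimates.
`expectedNullDistance()` implements the formula;
`mcNullDistance()` is its Monte-Carlo oracle, which simulates *raw*
$N(0,\Sigma)$ draws (no standardization), matching the assumptions of the
derivation — global row standardization induces $O(1/T)$ dependence that
the formula does not model. The test suite checks the two against each
other to 3 Monte-Carlo standard errors before the formula is trusted
anywhere.

```{r theory}
curve <- nullExpectationCurve(diag(5), 60)
curve[curve$k %in% c(5, 15, 30, 45, 55), ]
```

## What the generators emulate — and what they do not

`simulateDesign()` draws columns segment-by-segment from a multivariate
normal, or multivariate $t_3$ (the covariance acting as shape matrix — the
population covariance is then $3\Sigma$, but after row standardization only
the correlation structure matters). `makeBlockCovariance()` builds the
block-exchangeable designs used throughout: unit diagonal, correlation
$\rho$ inside diagonal blocks, zeros elsewhere; its smallest eigenvalue is
$\ge 1-\rho$, so every $\rho \in [0,1)$ is valid. AR temporal dependence is
available through the test fixtures and the sieve machinery.

These generators emulate abrupt, synchronized covariance switches with
exchangeable block structure. Real data differ in ways the passing tests
deliberately do not certify: gradual drifts, heteroskedastic bursts,
heavy-tailed *and* autocorrelated noise combined, missing values (rejected
outright), and effect structures that are not block-exchangeable.

## The simulation experiments and their defaults

Three experiment drivers replay the package's validation studies. Their
default repetition counts are scaled to hundreds rather than the tens of
thousands a publication-grade figure would use; the statistical assertions
made on them in the test suite use correspondingly wide (3 standard error)
bands. Full-scale counts are a `reps` argument away.

* `powerExperiment()` — a midpoint change from the identity to a covariance
  with a single correlated **2 × 2** upper-left block ($\rho = 0.9$), with
  $T(n) = n(n-1) + C$, $C = 30$. The altered block is the *same fixed local
  change at every n*: the covariance matrix has $O(n^2)$ entries whose noise
  enters the Frobenius distance, and a fixed-size signal stays equally
  detectable only when $T$ grows quadratically. (A block growing with $n$,
  e.g. $n/2$, makes the signal grow too and power then rises steeply in
  $n$ — empirically by an order of magnitude from $n=4$ to $n=8$ — which is
  why the fixed block is the design choice here.)
* `normComparisonExperiment()` — $n = 20$, $T = 400$, midpoint change, the
  altered block covering a fraction of the network (default grid
  $\{0.1, 0.5, 1\}$, i.e. blocks of 2, 10 and 20 nodes). For each fraction,
  $\rho$ is calibrated by bisection so the Frobenius test has 50% power
  (±0.03 at 150 calibration replicates); all four statistics are then
  compared *on shared datasets and shared bootstrap draws* at that $\rho$.
  Small fractions favor the maximum norm, large ones the Frobenius norm; the
  quadform trails both because its $n(n-1)/2$-dimensional weight matrix
  (190 × 190 here) is poorly estimated from $T = 400$ columns — at smaller
  $n$ (say 12, where the weight matrix is only 66 × 66) it catches up, which
  is why $n = 20$ is the default. One ordering does not reproduce at the
  full-network fraction: the calibrated $\rho$ there is so small that the
  determinant-based lrt statistic falls to null-level power, below the
  quadform; the experiment reports it as measured. The scans share a buffer
  $\Delta = 2n+1$ so that even the shortest segments keep the lrt's segment
  covariances full rank when bootstrap resamples repeat columns.
* `multipleCPExperiment()` — $T = 400$, $n = 10$, covariance alternating
  every 100 points between the identity and a 5 × 5-block design
  ($\rho = 0.9$). The middle change point ($t = 200$) is intrinsically
  hard: the first-pass split there sees identical mixtures on both sides,
  so the outer points are found first and $t = 200$ only on the recursion's
  children. Detection mass is summarized in 5-point bins
  (`locationMass()`, half-width 2).

## Numerical choices and degenerate inputs

* Segment covariances use the population divisor $1/(j-i+1)$; a
  `divisor = "sample"` switch gives $1/(j-i)$. The population convention
  makes $S(1,T)$ exactly a correlation matrix under the package's
  standardization.
* The quadform weight matrix gets a $10^{-8}$ ridge; a numerically singular
  estimate falls back to the Moore–Penrose pseudo-inverse with a warning.
* A singular segment covariance inside **lrt** raises an error advising a
  larger $\Delta$.
* Constant rows and missing values are rejected with named locations.
* One master seed drives everything; per-replicate substreams derive
  deterministically from (seed, b), and recursive segments derive their
  seeds from (seed, segment bounds), so every report is bit-for-bit
  reproducible.
* p-values use the literal counting formula $|\{b: Z^{(b)} \ge Z\}|/B$;
  `smoothPValue = TRUE` switches to $(1+\mathrm{count})/(B+1)$ to avoid
  exact zeros.

## Known limitations

The bootstrap calibration is slightly conservative at small sample sizes:
at $n = 5$, $T = 60$ the empirical type-I error of the nominal 5% test
measures near 2.5%, because the bootstrap standard deviation of $d(k)$
overshoots the sampling standard deviation by roughly 20% at that $T$ (the
overshoot decays as $T$ grows — about 10% at $T = 400$ — and the same code
measures 4.3% type-I error at $n = 4$, $T = 42$). Detection near the
boundaries is intrinsically hard regardless of $\Delta$; change points
within $\Delta$ of either end are not searched for. The quadform statistic
needs $T \gg n(n-1)/2$ and is restricted to single-replicate input (it is
defined on raw columns, not pooled covariances). Only abrupt changes are
modeled; sliding-window and gradual-change formulations are out of scope.
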