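// Distance curves d(k) for the change-point scan, computed in one pass over
// prefix cross-products. Y is an n x T x L cube of (standardized) replicate
// matrices; the pooled segment covariance is the equal-weight average of the
// per-replicate segment covariances. Statistic codes:
//   1 squared Frobenius norm  ||S(1,k) - S(k+1,T)||_F^2
//   2 maximum norm            max_ij |S(1,k)_ij - S(k+1,T)_ij|
//   3 -2 log likelihood ratio (Gaussian, known zero mean)
//   4 vech quadratic form (single replicate only; enforced by the caller)
//
// For the Frobenius norm the per-candidate value collapses to scalars:
// with P = prefix cross-product / L and A_T the pooled full cross-product,
//   S1 - S2 = P (1/m1 + 1/m2) - A_T / m2,
// so d(k) = c1^2 ||A||^2 - 2 c1 c2 <A, A_T> + c2^2 ||A_T||^2 with raw A,
// c1 = (1/m1 + 1/m2)/L, c2 = 1/m2 — no per-candidate temporaries.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double safe_log_det(const mat& S) {
  double val, sign;
  bool ok = log_det(val, sign, S);
  if (!ok || sign <= 0.0)
    Rcpp::stop("singular segment covariance in likelihood-ratio statistic; increase delta");
  return val;
}

// rank-1 update of an upper-triangular Cholesky factor: R'R + x x'
static void chol_rank1_update(mat& R, vec x) {
  const uword n = R.n_rows;
  for (uword k = 0; k < n; ++k) {
    const double rkk = R(k, k);
    const double r = std::sqrt(rkk * rkk + x[k] * x[k]);
    const double c = r / rkk, s = x[k] / rkk;
    R(k, k) = r;
    for (uword j = k + 1; j < n; ++j) {
      R(k, j) = (R(k, j) + s * x[j]) / c;
      x[j] = c * x[j] - s * R(k, j);
    }
  }
}

static double chol_log_det(const mat& R) {
  return 2.0 * accu(log(R.diag()));
}

// upper Cholesky of a pooled cross-product, or stop if singular
static mat chol_or_stop(const mat& A) {
  mat R;
  if (!chol(R, A) || A.n_rows != R.n_rows || any(R.diag() <= 0))
    Rcpp::stop("singular segment covariance in likelihood-ratio statistic; increase delta");
  return R;
}

// [[Rcpp::export]]
arma::vec cpp_dist_curves(const arma::cube& Y, const arma::ivec& ks,
                          const int stat, const double ridge) {
  const uword n = Y.n_rows, T = Y.n_cols, L = Y.n_slices;
  const uword K = ks.n_elem;
  vec out(K);

  if (stat == 4) {
    // strict lower-triangle vech of the per-column outer products (L == 1)
    const mat& Ym = Y.slice(0);
    const uword p = n * (n - 1) / 2;
    mat W(p, T);
    for (uword j = 0; j < T; ++j) {
      uword a = 0;
      for (uword c2 = 0; c2 < n; ++c2)
        for (uword r2 = c2 + 1; r2 < n; ++r2)
          W(a++, j) = Ym(r2, j) * Ym(c2, j);
    }
    mat Wc = W.each_col() - mean(W, 1);
    mat Sig = (Wc * Wc.t()) / double(T);
    Sig.diag() += ridge;
    mat cum = cumsum(W, 1);
    vec cT = cum.col(T - 1);
    mat Sinv;
    bool ok = inv_sympd(Sinv, Sig);
    if (!ok) {
      Rcpp::warning("singular vech covariance estimate; using pseudo-inverse");
      Sinv = pinv(Sig);
    }
    for (uword i = 0; i < K; ++i) {
      const uword k = (uword)ks[i];
      vec v = (cum.col(k - 1) - (double(k) / double(T)) * cT) / std::sqrt(double(T));
      out[i] = as_scalar(v.t() * Sinv * v);
    }
    return out;
  }

  // pooled full-range cross-product (unnormalized per replicate, averaged)
  mat AT(n, n, fill::zeros);
  for (uword l = 0; l < L; ++l)
    AT += Y.slice(l) * Y.slice(l).t();
  AT /= double(L);

  if (stat == 3) {
    // log det of the prefix/suffix cross-products by incremental rank-1
    // Cholesky updates: one O(n^3) factorization per pass, O(n^2) per column
    const double ld_full = safe_log_det(AT / double(T));
    const double nlogL = double(n) * std::log(double(L));
    vec ld1(K), ld2(K);

    mat A(n, n, fill::zeros);
    mat R1;
    uword idx = 0;
    for (uword j = 0; j < T && idx < K; ++j) {
      if (R1.n_rows == n) {
        for (uword l = 0; l < L; ++l)
          chol_rank1_update(R1, Y.slice(l).col(j));
      } else {
        for (uword l = 0; l < L; ++l)
          A += Y.slice(l).col(j) * Y.slice(l).col(j).t();
      }
      const uword k = j + 1;
      if ((uword)ks[idx] != k) continue;
      if (R1.n_rows != n) R1 = chol_or_stop(A);
      ld1[idx] = chol_log_det(R1) - nlogL - double(n) * std::log(double(k));
      ++idx;
    }
    mat B(n, n, fill::zeros);
    mat R2;
    uword ridx = K;  // candidates processed right to left
    for (uword c = T; c > 1 && ridx > 0; --c) {
      // add column c; afterwards B covers columns c..T (suffix for k = c - 1)
      if (R2.n_rows == n) {
        for (uword l = 0; l < L; ++l)
          chol_rank1_update(R2, Y.slice(l).col(c - 1));
      } else {
        for (uword l = 0; l < L; ++l)
          B += Y.slice(l).col(c - 1) * Y.slice(l).col(c - 1).t();
      }
      const uword k = c - 1;
      if ((uword)ks[ridx - 1] != k) continue;
      if (R2.n_rows != n) R2 = chol_or_stop(B);
      --ridx;
      ld2[ridx] = chol_log_det(R2) - nlogL - double(n) * std::log(double(T - k));
    }
    for (uword i = 0; i < K; ++i) {
      const double m1 = double(ks[i]), m2 = double(T - (uword)ks[i]);
      out[i] = double(L) * (double(T) * ld_full - m1 * ld1[i] - m2 * ld2[i]);
    }
    if (!out.is_finite())
      Rcpp::stop("singular segment covariance in likelihood-ratio statistic; increase delta");
    return out;
  }

  double aT2 = 0.0;
  if (stat == 1) aT2 = accu(square(AT));

  mat A(n, n, fill::zeros);
  uword idx = 0;
  for (uword j = 0; j < T && idx < K; ++j) {
    for (uword l = 0; l < L; ++l) {
      const vec x = Y.slice(l).col(j);
      A += x * x.t();
    }
    const uword k = j + 1;
    if ((uword)ks[idx] != k) continue;
    const double m1 = double(k), m2 = double(T - k);
    if (stat == 1) {
      const double c1 = (1.0 / m1 + 1.0 / m2) / double(L);
      const double c2 = 1.0 / m2;
      out[idx] = c1 * c1 * accu(square(A)) - 2.0 * c1 * c2 * accu(A % AT) +
                 c2 * c2 * aT2;
    } else {
      out[idx] = abs((A / (double(L) * m1)) - (AT - A / double(L)) / m2).max();
    }
    ++idx;
  }
  return out;
}
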