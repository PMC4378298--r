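// Fast bivariate spectral Granger causality kernel.
//
// Mirrors the R reference path exactly: least-squares VAR fit without
// intercept, residual covariance with denominator T - p - 2p, one-sided
// spectral density S = H Sigma H* tr, Geweke directed measures, and a
// normalized trapezoidal band integral with linearly interpolated band
// edges.  Used where many thousands of fits are needed (permutation
// nulls, Monte-Carlo calibration).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct BivarFit {
  cube coeffs;   // 2 x 2 x p
  mat sigma;     // 2 x 2
};

BivarFit fit_bivar(const mat& y, int p) {
  const int T = y.n_rows;
  if (T <= 2 * p + 1) Rcpp::stop("series too short for the requested order");
  mat Y = y.rows(p, T - 1);
  mat X(T - p, 2 * p);
  for (int k = 1; k <= p; ++k) {
    X.cols(2 * (k - 1), 2 * k - 1) = y.rows(p - k, T - 1 - k);
  }
  mat B = solve(X.t() * X, X.t() * Y, solve_opts::likely_sympd);
  mat E = Y - X * B;
  double denom = static_cast<double>(T - p - 2 * p);
  if (denom < 1) Rcpp::stop("too few observations for the covariance");
  BivarFit fit;
  fit.sigma = (E.t() * E) / denom;
  fit.coeffs = cube(2, 2, p);
  for (int k = 0; k < p; ++k) {
    fit.coeffs.slice(k) = B.rows(2 * k, 2 * k + 1).t();
  }
  return fit;
}

// Directed Geweke measures on the supplied grid; col 0 = 1->2, col 1 = 2->1.
// Scalarized 2x2 complex arithmetic (hot path of the permutation null).
mat directed_spectra(const BivarFit& fit, const vec& freqs, double tr) {
  typedef std::complex<double> cplx;
  const int p = fit.coeffs.n_slices;
  const mat& sig = fit.sigma;
  const double s_11 = sig(0, 0), s_22 = sig(1, 1), s_12 = sig(0, 1);
  const double det_sig_scale = s_11 * s_22;
  (void)det_sig_scale;
  mat out(freqs.n_elem, 2);
  for (uword fi = 0; fi < freqs.n_elem; ++fi) {
    cplx a11(1, 0), a12(0, 0), a21(0, 0), a22(1, 0);
    const double w = -2.0 * M_PI * freqs(fi) * tr;
    const cplx e1 = std::exp(cplx(0, w));
    cplx ek(1, 0);
    for (int k = 0; k < p; ++k) {
      ek *= e1;
      a11 -= fit.coeffs(0, 0, k) * ek;
      a12 -= fit.coeffs(0, 1, k) * ek;
      a21 -= fit.coeffs(1, 0, k) * ek;
      a22 -= fit.coeffs(1, 1, k) * ek;
    }
    const cplx det = a11 * a22 - a12 * a21;
    if (std::abs(det) < 1e-14) {
      Rcpp::stop("A(f) numerically singular at f = %g Hz", freqs(fi));
    }
    const cplx h11 = a22 / det, h12 = -a12 / det;
    const cplx h21 = -a21 / det, h22 = a11 / det;
    // S = H Sigma H* tr (only the diagonal is needed)
    const double s11 =
        (std::norm(h11) * s_11 + std::norm(h12) * s_22 +
         2.0 * s_12 * std::real(h11 * std::conj(h12))) * tr;
    const double s22 =
        (std::norm(h21) * s_11 + std::norm(h22) * s_22 +
         2.0 * s_12 * std::real(h21 * std::conj(h22))) * tr;
    const cplx ht11 = h11 + (s_12 / s_11) * h12;
    const cplx ht22 = h22 + (s_12 / s_22) * h21;
    const double intr1 = std::norm(ht11) * s_11 * tr;
    const double intr2 = std::norm(ht22) * s_22 * tr;
    if (s11 <= 0 || s22 <= 0 || intr1 <= 0 || intr2 <= 0) {
      Rcpp::stop("spectral matrix degenerate at f = %g Hz", freqs(fi));
    }
    double m12 = std::log(s22 / intr2);  // 1 -> 2
    double m21 = std::log(s11 / intr1);  // 2 -> 1
    out(fi, 0) = (m12 < 0 && m12 >= -1e-8) ? 0.0 : m12;
    out(fi, 1) = (m21 < 0 && m21 >= -1e-8) ? 0.0 : m21;
  }
  return out;
}

double interp_at(const vec& freqs, const vec& vals, double f) {
  uword i = 0;
  while (i + 1 < freqs.n_elem && freqs(i + 1) < f) ++i;
  if (freqs(i) == f) return vals(i);
  uword j = i + 1;
  while (freqs(j) < f) ++j;  // freqs(j) >= f
  if (freqs(j) == f) return vals(j);
  uword a = j - 1;
  double w = (f - freqs(a)) / (freqs(j) - freqs(a));
  return vals(a) + w * (vals(j) - vals(a));
}

double band_avg(const vec& freqs, const vec& vals, double f1, double f2) {
  std::vector<double> fe, ve;
  fe.push_back(f1);
  ve.push_back(interp_at(freqs, vals, f1));
  for (uword i = 0; i < freqs.n_elem; ++i) {
    if (freqs(i) > f1 && freqs(i) < f2) {
      fe.push_back(freqs(i));
      ve.push_back(vals(i));
    }
  }
  fe.push_back(f2);
  ve.push_back(interp_at(freqs, vals, f2));
  double acc = 0;
  for (size_t i = 1; i < fe.size(); ++i) {
    acc += (fe[i] - fe[i - 1]) * (ve[i] + ve[i - 1]) / 2.0;
  }
  return acc / (f2 - f1);
}

// Indices of grid points needed to integrate over [f1, f2] (one point of
// slack on each side for edge interpolation).
uvec band_support(const vec& freqs, double f1, double f2) {
  uword lo = 0, hi = freqs.n_elem - 1;
  for (uword i = 0; i < freqs.n_elem; ++i) {
    if (freqs(i) <= f1) lo = i;
    if (freqs(i) >= f2) { hi = i; break; }
  }
  return regspace<uvec>(lo, hi);
}

vec2 igc_one(const mat& y, int p, const vec& freqs, double tr, double f1,
             double f2) {
  BivarFit fit = fit_bivar(y, p);
  mat spec = directed_spectra(fit, freqs, tr);
  vec2 out;
  out(0) = band_avg(freqs, spec.col(0), f1, f2);
  out(1) = band_avg(freqs, spec.col(1), f1, f2);
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::vec igc_pair_cpp(const arma::mat& y, int p, const arma::vec& freqs,
                       double tr, double f1, double f2) {
  if (y.n_cols != 2) Rcpp::stop("y must have exactly two columns");
  if (f1 < freqs.min() || f2 > freqs.max() || f1 >= f2) {
    Rcpp::stop("band not covered by the frequency grid");
  }
  uvec sup = band_support(freqs, f1, f2);
  return igc_one(y, p, freqs.elem(sup), tr, f1, f2);
}

// Permutation null: per permutation, permute the time indices of the first
// column of every subject's pair series, recompute both directed
// band-integrated flows, and pool.  `cyclic = true` restricts the draw to
// cyclic permutations (a random rotation by 10..T-10 samples), which
// preserves each member's autocorrelation while destroying the cross-lag
// alignment; `cyclic = false` draws an unrestricted permutation.  Uses the
// R RNG (deterministic under set.seed).  Returns an
// (n_perm * n_subjects) x 2 matrix.
// [[Rcpp::export]]
arma::mat perm_null_cpp(Rcpp::List series, Rcpp::IntegerVector orders,
                        int n_perm, const arma::vec& freqs, double tr,
                        double f1, double f2, bool cyclic) {
  const int ns = series.size();
  if (orders.size() != ns) Rcpp::stop("one order per subject required");
  std::vector<mat> mats(ns);
  for (int s = 0; s < ns; ++s) {
    mats[s] = Rcpp::as<mat>(series[s]);
    if (mats[s].n_cols != 2) Rcpp::stop("each series must have two columns");
  }
  uvec sup = band_support(freqs, f1, f2);
  vec fsub = freqs.elem(sup);
  mat out(static_cast<uword>(n_perm) * ns, 2);
  uword row = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int s = 0; s < ns; ++s) {
      const mat& y = mats[s];
      const int T = static_cast<int>(y.n_rows);
      mat yp = y;
      if (cyclic) {
        if (T < 21) Rcpp::stop("cyclic scheme needs at least 21 samples");
        int k = 9 + Rcpp::sample(T - 19, 1)[0];  // rotation in 10..T-10
        for (int t = 0; t < T; ++t) {
          yp(t, 0) = y((t + k) % T, 0);
        }
      } else {
        Rcpp::IntegerVector idx = Rcpp::sample(T, T, false);
        for (int t = 0; t < T; ++t) {
          yp(t, 0) = y(idx[t] - 1, 0);
        }
      }
      out.row(row++) = igc_one(yp, orders[s], fsub, tr, f1, f2).t();
    }
  }
  return out;
}
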