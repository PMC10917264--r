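#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Inner loop of the cost-tilted Blahut-Arimoto iteration.  Maximizes
// I(p) - s * sum(p w) by multiplicative updates
//   p <- p * 2^( beta * (D(l) - s w(l) - ub) ),
// where D(l) = sum_n f(n|l) log2( f(n|l) / q(n) ) and ub is the current
// Csiszar upper bound.  beta = 1 is the classical update; beta > 1
// over-relaxes and is reset to 1 if the lower bound ever decreases.
//
// Ft is the transposed conditional matrix (outputs x inputs) and
// lo/hi give, per input, the contiguous output range carrying
// non-negligible probability, so each pass touches only the populated
// band of the Gaussian rows.
//
// Terminates when the double-bound gap drops below tol, or when the
// lower bound has improved by less than value_tol over the last 50
// iterations (value_tol = 0 disables the plateau rule).
//
// [[Rcpp::export]]
List ba_iterate_cpp(NumericMatrix Ft, IntegerVector lo, IntegerVector hi,
                    NumericVector Hneg, NumericVector w,
                    double s, NumericVector p0, double tol, int max_iter,
                    double beta, double value_tol) {
  const int M = Ft.nrow(), K = Ft.ncol();
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> q(M), lq(M), r(K);
  const double ln2 = std::log(2.0);
  const double* Fp = REAL(Ft);
  double lb = 0.0, ub = 0.0, gap = R_PosInf, lb_prev = R_NegInf;
  double bet = beta;
  int it = 0;
  std::vector<double> lb_hist;

  while (it < max_iter) {
    ++it;
    std::fill(q.begin(), q.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double pk = p[k];
      if (pk <= 0.0) continue;
      const double* col = Fp + (size_t) k * M;
      for (int n = lo[k]; n <= hi[k]; ++n) q[n] += pk * col[n];
    }
    for (int n = 0; n < M; ++n)
      lq[n] = q[n] > 0.0 ? std::log(q[n]) / ln2 : 0.0;
    ub = R_NegInf; lb = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* col = Fp + (size_t) k * M;
      double acc = 0.0;
      for (int n = lo[k]; n <= hi[k]; ++n) acc += col[n] * lq[n];
      r[k] = Hneg[k] - acc - s * w[k];
      if (r[k] > ub) ub = r[k];
      lb += p[k] * r[k];
    }
    gap = ub - lb;
    if (gap < tol) break;
    if (value_tol > 0.0) {
      lb_hist.push_back(lb);
      size_t m = lb_hist.size();
      if (m >= 50 && lb - lb_hist[m - 50] < value_tol) break;
    }
    if (bet > 1.0 && lb < lb_prev) bet = 1.0;
    lb_prev = lb;
    double Z = 0.0;
    for (int k = 0; k < K; ++k) {
      p[k] *= std::exp(ln2 * bet * (r[k] - ub));
      Z += p[k];
    }
    for (int k = 0; k < K; ++k) p[k] /= Z;
  }

  double Wp = 0.0;
  for (int k = 0; k < K; ++k) Wp += p[k] * w[k];
  return List::create(
    _["p"] = NumericVector(p.begin(), p.end()),
    _["value"] = lb, _["I"] = lb + s * Wp, _["W"] = Wp,
    _["gap"] = gap, _["iterations"] = it, _["converged"] = gap < tol);
}
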