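#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-kernel density accumulation on the integer column grid.
// `kernel` holds dnorm(-K..K, sd = h); contributions beyond +-K are dropped
// (mass < 1e-8 of a kernel at K = 6h). Identical truncation is used for
// observed and null profiles so the test statistic is comparable.

static void accumulate(const int* pos, int n, int L, const double* kern,
                       int K, double scale, double* d) {
  for (int i = 0; i < n; ++i) {
    int p = pos[i];
    int lo = p - K < 1 ? 1 : p - K;
    int hi = p + K > L ? L : p + K;
    for (int x = lo; x <= hi; ++x) d[x - 1] += scale * kern[x - p + K];
  }
}

// [[Rcpp::export]]
NumericVector cpp_density_profile(IntegerVector positions, int L,
                                  NumericVector kernel, double scale) {
  int K = (kernel.size() - 1) / 2;
  NumericVector d(L);
  accumulate(INTEGER(positions), positions.size(), L, REAL(kernel), K,
             scale, REAL(d));
  return d;
}

// Per-simulation maxima of the relative-density statistic. Position matrices
// are n_b x nSim (one column per simulation). Densities are scaled by
// 1/n_total; the relative density of branch b is d_b / max(sum of the other
// two, eps).
// [[Rcpp::export]]
NumericMatrix cpp_null_maxima(IntegerMatrix pos1, IntegerMatrix pos2,
                              IntegerMatrix pos3, int L,
                              NumericVector kernel, double eps,
                              double invNtot) {
  int nSim = pos1.ncol();
  if (pos2.ncol() != nSim || pos3.ncol() != nSim)
    stop("position matrices disagree in simulation count");
  int K = (kernel.size() - 1) / 2;
  const double* kern = REAL(kernel);
  NumericMatrix out(nSim, 3);
  std::vector<double> d1(L), d2(L), d3(L);
  for (int s = 0; s < nSim; ++s) {
    std::fill(d1.begin(), d1.end(), 0.0);
    std::fill(d2.begin(), d2.end(), 0.0);
    std::fill(d3.begin(), d3.end(), 0.0);
    accumulate(&pos1(0, s), pos1.nrow(), L, kern, K, invNtot, d1.data());
    accumulate(&pos2(0, s), pos2.nrow(), L, kern, K, invNtot, d2.data());
    accumulate(&pos3(0, s), pos3.nrow(), L, kern, K, invNtot, d3.data());
    double m1 = 0, m2 = 0, m3 = 0;
    for (int x = 0; x < L; ++x) {
      double den1 = d2[x] + d3[x]; if (den1 < eps) den1 = eps;
      double den2 = d1[x] + d3[x]; if (den2 < eps) den2 = eps;
      double den3 = d1[x] + d2[x]; if (den3 < eps) den3 = eps;
      double r1 = d1[x] / den1, r2 = d2[x] / den2, r3 = d3[x] / den3;
      if (r1 > m1) m1 = r1;
      if (r2 > m2) m2 = r2;
      if (r3 > m3) m3 = r3;
    }
    out(s, 0) = m1; out(s, 1) = m2; out(s, 2) = m3;
  }
  return out;
}
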