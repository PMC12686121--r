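#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Maximal information coefficient for a numeric feature against a binary
// label. With the label axis fixed at its two natural rows, the MINE search
// over x*y grids with x*y <= B = n^alpha reduces to maximising mutual
// information over x-axis partitions with at most floor(B/2) bins; the
// normaliser log2(min(kx, 2)) is then 1 bit. The partition maximisation is
// done exactly by dynamic programming over tie-respecting clumps of sorted x
// (clumps are pre-merged to at most c * kmax superclumps, as in ApproxMaxMI,
// before the DP).

static inline double plogp_term(double n1, double n0) {
  // contribution of one bin to  -n * H(Y | bin assignment)
  const double nb = n1 + n0;
  double s = 0.0;
  if (n1 > 0) s += n1 * std::log2(n1 / nb);
  if (n0 > 0) s += n0 * std::log2(n0 / nb);
  return s;
}

// [[Rcpp::export(name = ".mic_binary_cpp")]]
double mic_binary_cpp(NumericVector x, IntegerVector y, double alpha = 0.6,
                      double c = 5.0) {
  const int n = x.size();
  if (n != y.size()) stop("x and y lengths differ");
  if (n < 2) return 0.0;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  // tie-respecting clumps along sorted x
  std::vector<double> c1, c0;
  double last = x[ord[0]];
  c1.push_back(0.0);
  c0.push_back(0.0);
  for (int i = 0; i < n; ++i) {
    const int idx = ord[i];
    if (x[idx] != last) {
      c1.push_back(0.0);
      c0.push_back(0.0);
      last = x[idx];
    }
    if (y[idx] == 1) c1.back() += 1.0; else c0.back() += 1.0;
  }
  if (c1.size() == 1) return 0.0;  // constant feature

  const double B = std::max(4.0, std::pow((double)n, alpha));
  const int kmax = std::max(2, (int)std::floor(B / 2.0));

  // pre-merge clumps to at most c * kmax superclumps (equal-frequency,
  // never splitting ties)
  const int max_clumps = std::max(2, (int)std::floor(c * kmax));
  if ((int)c1.size() > max_clumps) {
    std::vector<double> m1, m0;
    const double target = (double)n / max_clumps;
    double acc = 0.0;
    m1.push_back(0.0);
    m0.push_back(0.0);
    for (size_t j = 0; j < c1.size(); ++j) {
      const double w = c1[j] + c0[j];
      if (acc >= target && m1.size() < (size_t)max_clumps &&
          (m1.back() + m0.back()) > 0) {
        m1.push_back(0.0);
        m0.push_back(0.0);
        acc = 0.0;
      }
      m1.back() += c1[j];
      m0.back() += c0[j];
      acc += w;
    }
    c1.swap(m1);
    c0.swap(m0);
  }

  const int C = (int)c1.size();
  std::vector<double> p1(C + 1, 0.0), p0(C + 1, 0.0);
  for (int j = 0; j < C; ++j) {
    p1[j + 1] = p1[j] + c1[j];
    p0[j + 1] = p0[j] + c0[j];
  }
  const double n1 = p1[C], n0 = p0[C];
  double hy = 0.0;  // H(Y) in bits
  if (n1 > 0) hy -= (n1 / n) * std::log2(n1 / n);
  if (n0 > 0) hy -= (n0 / n) * std::log2(n0 / n);
  if (hy == 0.0) return 0.0;  // constant label

  const int K = std::min(kmax, C);
  const double NEG = -1e300;
  // f[t][i]: max over partitions of first i clumps into exactly t bins of
  // sum over bins of -n_b * H(Y|b)
  std::vector<std::vector<double> > f(K + 1,
                                      std::vector<double>(C + 1, NEG));
  for (int i = 1; i <= C; ++i)
    f[1][i] = plogp_term(p1[i], p0[i]);
  double best = f[1][C];
  for (int t = 2; t <= K; ++t) {
    for (int i = t; i <= C; ++i) {
      double m = NEG;
      for (int j = t - 1; j < i; ++j) {
        if (f[t - 1][j] == NEG) continue;
        const double v = f[t - 1][j] + plogp_term(p1[i] - p1[j], p0[i] - p0[j]);
        if (v > m) m = v;
      }
      f[t][i] = m;
    }
    if (f[t][C] > best) best = f[t][C];
  }

  double mic = hy + best / n;  // I = H(Y) - H(Y|X); normaliser is 1 bit
  if (mic < 0.0) mic = 0.0;
  if (mic > 1.0) mic = 1.0;
  return mic;
}
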