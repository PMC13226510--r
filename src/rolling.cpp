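#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Causal trailing-window statistics. Window at position i (1-based in R)
// covers samples [max(0, i - w + 1), i]: expanding during warm-up, length w
// afterwards. Returns an n x 4 matrix: mean, min, max, sample SD (0 when
// the window holds a single sample).
// [[Rcpp::export]]
NumericMatrix roll_stats_cpp(NumericVector x, int w) {
  const int n = x.size();
  NumericMatrix out(n, 4);
  // prefix sums in long double to keep the sliding mean/SD exact enough
  std::vector<long double> s(n + 1, 0.0L), ss(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + (long double)x[i];
    ss[i + 1] = ss[i] + (long double)x[i] * (long double)x[i];
  }
  std::deque<int> qmin, qmax;
  for (int i = 0; i < n; ++i) {
    int lo = i - w + 1;
    if (lo < 0) lo = 0;
    while (!qmin.empty() && qmin.front() < lo) qmin.pop_front();
    while (!qmax.empty() && qmax.front() < lo) qmax.pop_front();
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmin.push_back(i);
    qmax.push_back(i);
    const int m = i - lo + 1;
    const long double sum = s[i + 1] - s[lo];
    const long double sumsq = ss[i + 1] - ss[lo];
    const long double mean = sum / m;
    out(i, 0) = (double)mean;
    out(i, 1) = x[qmin.front()];
    out(i, 2) = x[qmax.front()];
    if (m > 1) {
      long double var = (sumsq - sum * sum / m) / (m - 1);
      out(i, 3) = var > 0 ? (double)std::sqrt((double)var) : 0.0;
    } else {
      out(i, 3) = 0.0;
    }
  }
  return out;
}
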