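#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter (a[0] assumed 1 after normalization).
// [[Rcpp::export]]
NumericVector iir_df2t(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size();
  int nw = std::max(nb, na) - 1;
  double a0 = a[0];
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  std::vector<double> w(nw, 0.0);
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k)
      w[k] = bb[k + 1] * xi + w[k + 1] - aa[k + 1] * yi;
    if (nw > 0)
      w[nw - 1] = bb[nw] * xi - aa[nw] * yi;
    y[i] = yi;
  }
  return y;
}

// Higher-order Hinkley jump detector core.
//
// Scans x for alternating jumps between `closed` and `open`.  In each arm the
// sample is normalized to z = (x - base) / (target - base); the order-1
// statistic is the classic cumulative sum of (z - 1/2) clipped at zero, and
// each higher order accumulates the previous one, all resetting whenever the
// order-1 statistic touches zero.  A jump fires when the order-p statistic
// reaches threshold h, and is placed at the most recent zero of the order-1
// statistic; the detector then re-arms toward the other level from that point.
//
// Returns 0-based sample indices at which the state changes (first event is
// assumed closed; a trace that starts open yields a transition at/near 0).
// [[Rcpp::export]]
IntegerVector hohd_core(NumericVector x, double closed, double open,
                        int order, double h) {
  int n = x.size();
  if (order < 1) stop("order must be >= 1");
  std::vector<int> trans;
  std::vector<double> g(order + 1, 0.0);
  bool toward_open = true;       // currently at closed level, watching for open
  int last_zero = -1;            // last index with g1 == 0
  double span = open - closed;
  if (span == 0.0) return IntegerVector(0);
  int i = 0;
  while (i < n) {
    double base = toward_open ? closed : open;
    double tgt  = toward_open ? open : closed;
    double z = (x[i] - base) / (tgt - base);
    double g1 = g[1] + (z - 0.5);
    if (g1 <= 0.0) {
      for (int k = 1; k <= order; ++k) g[k] = 0.0;
      last_zero = i;
    } else {
      g[1] = g1;
      for (int k = 2; k <= order; ++k) g[k] += g[k - 1];
    }
    if (g[order] >= h && g[1] > 0.0) {
      int jump = last_zero + 1;             // first sample of the new state
      if (!trans.empty() && jump <= trans.back()) jump = trans.back() + 1;
      if (jump > n - 1) jump = n - 1;
      trans.push_back(jump);
      toward_open = !toward_open;
      for (int k = 1; k <= order; ++k) g[k] = 0.0;
      last_zero = jump - 1;
      i = jump;                              // rescan post-jump samples in new arm
      continue;
    }
    ++i;
  }
  return wrap(trans);
}
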