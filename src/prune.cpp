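#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for the k-state Mk model with closed-form transition
// probabilities. Transition rows are uniform off-diagonal, so P %*% L
// reduces to pdiff * colsum + e * L with e = exp(-k d / (k-1)).
//
// postorder: internal node ids (1-based), children-before-parents, root last
// child_ptr: 0-based offsets into child_ids, length = length(postorder) + 1
// child_ids: child node ids (1-based) grouped per postorder entry
// edlen:     expected substitutions on the edge above each node (root: unused)
// tippart:   (ntip * k) x nchar tip partials, tip t occupies rows
//            (t-1)*k .. t*k-1 (0-based)
// Returns the per-character log-likelihood (root frequencies 1/k).
// [[Rcpp::export]]
NumericVector mk_prune_kernel(IntegerVector postorder, IntegerVector child_ptr,
                              IntegerVector child_ids, NumericVector edlen,
                              NumericMatrix tippart, int k, int ntip,
                              int nnode) {
  const int nchar = tippart.ncol();
  const int npost = postorder.size();
  std::vector<double> part((size_t)nnode * k * nchar, 0.0);
  std::vector<double> logscale(nchar, 0.0);
  std::vector<char> istip(nnode + 1, 0);
  for (int t = 1; t <= ntip; ++t) istip[t] = 1;

  // copy tip partials into the node buffer
  for (int t = 0; t < ntip; ++t)
    for (int c = 0; c < nchar; ++c)
      for (int s = 0; s < k; ++s)
        part[((size_t)t * k + s) * nchar + c] = tippart(t * k + s, c);

  std::vector<double> acc((size_t)k * nchar);
  for (int i = 0; i < npost; ++i) {
    const int v = postorder[i];  // 1-based
    std::fill(acc.begin(), acc.end(), 1.0);
    for (int j = child_ptr[i]; j < child_ptr[i + 1]; ++j) {
      const int c = child_ids[j];  // 1-based
      const double d = edlen[c - 1];
      const double e = std::exp(-(double)k * d / (k - 1.0));
      const double pdiff = (1.0 - e) / k;
      const double *L = &part[(size_t)(c - 1) * k * nchar];
      for (int ch = 0; ch < nchar; ++ch) {
        double s = 0.0;
        for (int st = 0; st < k; ++st) s += L[(size_t)st * nchar + ch];
        const double base = pdiff * s;
        for (int st = 0; st < k; ++st)
          acc[(size_t)st * nchar + ch] *= base + e * L[(size_t)st * nchar + ch];
      }
    }
    double *out = &part[(size_t)(v - 1) * k * nchar];
    for (int ch = 0; ch < nchar; ++ch) {
      double m = 0.0;
      for (int st = 0; st < k; ++st) {
        const double val = acc[(size_t)st * nchar + ch];
        if (val > m) m = val;
      }
      if (m > 0.0 && m != 1.0) {
        for (int st = 0; st < k; ++st)
          out[(size_t)st * nchar + ch] = acc[(size_t)st * nchar + ch] / m;
        logscale[ch] += std::log(m);
      } else {
        for (int st = 0; st < k; ++st)
          out[(size_t)st * nchar + ch] = acc[(size_t)st * nchar + ch];
      }
    }
  }

  const int root = postorder[npost - 1];
  NumericVector ll(nchar);
  const double *R = &part[(size_t)(root - 1) * k * nchar];
  for (int ch = 0; ch < nchar; ++ch) {
    double s = 0.0;
    for (int st = 0; st < k; ++st) s += R[(size_t)st * nchar + ch];
    ll[ch] = std::log(s / k) + logscale[ch];
  }
  return ll;
}

// Same pruning pass, but returns the root-node partial likelihoods
// (k x nchar, scaled; scale factors cancel on normalization), used for
// conditional state sampling at a focal node after re-rooting there.
// [[Rcpp::export]]
NumericMatrix mk_prune_partials(IntegerVector postorder,
                                IntegerVector child_ptr,
                                IntegerVector child_ids, NumericVector edlen,
                                NumericMatrix tippart, int k, int ntip,
                                int nnode) {
  const int nchar = tippart.ncol();
  const int npost = postorder.size();
  std::vector<double> part((size_t)nnode * k * nchar, 0.0);
  for (int t = 0; t < ntip; ++t)
    for (int c = 0; c < nchar; ++c)
      for (int s = 0; s < k; ++s)
        part[((size_t)t * k + s) * nchar + c] = tippart(t * k + s, c);

  std::vector<double> acc((size_t)k * nchar);
  for (int i = 0; i < npost; ++i) {
    const int v = postorder[i];
    std::fill(acc.begin(), acc.end(), 1.0);
    for (int j = child_ptr[i]; j < child_ptr[i + 1]; ++j) {
      const int c = child_ids[j];
      const double d = edlen[c - 1];
      const double e = std::exp(-(double)k * d / (k - 1.0));
      const double pdiff = (1.0 - e) / k;
      const double *L = &part[(size_t)(c - 1) * k * nchar];
      for (int ch = 0; ch < nchar; ++ch) {
        double s = 0.0;
        for (int st = 0; st < k; ++st) s += L[(size_t)st * nchar + ch];
        const double base = pdiff * s;
        for (int st = 0; st < k; ++st)
          acc[(size_t)st * nchar + ch] *= base + e * L[(size_t)st * nchar + ch];
      }
    }
    double *out = &part[(size_t)(v - 1) * k * nchar];
    for (int ch = 0; ch < nchar; ++ch) {
      double m = 0.0;
      for (int st = 0; st < k; ++st) {
        const double val = acc[(size_t)st * nchar + ch];
        if (val > m) m = val;
      }
      const double div = (m > 0.0) ? m : 1.0;
      for (int st = 0; st < k; ++st)
        out[(size_t)st * nchar + ch] = acc[(size_t)st * nchar + ch] / div;
    }
  }

  const int root = postorder[npost - 1];
  NumericMatrix res(k, nchar);
  const double *R = &part[(size_t)(root - 1) * k * nchar];
  for (int ch = 0; ch < nchar; ++ch)
    for (int st = 0; st < k; ++st) res(st, ch) = R[(size_t)st * nchar + ch];
  return res;
}
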