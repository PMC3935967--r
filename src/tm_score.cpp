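// TM-score superposition search for equal-length CA traces.
//
// Every contiguous window of length >= 4 seeds a least-squares
// superposition (Kabsch) that is iteratively refined on the residues
// within the distance cutoff; the best full-chain TM sum over all seeds is
// returned. The seed set is exhaustive because scrambled models can have
// narrow superposition basins reachable only from one specific window;
// at C speed this costs a few ms per call for chains under ~100 residues.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// distances of all rows of `mob` to `fix` after superposing on rows `idx`
static vec fit_distances(const mat& mob, const mat& fix, const uvec& idx) {
  mat a = mob.rows(idx);
  mat b = fix.rows(idx);
  rowvec ca = mean(a, 0), cb = mean(b, 0);
  a.each_row() -= ca;
  b.each_row() -= cb;
  mat u, v;
  vec s;
  svd(u, s, v, a.t() * b);
  mat r = v * diagmat(vec({1.0, 1.0, det(v * u.t()) > 0 ? 1.0 : -1.0})) * u.t();
  mat moved = (mob.each_row() - ca) * r.t();
  moved.each_row() += cb;
  return sqrt(sum(square(moved - fix), 1));
}

static double tm_sum(const vec& d, double d0) {
  return mean(1.0 / (1.0 + square(d / d0)));
}

static double refine_seed(const mat& mob, const mat& fix, uvec idx,
                          double d0, int max_iter) {
  double best = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    vec d = fit_distances(mob, fix, idx);
    double sc = tm_sum(d, d0);
    if (sc > best) best = sc;
    double dcut = std::max(d0, 3.0);
    uvec nxt = find(d < dcut);
    while (nxt.n_elem < 3 && dcut < 50.0) {
      dcut += 0.5;
      nxt = find(d < dcut);
    }
    if (nxt.n_elem < 3 || (nxt.n_elem == idx.n_elem &&
                           all(nxt == idx))) break;
    idx = nxt;
  }
  return best;
}

// [[Rcpp::export(name = ".tm_score_search")]]
double tm_score_search(const arma::mat& mobile, const arma::mat& fixed,
                       double d0, int max_iter = 20) {
  const int l = mobile.n_rows;
  double best = 0.0;
  for (int sl = 4; sl <= l; ++sl) {
    for (int s = 0; s <= l - sl; ++s) {
      uvec idx = regspace<uvec>(s, s + sl - 1);
      double sc = refine_seed(mobile, fixed, idx, d0, max_iter);
      if (sc > best) best = sc;
    }
  }
  return best;
}
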