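// Nearest-neighbour and locally weighted regression kernels for the EDM
// (empirical dynamic modelling) layer.  Row index == time index: series are
// evenly spaced, so temporal exclusion is an index-difference test.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double WEIGHT_FLOOR_FRAC = 1e-6;  // floor relative to max weight

// Euclidean distance between rows a and b of `block`; both assumed finite.
static inline double row_dist(const arma::mat& block, arma::uword a, arma::uword b) {
  double s = 0.0;
  for (arma::uword j = 0; j < block.n_cols; ++j) {
    double d = block(a, j) - block(b, j);
    s += d * d;
  }
  return std::sqrt(s);
}

// For each prediction row, find the k nearest library rows (excluding the
// row itself and any library row within `exclusion_radius` time steps) and
// return exponential simplex weights w_i = exp(-d_i / d_1).  Zero nearest
// distance: tied zero-distance neighbours share equal weight and all others
// drop to the weight floor.  Rows with fewer than k admissible neighbours
// get NA entries.
// [[Rcpp::export]]
List simplex_neighbours_cpp(const arma::mat& block,
                            const IntegerVector& lib,
                            const IntegerVector& pred,
                            const int k,
                            const int exclusion_radius) {
  const int npred = pred.size();
  const int nlib = lib.size();
  IntegerMatrix ind(npred, k);
  NumericMatrix wt(npred, k);
  std::fill(ind.begin(), ind.end(), NA_INTEGER);
  std::fill(wt.begin(), wt.end(), NA_REAL);

  std::vector<std::pair<double, int> > cand;
  cand.reserve(nlib);

  for (int p = 0; p < npred; ++p) {
    const int pt = pred[p];          // 1-based time index
    cand.clear();
    for (int l = 0; l < nlib; ++l) {
      const int lt = lib[l];
      if (lt == pt) continue;                          // leave-one-out
      if (std::abs(lt - pt) <= exclusion_radius) continue;
      double d = row_dist(block, (arma::uword)(pt - 1), (arma::uword)(lt - 1));
      cand.push_back(std::make_pair(d, lt));
    }
    if ((int)cand.size() < k) continue;
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    const double d1 = cand[0].first;
    double wmax = 0.0;
    std::vector<double> w(k);
    for (int j = 0; j < k; ++j) {
      if (d1 > 0.0) {
        w[j] = std::exp(-cand[j].first / d1);
      } else {
        w[j] = (cand[j].first == 0.0) ? 1.0 : 0.0;
      }
      if (w[j] > wmax) wmax = w[j];
    }
    for (int j = 0; j < k; ++j) {
      double wj = std::max(w[j], WEIGHT_FLOOR_FRAC * wmax);
      ind(p, j) = cand[j].second;
      wt(p, j) = wj;
    }
  }
  return List::create(_["ind"] = ind, _["w"] = wt);
}

// S-map: one locally weighted linear regression (intercept included) per
// query point, weights exp(-theta * d / dbar) with dbar the mean distance
// from the query to the admissible library rows.  Solved by SVD
// pseudo-inverse so rank-deficient (e.g. constant-column) designs are
// handled.  query_time < 0 disables temporal exclusion for that query.
// [[Rcpp::export]]
List smap_predict_cpp(const arma::mat& libX,
                      const arma::vec& libY,
                      const arma::ivec& lib_time,
                      const arma::mat& queries,
                      const arma::ivec& query_time,
                      const double theta,
                      const int exclusion_radius) {
  const arma::uword m = queries.n_rows;
  const arma::uword nlib = libX.n_rows;
  const arma::uword d = libX.n_cols;
  arma::vec pred(m);
  pred.fill(arma::datum::nan);
  arma::mat coef(m, d + 1);
  coef.fill(arma::datum::nan);
  LogicalVector ok(m, false);

  for (arma::uword q = 0; q < m; ++q) {
    const int qt = query_time(q);
    std::vector<arma::uword> use;
    use.reserve(nlib);
    for (arma::uword l = 0; l < nlib; ++l) {
      if (qt >= 0 && std::abs((int)lib_time(l) - qt) <= exclusion_radius) continue;
      use.push_back(l);
    }
    const arma::uword n = use.size();
    if (n < d + 2) continue;

    arma::vec dist(n);
    for (arma::uword i = 0; i < n; ++i) {
      double s = 0.0;
      for (arma::uword j = 0; j < d; ++j) {
        double dd = libX(use[i], j) - queries(q, j);
        s += dd * dd;
      }
      dist(i) = std::sqrt(s);
    }
    double dbar = arma::mean(dist);
    arma::vec w(n);
    if (dbar <= 0.0 || theta == 0.0) {
      w.ones();
    } else {
      w = arma::exp(-theta * dist / dbar);
    }
    double wsum = arma::accu(w);
    if (!(wsum > 1e-12)) continue;  // degenerate weighting

    arma::mat A(n, d + 1);
    arma::vec b(n);
    for (arma::uword i = 0; i < n; ++i) {
      A(i, 0) = w(i);
      for (arma::uword j = 0; j < d; ++j) A(i, j + 1) = w(i) * libX(use[i], j);
      b(i) = w(i) * libY(use[i]);
    }
    arma::vec beta;
    bool solved = false;
    try {
      arma::mat Ainv = arma::pinv(A);
      beta = Ainv * b;
      solved = beta.is_finite();
    } catch (...) {
      solved = false;
    }
    if (!solved) continue;

    double yhat = beta(0);
    for (arma::uword j = 0; j < d; ++j) yhat += beta(j + 1) * queries(q, j);
    pred(q) = yhat;
    coef.row(q) = beta.t();
    ok(q) = true;
  }
  return List::create(_["pred"] = pred, _["coef"] = coef, _["ok"] = ok);
}
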