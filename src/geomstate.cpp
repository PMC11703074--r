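// Hot loops of the circularity pipeline: stratified-bootstrap condition
// means, per-window standardization, top-2 PCA scores via the k x k Gram
// matrix, and the polygon circularity. Used by the time-course engine,
// the label-shuffle permutation null and the searchlight. Randomness goes
// through R's RNG so set.seed() governs everything.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// circularity 4*pi*A/P^2 of ordered 2D vertices (rows of V)
static double circ_from_scores(const arma::mat& V) {
  const int n = V.n_rows;
  double area = 0.0, per = 0.0;
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    area += V(i, 0) * V(j, 1) - V(j, 0) * V(i, 1);
    const double dx = V(j, 0) - V(i, 0), dy = V(j, 1) - V(i, 1);
    per += std::sqrt(dx * dx + dy * dy);
  }
  area = 0.5 * std::fabs(area);
  if (per <= 0.0) return 0.0;
  return 4.0 * M_PI * area / (per * per);
}

// condition matrix (k conditions x channels, rows in polygon order) ->
// z-score columns (zero-variance -> 0) -> top-2 PCA scores -> circularity
static double circ_condmat(arma::mat x) {
  const int k = x.n_rows;
  if (k < 3) return NA_REAL;
  arma::rowvec mu = arma::mean(x, 0);
  x.each_row() -= mu;
  arma::rowvec sd = arma::sqrt(arma::sum(arma::square(x), 0) / (k - 1));
  for (arma::uword c = 0; c < x.n_cols; ++c) {
    if (sd(c) > 0) x.col(c) /= sd(c); else x.col(c).zeros();
  }
  arma::mat g = x * x.t();
  arma::vec eval; arma::mat evec;
  if (!arma::eig_sym(eval, evec, g)) return NA_REAL;
  arma::mat V(k, 2);
  for (int a = 0; a < 2; ++a) {
    double lam = eval(k - 1 - a);
    if (lam < 0) lam = 0;
    V.col(a) = evec.col(k - 1 - a) * std::sqrt(lam);
  }
  return circ_from_scores(V);
}

// [[Rcpp::export(name = "cpp_condmat_circularity")]]
double cpp_condmat_circularity(const arma::mat& x) {
  return circ_condmat(x);
}

// mean circularity per window over stratified bootstrap resamples.
// M: trials x (n_ch * nw); lab: 0-based condition index per trial.
static arma::vec curve_resampled(const arma::mat& M,
                                 const std::vector<std::vector<int> >& bycond,
                                 const arma::ivec& lab, int k, int n_ch,
                                 int n_resamples) {
  const int nw = M.n_cols / n_ch;
  const int n = M.n_rows;
  arma::vec counts(k, arma::fill::zeros);
  for (int t = 0; t < n; ++t) counts(lab(t)) += 1.0;
  arma::vec acc(nw, arma::fill::zeros);
  arma::mat cs(k, M.n_cols);
  for (int r = 0; r < n_resamples; ++r) {
    cs.zeros();
    for (int c = 0; c < k; ++c) {
      const std::vector<int>& ii = bycond[c];
      const int m = ii.size();
      for (int t = 0; t < m; ++t) {
        const int pick = ii[(int)(unif_rand() * m) % m];
        cs.row(c) += M.row(pick);
      }
    }
    cs.each_col() /= counts;
    for (int w = 0; w < nw; ++w)
      acc(w) += circ_condmat(cs.cols(w * n_ch, (w + 1) * n_ch - 1));
  }
  return acc / n_resamples;
}

static std::vector<std::vector<int> > split_by_cond(const arma::ivec& lab, int k) {
  std::vector<std::vector<int> > bycond(k);
  for (arma::uword t = 0; t < lab.n_elem; ++t) bycond[lab(t)].push_back(t);
  return bycond;
}

// [[Rcpp::export(name = "cpp_tc_curve")]]
arma::vec cpp_tc_curve(const arma::mat& M, const arma::ivec& lab, int k,
                       int n_ch, int n_resamples) {
  return curve_resampled(M, split_by_cond(lab, k), lab, k, n_ch, n_resamples);
}

// [[Rcpp::export(name = "cpp_perm_null")]]
arma::mat cpp_perm_null(const arma::mat& M, const arma::ivec& lab, int k,
                        int n_ch, int n_perm, int n_resamples) {
  const int nw = M.n_cols / n_ch;
  const int n = M.n_rows;
  arma::mat out(n_perm, nw);
  arma::ivec sh = lab;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {          // Fisher-Yates via R's RNG
      const int j = (int)(unif_rand() * (i + 1)) % (i + 1);
      std::swap(sh(i), sh(j));
    }
    out.row(p) = curve_resampled(M, split_by_cond(sh, k), sh, k, n_ch,
                                 n_resamples).t();
  }
  return out;
}

// searchlight: condition means cm (conditions x voxels, rows in polygon
// order); spheres: list of 1-based voxel index vectors; returns C per sphere
// (NA when the sphere has fewer than 3 voxels)
// [[Rcpp::export(name = "cpp_sphere_circularity")]]
NumericVector cpp_sphere_circularity(const arma::mat& cm, const List& spheres) {
  const int ns = spheres.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector nb = spheres[s];
    if (nb.size() < 3) { out[s] = NA_REAL; continue; }
    arma::uvec idx(nb.size());
    for (int i = 0; i < nb.size(); ++i) idx(i) = nb[i] - 1;
    out[s] = circ_condmat(cm.cols(idx));
  }
  return out;
}
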