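#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Distances below this are reported as exactly zero (numerical floor).
static const double DIST_FLOOR = 1e-9;

// Residue-order permutations, lexicographic; first index wins on ties.
static const int PERM2[2][2] = {{0, 1}, {1, 0}};
static const int PERM3[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

// Core least-squares distance between two N x 3 point sets under optimal
// proper rotation + translation, scale fixed to 1. Rows are points.
// If Rout/tout are non-null the optimal transform is returned.
static double ls_core(const arma::mat& X, const arma::mat& Y,
                      arma::mat* Rout, arma::rowvec* tout) {
  arma::rowvec xbar = arma::mean(X, 0);
  arma::rowvec ybar = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - xbar;
  arma::mat Yc = Y.each_row() - ybar;
  arma::mat H = Yc.t() * Xc;  // sum over points of y' x'^T
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failed in least-squares superposition");
  double sgn = (arma::det(V * U.t()) < 0.0) ? -1.0 : 1.0;
  arma::vec d = {1.0, 1.0, sgn};
  double tr = arma::dot(s, d);
  double magnitude = arma::accu(Xc % Xc) + arma::accu(Yc % Yc);
  double ss = magnitude - 2.0 * tr;
  // cancellation floor: residuals indistinguishable from rounding are zero
  if (ss < 1e-12 * magnitude) ss = 0.0;
  double dist = std::sqrt(ss);
  if (dist < DIST_FLOOR) dist = 0.0;
  if (Rout != nullptr) {
    arma::mat R = V * arma::diagmat(d) * U.t();
    *Rout = R;
    if (tout != nullptr) *tout = xbar - ybar * R.t();
  }
  return dist;
}

// Permute whole residues (blocks of n consecutive rows) of X.
static arma::mat permute_blocks(const arma::mat& X, const int* perm, int m,
                                int n) {
  arma::mat P(X.n_rows, 3);
  for (int i = 0; i < m; ++i)
    P.rows(i * n, i * n + n - 1) = X.rows(perm[i] * n, perm[i] * n + n - 1);
  return P;
}

static double dss_core(const arma::mat& X, const arma::mat& Y, int m, int n,
                       int* best) {
  int nperm = (m == 2) ? 2 : 6;
  double dmin = R_PosInf;
  int bi = 0;
  for (int p = 0; p < nperm; ++p) {
    const int* perm = (m == 2) ? PERM2[p] : PERM3[p];
    double d = ls_core(permute_blocks(X, perm, m, n), Y, nullptr, nullptr);
    if (d < dmin) {  // strict: first permutation wins on exact ties
      dmin = d;
      bi = p;
    }
  }
  if (best != nullptr) *best = bi;
  return dmin;
}

// [[Rcpp::export]]
List cpp_ls_distance(const arma::mat& X, const arma::mat& Y) {
  if (X.n_rows != Y.n_rows || X.n_cols != 3 || Y.n_cols != 3)
    stop("point sets must be equal-size N x 3 matrices");
  arma::mat R;
  arma::rowvec t;
  double d = ls_core(X, Y, &R, &t);
  return List::create(_["d_ls"] = d, _["rotation"] = R,
                      _["translation"] = arma::vec(t.t()), _["scale"] = 1.0);
}

// [[Rcpp::export]]
List cpp_dss(const arma::mat& X, const arma::mat& Y, int m, int n) {
  int best = 0;
  double d = dss_core(X, Y, m, n, &best);
  int nperm = (m == 2) ? 2 : 6;
  IntegerVector perm(m);
  for (int i = 0; i < m; ++i)
    perm[i] = ((m == 2) ? PERM2[best][i] : PERM3[best][i]) + 1;
  return List::create(_["d_ss"] = d, _["permutation"] = perm,
                      _["n_evaluated"] = nperm);
}

// Symmetric matrix of d_SS over a list of (m*n) x 3 coordinate matrices.
// [[Rcpp::export]]
arma::mat cpp_dss_matrix(const List& coords, int m, int n) {
  int N = coords.size();
  std::vector<arma::mat> pts(N);
  for (int i = 0; i < N; ++i) pts[i] = as<arma::mat>(coords[i]);
  arma::mat D(N, N, arma::fill::zeros);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double d = dss_core(pts[i], pts[j], m, n, nullptr);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// Cross matrix: rows = query patches, cols = representative patches.
// [[Rcpp::export]]
arma::mat cpp_dss_cross(const List& queries, const List& reps, int m, int n) {
  int K = queries.size(), L = reps.size();
  std::vector<arma::mat> qs(K), rs(L);
  for (int i = 0; i < K; ++i) qs[i] = as<arma::mat>(queries[i]);
  for (int j = 0; j < L; ++j) rs[j] = as<arma::mat>(reps[j]);
  arma::mat D(K, L);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < L; ++j) D(i, j) = dss_core(qs[i], rs[j], m, n, nullptr);
  return D;
}
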