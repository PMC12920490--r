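// SIMPLS partial least squares with leave-one-out machinery.
//
// All cross-validation loops live here because the permutation null of the
// two-step procedure re-runs leave-one-out prediction hundreds of times per
// model; fold preparation (median imputation of missing cells, column
// z-scoring, response centering) is done inside every training fold so no
// information from a held-out row ever leaks into its own prediction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double TOL = 1e-12;

// Median of the finite entries of v (0 if none).
static double finite_median(const vec& v) {
  std::vector<double> f;
  f.reserve(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) {
    if (std::isfinite(v[i])) f.push_back(v[i]);
  }
  if (f.empty()) return 0.0;
  std::sort(f.begin(), f.end());
  size_t n = f.size();
  return (n % 2 == 1) ? f[n / 2] : 0.5 * (f[n / 2 - 1] + f[n / 2]);
}

// Impute NaNs with per-column training medians, then z-score columns.
// Zero-variance columns get sd = 1 (their z is 0, coefficient inert).
static void prep_train(const mat& X, mat& Z, rowvec& mu, rowvec& sd,
                       rowvec& med) {
  uword n = X.n_rows, p = X.n_cols;
  Z.set_size(n, p);
  mu.set_size(p); sd.set_size(p); med.set_size(p);
  for (uword j = 0; j < p; ++j) {
    vec col = X.col(j);
    med[j] = finite_median(col);
    for (uword i = 0; i < n; ++i) {
      if (!std::isfinite(col[i])) col[i] = med[j];
    }
    mu[j] = mean(col);
    double s = stddev(col);
    sd[j] = (s > TOL) ? s : 1.0;
    Z.col(j) = (col - mu[j]) / sd[j];
  }
}

static rowvec prep_row(const rowvec& x, const rowvec& mu, const rowvec& sd,
                       const rowvec& med) {
  rowvec z = x;
  for (uword j = 0; j < z.n_elem; ++j) {
    if (!std::isfinite(z[j])) z[j] = med[j];
    z[j] = (z[j] - mu[j]) / sd[j];
  }
  return z;
}

// SIMPLS (de Jong) on centered/scaled Z and centered y. Fills B (p x K)
// with the coefficient vector at each number of components 1..K; if the
// rank runs out early, later columns repeat the last valid one. Returns the
// effective number of components.
static int simpls(const mat& Z, const vec& yc, int K, mat& B,
                  bool* exhausted = nullptr) {
  uword p = Z.n_cols;
  B.zeros(p, K);
  vec s = Z.t() * yc;
  double s0 = std::max(norm(s), 1.0);
  mat V(p, K, fill::zeros), R(p, K, fill::zeros);
  vec q(K, fill::zeros);
  if (exhausted) *exhausted = false;
  int a = 0;
  for (; a < K; ++a) {
    // covariance exhausted: remaining components add nothing (benign)
    if (norm(s) < 1e-9 * s0) {
      if (exhausted) *exhausted = true;
      break;
    }
    vec r = s;
    vec t = Z * r;
    double nt = norm(t);
    if (nt < 1e-10) break;
    t /= nt; r /= nt;
    vec pl = Z.t() * t;
    double qa = dot(yc, t);
    vec v = pl;
    if (a > 0) v -= V.cols(0, a - 1) * (V.cols(0, a - 1).t() * pl);
    double nv = norm(v);
    if (nv < 1e-10) break;
    v /= nv;
    s -= v * dot(v, s);
    R.col(a) = r; V.col(a) = v; q[a] = qa;
    B.col(a) = R.cols(0, a) * q.subvec(0, a);
  }
  for (int k = a; k < K; ++k) {
    if (a > 0) B.col(k) = B.col(a - 1);
  }
  return a;
}

static double pearson(const vec& a, const vec& b) {
  double sa = stddev(a), sb = stddev(b);
  if (sa < TOL || sb < TOL) return 0.0;
  return as_scalar(cor(a, b));
}

// [[Rcpp::export]]
Rcpp::List cpp_simpls_fit(const arma::mat& Z, const arma::vec& yc, int K) {
  mat B;
  bool exhausted = false;
  int eff = simpls(Z, yc, K, B, &exhausted);
  return Rcpp::List::create(Rcpp::Named("coefficients") = B,
                            Rcpp::Named("n_effective") = eff,
                            Rcpp::Named("exhausted") = exhausted);
}

// Leave-one-out predictions at every 1..Kmax, fold-honest preparation.
// [[Rcpp::export]]
arma::mat cpp_loo_preds(const arma::mat& X, const arma::vec& y, int Kmax) {
  uword n = X.n_rows;
  mat preds(n, Kmax, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    mat Xtr = X; Xtr.shed_row(i);
    vec ytr = y; ytr.shed_row(i);
    mat Z; rowvec mu, sd, med;
    prep_train(Xtr, Z, mu, sd, med);
    double ym = mean(ytr);
    mat B;
    simpls(Z, ytr - ym, Kmax, B);
    rowvec zi = prep_row(X.row(i), mu, sd, med);
    preds.row(i) = zi * B + ym;
  }
  return preds;
}

// Inner-LOO mean squared error per number of components.
static vec inner_mse(const mat& X, const vec& y, int Kmax) {
  mat preds(X.n_rows, Kmax);
  uword n = X.n_rows;
  for (uword i = 0; i < n; ++i) {
    mat Xtr = X; Xtr.shed_row(i);
    vec ytr = y; ytr.shed_row(i);
    mat Z; rowvec mu, sd, med;
    prep_train(Xtr, Z, mu, sd, med);
    double ym = mean(ytr);
    mat B;
    simpls(Z, ytr - ym, Kmax, B);
    rowvec zi = prep_row(X.row(i), mu, sd, med);
    preds.row(i) = zi * B + ym;
  }
  vec mse(Kmax);
  for (int k = 0; k < Kmax; ++k) {
    mse[k] = mean(square(preds.col(k) - y));
  }
  return mse;
}

// Nested leave-one-out CV: the outer fold's K is picked by an inner LOO
// over the remaining n-1 rows (ties -> smallest K).
// [[Rcpp::export]]
Rcpp::List cpp_nested_cv(const arma::mat& X, const arma::vec& y, int Kmax) {
  uword n = X.n_rows;
  vec pred(n);
  ivec chosen(n);
  for (uword i = 0; i < n; ++i) {
    mat Xtr = X; Xtr.shed_row(i);
    vec ytr = y; ytr.shed_row(i);
    vec mse = inner_mse(Xtr, ytr, Kmax);
    int kbest = 0;
    for (int k = 1; k < Kmax; ++k) {
      if (mse[k] < mse[kbest] - TOL) kbest = k;
    }
    chosen[i] = kbest + 1;
    mat Z; rowvec mu, sd, med;
    prep_train(Xtr, Z, mu, sd, med);
    double ym = mean(ytr);
    mat B;
    simpls(Z, ytr - ym, kbest + 1, B);
    rowvec zi = prep_row(X.row(i), mu, sd, med);
    pred[i] = as_scalar(zi * B.col(kbest)) + ym;
  }
  return Rcpp::List::create(
      Rcpp::Named("predictions") = pred,
      Rcpp::Named("chosen_k") = chosen,
      Rcpp::Named("r") = pearson(y, pred));
}

// Permutation null of the out-of-sample correlation, reduced scheme:
// leave-one-out at a fixed K for every permuted response. `perms` holds
// 0-based row indices, one column per permutation.
// [[Rcpp::export]]
arma::vec cpp_perm_r_fixed_k(const arma::mat& X, const arma::vec& y, int K,
                             const arma::umat& perms) {
  uword n = X.n_rows, m = perms.n_cols;
  vec out(m);
  // fold preparations do not depend on y only through Xtr; cache them
  std::vector<mat> Zs(n);
  std::vector<rowvec> mus(n), sds(n), meds(n), zis(n);
  for (uword i = 0; i < n; ++i) {
    mat Xtr = X; Xtr.shed_row(i);
    prep_train(Xtr, Zs[i], mus[i], sds[i], meds[i]);
    zis[i] = prep_row(X.row(i), mus[i], sds[i], meds[i]);
  }
  for (uword s = 0; s < m; ++s) {
    vec yp = y(perms.col(s));
    vec pred(n);
    for (uword i = 0; i < n; ++i) {
      vec ytr = yp; ytr.shed_row(i);
      double ym = mean(ytr);
      mat B;
      simpls(Zs[i], ytr - ym, K, B);
      pred[i] = as_scalar(zis[i] * B.col(K - 1)) + ym;
    }
    out[s] = pearson(yp, pred);
  }
  return out;
}

// Permutation null of r, full scheme: the entire nested procedure is
// re-run on every permuted response.
// [[Rcpp::export]]
arma::vec cpp_perm_r_nested(const arma::mat& X, const arma::vec& y, int Kmax,
                            const arma::umat& perms) {
  uword m = perms.n_cols;
  vec out(m);
  for (uword s = 0; s < m; ++s) {
    vec yp = y(perms.col(s));
    Rcpp::List res = cpp_nested_cv(X, yp, Kmax);
    out[s] = Rcpp::as<double>(res["r"]);
  }
  return out;
}

// Null distribution of the final full-data weights: refit at fixed K for
// every permuted response. Rows of the result are permutations.
// [[Rcpp::export]]
arma::mat cpp_perm_weights(const arma::mat& X, const arma::vec& y, int K,
                           const arma::umat& perms) {
  mat Z; rowvec mu, sd, med;
  prep_train(X, Z, mu, sd, med);
  uword m = perms.n_cols, p = X.n_cols;
  mat out(m, p);
  for (uword s = 0; s < m; ++s) {
    vec yp = y(perms.col(s));
    vec yc = yp - mean(yp);
    mat B;
    simpls(Z, yc, K, B);
    out.row(s) = B.col(K - 1).t();
  }
  return out;
}
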