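#include <Rcpp.h>
using namespace Rcpp;

// Dirichlet-multinomial log-density terms shared by the likelihood and the
// samplers. All densities are computed in log space via lgamma; the
// multinomial coefficient log[T!/(prod x_i!)] is constant in all parameters
// and is added (when wanted) on the R side from a per-cell precomputed
// vector, so the C++ routines return
//   sum_i [lgamma(x_i + a_i) - lgamma(a_i)] + lgamma(|a|) - lgamma(T + |a|).
// Terms with x_i == 0 vanish and are skipped.

// [[Rcpp::export]]
NumericMatrix cc_dm_loglik_mat(const NumericMatrix& X,
                               const NumericMatrix& alpha,
                               const NumericVector& b) {
  const int F = X.nrow(), C = X.ncol(), K = alpha.nrow();
  if (alpha.ncol() != F) stop("alpha has %d columns but X has %d features",
                              alpha.ncol(), F);
  if (b.size() != C) stop("length(b) must equal ncol(X)");
  NumericMatrix out(C, K);
  std::vector<double> T(C, 0.0);
  for (int j = 0; j < C; ++j) {
    double t = 0.0;
    for (int i = 0; i < F; ++i) t += X(i, j);
    T[j] = t;
  }
  std::vector<double> S(K, 0.0);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int i = 0; i < F; ++i) s += alpha(k, i);
    S[k] = s;
  }
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < C; ++j) {
      const double bj = b[j];
      double acc = R::lgammafn(S[k] * bj) - R::lgammafn(T[j] + S[k] * bj);
      for (int i = 0; i < F; ++i) {
        const double x = X(i, j);
        if (x > 0) {
          const double a = alpha(k, i) * bj;
          acc += R::lgammafn(x + a) - R::lgammafn(a);
        }
      }
      out(j, k) = acc;
    }
  }
  return out;
}

// One Metropolis sweep over every element of the K x F Dirichlet parameter
// block for one source. Proposals are element-wise multiplicative log-normal
// random walks a' = a * exp(eps), eps ~ N(0, step^2); the acceptance
// log-ratio is the change in the complete log-posterior restricted to the
// cells currently assigned to the row's cluster, plus the proposal-asymmetry
// correction log(a'/a) = eps. Elements are visited sequentially, so |alpha|
// reflects earlier acceptances in the same sweep. Rows whose cluster is
// currently empty are frozen (no proposal counted).
// [[Rcpp::export]]
List cc_mh_alpha_sweep(const NumericMatrix& X,
                       const NumericMatrix& alpha,
                       const IntegerVector& z,
                       const NumericVector& b,
                       const double step,
                       const bool diagnostics) {
  const int F = X.nrow(), C = X.ncol(), K = alpha.nrow();
  if (z.size() != C) stop("length(z) must equal ncol(X)");
  NumericMatrix A = clone(alpha);
  std::vector<double> T(C, 0.0);
  for (int j = 0; j < C; ++j) {
    double t = 0.0;
    for (int i = 0; i < F; ++i) t += X(i, j);
    T[j] = t;
  }
  std::vector< std::vector<int> > members(K);
  for (int j = 0; j < C; ++j) {
    const int k = z[j] - 1;
    if (k < 0 || k >= K) stop("z contains a label outside 1..K");
    members[k].push_back(j);
  }
  std::vector<double> S(K, 0.0);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int i = 0; i < F; ++i) s += A(k, i);
    S[k] = s;
  }
  int n_acc = 0, n_prop = 0;
  std::vector<int> d_k, d_i, d_acc;
  std::vector<double> d_prop, d_lr;
  for (int k = 0; k < K; ++k) {
    if (members[k].empty()) continue;  // frozen while empty
    for (int i = 0; i < F; ++i) {
      const double a = A(k, i);
      const double eps = R::norm_rand() * step;
      const double ap = a * std::exp(eps);
      const double Sp = S[k] + ap - a;
      double lr = eps;  // log(ap / a): proposal asymmetry
      for (std::size_t m = 0; m < members[k].size(); ++m) {
        const int j = members[k][m];
        const double bj = b[j];
        const double x = X(i, j);
        if (x > 0)
          lr += R::lgammafn(x + ap * bj) - R::lgammafn(ap * bj)
              - R::lgammafn(x + a * bj) + R::lgammafn(a * bj);
        lr += R::lgammafn(Sp * bj) - R::lgammafn(T[j] + Sp * bj)
            - R::lgammafn(S[k] * bj) + R::lgammafn(T[j] + S[k] * bj);
      }
      ++n_prop;
      const bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        A(k, i) = ap;
        S[k] = Sp;
        ++n_acc;
      }
      if (diagnostics) {
        d_k.push_back(k + 1);
        d_i.push_back(i + 1);
        d_prop.push_back(ap);
        d_lr.push_back(lr);
        d_acc.push_back(acc ? 1 : 0);
      }
    }
  }
  List out = List::create(_["alpha"] = A,
                          _["n_accept"] = n_acc,
                          _["n_propose"] = n_prop);
  if (diagnostics)
    out["trace"] = List::create(_["k"] = wrap(d_k), _["i"] = wrap(d_i),
                                _["proposed"] = wrap(d_prop),
                                _["log_ratio"] = wrap(d_lr),
                                _["accepted"] = wrap(d_acc));
  return out;
}

static double dm_cell_diff(const NumericMatrix& X, const NumericMatrix& A,
                           const std::vector<double>& S,
                           const std::vector<double>& T,
                           const int k, const int j,
                           const double b_cur, const double b_prop) {
  const int F = X.nrow();
  double d = R::lgammafn(S[k] * b_prop) - R::lgammafn(T[j] + S[k] * b_prop)
           - R::lgammafn(S[k] * b_cur) + R::lgammafn(T[j] + S[k] * b_cur);
  for (int i = 0; i < F; ++i) {
    const double x = X(i, j);
    if (x > 0) {
      const double a = A(k, i);
      d += R::lgammafn(x + a * b_prop) - R::lgammafn(a * b_prop)
         - R::lgammafn(x + a * b_cur) + R::lgammafn(a * b_cur);
    }
  }
  return d;
}

// One Metropolis sweep over the C cell-specific random effects b_j.
// Multiplicative log-normal proposal; the acceptance log-ratio uses only
// cell j's two DM terms plus the log-normal prior
// -log b - (log b)^2 / (2 sigma_b^2), plus the asymmetry correction.
// [[Rcpp::export]]
List cc_mh_b_sweep(const NumericMatrix& X1, const NumericMatrix& X2,
                   const NumericMatrix& A1, const NumericMatrix& A2,
                   const IntegerVector& z, const NumericVector& b,
                   const double sigma_b2, const double step,
                   const bool diagnostics) {
  const int C = X1.ncol(), K = A1.nrow();
  NumericVector bb = clone(b);
  std::vector<double> T1(C, 0.0), T2(C, 0.0);
  for (int j = 0; j < C; ++j) {
    double t = 0.0;
    for (int i = 0; i < X1.nrow(); ++i) t += X1(i, j);
    T1[j] = t;
    t = 0.0;
    for (int i = 0; i < X2.nrow(); ++i) t += X2(i, j);
    T2[j] = t;
  }
  std::vector<double> S1(K, 0.0), S2(K, 0.0);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < A1.ncol(); ++i) S1[k] += A1(k, i);
    for (int i = 0; i < A2.ncol(); ++i) S2[k] += A2(k, i);
  }
  int n_acc = 0;
  std::vector<double> d_prop, d_lr;
  std::vector<int> d_acc;
  for (int j = 0; j < C; ++j) {
    const int k = z[j] - 1;
    if (k < 0 || k >= K) stop("z contains a label outside 1..K");
    const double bj = bb[j];
    const double eps = R::norm_rand() * step;
    const double bp = bj * std::exp(eps);
    const double lb = std::log(bj), lbp = std::log(bp);
    double lr = eps
      + (-lbp - lbp * lbp / (2.0 * sigma_b2))
      - (-lb - lb * lb / (2.0 * sigma_b2));
    lr += dm_cell_diff(X1, A1, S1, T1, k, j, bj, bp);
    lr += dm_cell_diff(X2, A2, S2, T2, k, j, bj, bp);
    const bool acc = std::log(R::unif_rand()) < lr;
    if (acc) {
      bb[j] = bp;
      ++n_acc;
    }
    if (diagnostics) {
      d_prop.push_back(bp);
      d_lr.push_back(lr);
      d_acc.push_back(acc ? 1 : 0);
    }
  }
  List out = List::create(_["b"] = bb,
                          _["n_accept"] = n_acc,
                          _["n_propose"] = C);
  if (diagnostics)
    out["trace"] = List::create(_["proposed"] = wrap(d_prop),
                                _["log_ratio"] = wrap(d_lr),
                                _["accepted"] = wrap(d_acc));
  return out;
}
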