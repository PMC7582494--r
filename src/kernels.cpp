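// Fused numeric kernels for the hot paths of the network: batch
// normalization, activations, the per-group max reduction, edge-feature
// gather/scatter and per-sample channel gating. Matrices are column-major
// doubles; group layouts follow the package convention (neighbor index
// varying fastest within contiguous per-point blocks).

#include <Rcpp.h>
using namespace Rcpp;

// y = x * s[col] (per-channel scaling)
// [[Rcpp::export(name = ".c_col_scale")]]
NumericMatrix c_col_scale(const NumericMatrix& X, const NumericVector& s) {
  int n = X.nrow(), C = X.ncol();
  NumericMatrix Y = no_init(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    double sc = s[c];
    for (int i = 0; i < n; ++i) y[i] = x[i] * sc;
  }
  return Y;
}

// training-mode batch norm: biased batch variance, returns the normalized
// input alongside the output so the backward pass can reuse it
// [[Rcpp::export(name = ".c_bn_train_fw")]]
List c_bn_train_fw(const NumericMatrix& X, const NumericVector& gamma,
                   const NumericVector& beta, double eps) {
  int n = X.nrow(), C = X.ncol();
  NumericMatrix out = no_init(n, C), xhat = no_init(n, C);
  NumericVector mu = no_init(C), var = no_init(C), inv = no_init(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += x[i];
    m /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { double d = x[i] - m; v += d * d; }
    v /= n;
    double iv = 1.0 / std::sqrt(v + eps);
    double g = gamma[c], b = beta[c];
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) {
      xh[i] = (x[i] - m) * iv;
      o[i] = xh[i] * g + b;
    }
    mu[c] = m; var[c] = v; inv[c] = iv;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".c_bn_train_bw")]]
List c_bn_train_bw(const NumericMatrix& dY, const NumericMatrix& xhat,
                   const NumericVector& inv, const NumericVector& gamma) {
  int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX = no_init(n, C);
  NumericVector dgamma = no_init(C), dbeta = no_init(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double* dx = &dX(0, c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) { sg += dy[i] * xh[i]; sb += dy[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    double g = gamma[c], iv = inv[c];
    double m1 = g * sb / n, m2 = g * sg / n;
    for (int i = 0; i < n; ++i)
      dx[i] = (g * dy[i] - m1 - xh[i] * m2) * iv;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// eval-mode batch norm using running statistics
// [[Rcpp::export(name = ".c_bn_eval_fw")]]
NumericMatrix c_bn_eval_fw(const NumericMatrix& X, const NumericVector& gamma,
                           const NumericVector& beta,
                           const NumericVector& rmean,
                           const NumericVector& rvar, double eps) {
  int n = X.nrow(), C = X.ncol();
  NumericMatrix out = no_init(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* o = &out(0, c);
    double iv = 1.0 / std::sqrt(rvar[c] + eps);
    double a = gamma[c] * iv;
    double b = beta[c] - rmean[c] * a;
    for (int i = 0; i < n; ++i) o[i] = x[i] * a + b;
  }
  return out;
}

// leaky ReLU (slope 0 gives plain ReLU)
// [[Rcpp::export(name = ".c_leaky_fw")]]
NumericMatrix c_leaky_fw(const NumericMatrix& X, double slope) {
  int m = X.nrow() * X.ncol();
  NumericMatrix Y = no_init(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* y = Y.begin();
  for (int i = 0; i < m; ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return Y;
}

// [[Rcpp::export(name = ".c_leaky_bw")]]
NumericMatrix c_leaky_bw(const NumericMatrix& dY, const NumericMatrix& X,
                         double slope) {
  int m = X.nrow() * X.ncol();
  NumericMatrix dX = no_init(X.nrow(), X.ncol());
  const double* x = X.begin();
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (int i = 0; i < m; ++i) dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dX;
}

// max over each block of k consecutive rows, with 1-based argmax
// [[Rcpp::export(name = ".c_maxk_fw")]]
List c_maxk_fw(const NumericMatrix& E, int k) {
  int nk = E.nrow(), C = E.ncol(), n = nk / k;
  NumericMatrix out = no_init(n, C);
  IntegerMatrix amax = no_init(n, C);
  for (int c = 0; c < C; ++c) {
    const double* e = &E(0, c);
    double* o = &out(0, c);
    int* a = &amax(0, c);
    for (int p = 0; p < n; ++p) {
      const double* g = e + (size_t)p * k;
      double best = g[0]; int bj = 0;
      for (int j = 1; j < k; ++j)
        if (g[j] > best) { best = g[j]; bj = j; }
      o[p] = best; a[p] = bj + 1;
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export(name = ".c_maxk_bw")]]
NumericMatrix c_maxk_bw(const NumericMatrix& dY, const IntegerMatrix& amax,
                        int k) {
  int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dE((size_t)n * k, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const int* a = &amax(0, c);
    double* de = &dE(0, c);
    for (int p = 0; p < n; ++p)
      de[(size_t)p * k + a[p] - 1] = dy[p];
  }
  return dE;
}

// edge features (x_j - x_i, x_i): idx is (rows) x k of 1-based indices into
// P's rows, row i being the center of group i
// [[Rcpp::export(name = ".c_edge_gather")]]
NumericMatrix c_edge_gather(const NumericMatrix& P, const IntegerMatrix& idx) {
  int N = idx.nrow(), k = idx.ncol(), D = P.ncol();
  NumericMatrix E = no_init((size_t)N * k, 2 * D);
  for (int d = 0; d < D; ++d) {
    const double* pc = &P(0, d);
    double* e1 = &E(0, d);
    double* e2 = &E(0, D + d);
    for (int i = 0; i < N; ++i) {
      double xi = pc[i];
      size_t base = (size_t)i * k;
      for (int j = 0; j < k; ++j) {
        double xj = pc[idx(i, j) - 1];
        e1[base + j] = xj - xi;
        e2[base + j] = xi;
      }
    }
  }
  return E;
}

// adjoint of c_edge_gather: accumulates dE back onto the n point rows
// [[Rcpp::export(name = ".c_edge_scatter")]]
NumericMatrix c_edge_scatter(const NumericMatrix& dE, const IntegerMatrix& idx,
                             int n) {
  int N = idx.nrow(), k = idx.ncol(), D = dE.ncol() / 2;
  NumericMatrix dP(n, D);
  for (int d = 0; d < D; ++d) {
    const double* e1 = &dE(0, d);
    const double* e2 = &dE(0, D + d);
    double* pc = &dP(0, d);
    for (int i = 0; i < N; ++i) {
      size_t base = (size_t)i * k;
      double acc_i = 0.0;
      for (int j = 0; j < k; ++j) {
        double g = e1[base + j];
        pc[idx(i, j) - 1] += g;
        acc_i += e2[base + j] - g;
      }
      pc[i] += acc_i;
    }
  }
  return dP;
}

// out(r, c) = M(r, c) * S(grp[r], c): per-sample per-channel gating
// [[Rcpp::export(name = ".c_group_scale")]]
NumericMatrix c_group_scale(const NumericMatrix& M, const NumericMatrix& S,
                            const IntegerVector& grp) {
  int n = M.nrow(), C = M.ncol();
  NumericMatrix out = no_init(n, C);
  for (int c = 0; c < C; ++c) {
    const double* m = &M(0, c);
    const double* s = &S(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) o[i] = m[i] * s[grp[i] - 1];
  }
  return out;
}

// per-sample column sums: B x C matrix of sums of M's rows by group id
// [[Rcpp::export(name = ".c_group_colsum")]]
NumericMatrix c_group_colsum(const NumericMatrix& M, const IntegerVector& grp,
                             int B) {
  int n = M.nrow(), C = M.ncol();
  NumericMatrix out(B, C);
  for (int c = 0; c < C; ++c) {
    const double* m = &M(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) o[grp[i] - 1] += m[i];
  }
  return out;
}

// sum over columns of M * W elementwise per group: the gradient of the gate
// scalars, ds(g, c) = sum_{r in g} dY(r, c) * M(r, c)
// [[Rcpp::export(name = ".c_group_dot")]]
NumericMatrix c_group_dot(const NumericMatrix& dY, const NumericMatrix& M,
                          const IntegerVector& grp, int B) {
  int n = M.nrow(), C = M.ncol();
  NumericMatrix out(B, C);
  for (int c = 0; c < C; ++c) {
    const double* m = &M(0, c);
    const double* dy = &dY(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) o[grp[i] - 1] += dy[i] * m[i];
  }
  return out;
}

// kNN indices for one cloud: exact squared Euclidean distances with
// (distance, index) lexicographic ordering, so ties break by ascending
// point index; column 1 is the center itself
// [[Rcpp::export(name = ".c_knn_idx")]]
IntegerMatrix c_knn_idx(const NumericMatrix& X, int k) {
  int N = X.nrow(), D = X.ncol();
  IntegerMatrix idx = no_init(N, k);
  std::vector<double> d2((size_t)N);
  std::vector<int> ord((size_t)N);
  const double* xp = X.begin();
  for (int i = 0; i < N; ++i) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int d = 0; d < D; ++d) {
      const double* col = xp + (size_t)d * N;
      double xi = col[i];
      for (int j = 0; j < N; ++j) {
        double diff = col[j] - xi;
        d2[j] += diff * diff;
      }
    }
    d2[i] = -1.0;  // the center sorts first
    for (int j = 0; j < N; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        if (d2[a] != d2[b]) return d2[a] < d2[b];
                        return a < b;
                      });
    for (int j = 0; j < k; ++j) idx(i, j) = ord[j] + 1;
  }
  return idx;
}

// edge-decomposed shared MLP: H[(i-1)*k + j, c] = A(idx(i,j), c) + C2(i, c)
// where A = P W1 and C2 = P (W2 - W1); equivalent to applying the dense map
// to (x_j - x_i, x_i) but with the matmul done per point instead of per edge
// [[Rcpp::export(name = ".c_gather_sum")]]
NumericMatrix c_gather_sum(const NumericMatrix& A, const NumericMatrix& C2,
                           const IntegerMatrix& idx) {
  int N = idx.nrow(), k = idx.ncol(), C = A.ncol();
  NumericMatrix H = no_init((size_t)N * k, C);
  for (int c = 0; c < C; ++c) {
    const double* a = &A(0, c);
    const double* c2 = &C2(0, c);
    double* h = &H(0, c);
    for (int i = 0; i < N; ++i) {
      size_t base = (size_t)i * k;
      double ci = c2[i];
      for (int j = 0; j < k; ++j)
        h[base + j] = a[idx(i, j) - 1] + ci;
    }
  }
  return H;
}

// adjoint pieces of c_gather_sum: accumulate dH onto neighbor rows
// [[Rcpp::export(name = ".c_nbr_scatter")]]
NumericMatrix c_nbr_scatter(const NumericMatrix& dH, const IntegerMatrix& idx,
                            int n) {
  int N = idx.nrow(), k = idx.ncol(), C = dH.ncol();
  NumericMatrix dA(n, C);
  for (int c = 0; c < C; ++c) {
    const double* dh = &dH(0, c);
    double* da = &dA(0, c);
    for (int i = 0; i < N; ++i) {
      size_t base = (size_t)i * k;
      for (int j = 0; j < k; ++j)
        da[idx(i, j) - 1] += dh[base + j];
    }
  }
  return dA;
}

// sum over each block of k consecutive rows (per-center sum)
// [[Rcpp::export(name = ".c_centersum")]]
NumericMatrix c_centersum(const NumericMatrix& dH, int k) {
  int nk = dH.nrow(), C = dH.ncol(), n = nk / k;
  NumericMatrix out = no_init(n, C);
  for (int c = 0; c < C; ++c) {
    const double* dh = &dH(0, c);
    double* o = &out(0, c);
    for (int p = 0; p < n; ++p) {
      const double* g = dh + (size_t)p * k;
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += g[j];
      o[p] = s;
    }
  }
  return out;
}
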