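#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline double sqdist(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// copy row i of an N x 3 matrix (column-major) into p
static inline void row3(const NumericMatrix& m, int i, double* p) {
  p[0] = m(i, 0); p[1] = m(i, 1); p[2] = m(i, 2);
}

// K nearest neighbours of each query point among the reference points.
// Ordering: increasing distance, ties broken by lower reference index.
// Returns 1-based index matrix (M x K) and the matching distances.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int K) {
  const int M = query.nrow(), N = ref.nrow();
  if (K > N) stop("K (%d) exceeds number of reference points (%d)", K, N);
  IntegerMatrix idx(M, K);
  NumericMatrix dst(M, K);
  std::vector<std::pair<double, int> > cand(N);
  double q[3], r[3];
  for (int i = 0; i < M; ++i) {
    row3(query, i, q);
    for (int j = 0; j < N; ++j) {
      row3(ref, j, r);
      cand[j] = std::make_pair(sqdist(q, r), j);
    }
    std::partial_sort(cand.begin(), cand.begin() + K, cand.end());
    for (int k = 0; k < K; ++k) {
      idx(i, k) = cand[k].second + 1;
      dst(i, k) = std::sqrt(cand[k].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Neighbourhood table for centers drawn from the cloud itself: each center is
// always its own first neighbour, remaining K-1 slots by (distance, index).
// [[Rcpp::export]]
List cpp_knn_group(NumericMatrix coords, IntegerVector centers, int K) {
  const int N = coords.nrow(), M = centers.size();
  if (K > N) stop("K (%d) exceeds number of points (%d)", K, N);
  IntegerMatrix idx(M, K);
  NumericMatrix dst(M, K);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(N);
  double q[3], r[3];
  for (int i = 0; i < M; ++i) {
    int ci = centers[i] - 1;
    if (ci < 0 || ci >= N) stop("center index out of range");
    row3(coords, ci, q);
    cand.clear();
    for (int j = 0; j < N; ++j) {
      if (j == ci) continue;
      row3(coords, j, r);
      cand.push_back(std::make_pair(sqdist(q, r), j));
    }
    idx(i, 0) = ci + 1;
    dst(i, 0) = 0.0;
    const int kk = K - 1;
    if (kk > 0) {
      std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
      for (int k = 0; k < kk; ++k) {
        idx(i, k + 1) = cand[k].second + 1;
        dst(i, k + 1) = std::sqrt(cand[k].first);
      }
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Farthest point sampling: greedy max-min selection starting from `start`
// (1-based). Ties broken by lower index. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix coords, int m, int start) {
  const int N = coords.nrow();
  if (m < 1 || m > N) stop("m must be in [1, N]");
  if (start < 1 || start > N) stop("start index out of range");
  IntegerVector out(m);
  std::vector<double> mind(N);
  double p[3], q[3];
  int cur = start - 1;
  out[0] = cur + 1;
  row3(coords, cur, p);
  for (int j = 0; j < N; ++j) { row3(coords, j, q); mind[j] = sqdist(p, q); }
  for (int s = 1; s < m; ++s) {
    int best = 0;
    double bestd = -1.0;
    for (int j = 0; j < N; ++j) {
      if (mind[j] > bestd) { bestd = mind[j]; best = j; }
    }
    out[s] = best + 1;
    row3(coords, best, p);
    for (int j = 0; j < N; ++j) {
      row3(coords, j, q);
      double d = sqdist(p, q);
      if (d < mind[j]) mind[j] = d;
    }
  }
  return out;
}

// Mean distance from each point to its k nearest neighbours (self excluded);
// substrate of the statistical outlier filter.
// [[Rcpp::export]]
NumericVector cpp_mean_knn_dist(NumericMatrix coords, int k) {
  const int N = coords.nrow();
  if (k >= N) stop("k must be smaller than the number of points");
  NumericVector out(N);
  std::vector<double> d(N);
  double q[3], r[3];
  for (int i = 0; i < N; ++i) {
    row3(coords, i, q);
    for (int j = 0; j < N; ++j) { row3(coords, j, r); d[j] = sqdist(q, r); }
    d[i] = R_PosInf;  // exclude self
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double s = 0.0;
    for (int t = 0; t < k; ++t) s += std::sqrt(d[t]);
    out[i] = s / k;
  }
  return out;
}

// Euclidean connectivity clustering: points i, j connected iff
// ||p_i - p_j|| <= eps; returns 1-based component labels in first-point order.
// [[Rcpp::export]]
IntegerVector cpp_euclidean_cluster(NumericMatrix coords, double eps) {
  const int N = coords.nrow();
  const double e2 = eps * eps;
  IntegerVector lab(N, 0);
  std::queue<int> bfs;
  double q[3], r[3];
  int next = 0;
  for (int i = 0; i < N; ++i) {
    if (lab[i] != 0) continue;
    lab[i] = ++next;
    bfs.push(i);
    while (!bfs.empty()) {
      int u = bfs.front(); bfs.pop();
      row3(coords, u, q);
      for (int v = 0; v < N; ++v) {
        if (lab[v] != 0) continue;
        row3(coords, v, r);
        if (sqdist(q, r) <= e2) { lab[v] = next; bfs.push(v); }
      }
    }
  }
  return lab;
}

// ---- grouped-feature kernels -----------------------------------------------
// Neighbour-feature matrices are (M*K) x d with center-major rows: row
// (i-1)*K + k-1 holds neighbour k of center i. These kernels implement the
// per-neighbourhood reductions used by the pooling layers.

// channelwise max over K neighbours; argk records the winning k (first on
// ties) for gradient routing.
// [[Rcpp::export]]
List cpp_group_max(NumericMatrix X, int M, int K) {
  const int d = X.ncol();
  NumericMatrix val(M, d);
  IntegerMatrix argk(M, d);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < M; ++i) {
      double best = X(i * K, j);
      int bk = 1;
      for (int k = 1; k < K; ++k) {
        double v = X(i * K + k, j);
        if (v > best) { best = v; bk = k + 1; }
      }
      val(i, j) = best;
      argk(i, j) = bk;
    }
  }
  return List::create(_["val"] = val, _["argk"] = argk);
}

// [[Rcpp::export]]
NumericMatrix cpp_group_max_backward(NumericMatrix dVal, IntegerMatrix argk,
                                     int M, int K) {
  const int d = dVal.ncol();
  NumericMatrix dX(M * K, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < M; ++i)
      dX(i * K + (argk(i, j) - 1), j) = dVal(i, j);
  return dX;
}

// sum over the K neighbours of each center
// [[Rcpp::export]]
NumericMatrix cpp_group_sum(NumericMatrix X, int M, int K) {
  const int d = X.ncol();
  NumericMatrix out(M, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < M; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += X(i * K + k, j);
      out(i, j) = s;
    }
  return out;
}

// replicate each center row K times (the expansion adjoint of group_sum)
// [[Rcpp::export]]
NumericMatrix cpp_expand_centers(NumericMatrix X, int K) {
  const int M = X.nrow(), d = X.ncol();
  NumericMatrix out(M * K, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < M; ++i) {
      double v = X(i, j);
      for (int k = 0; k < K; ++k) out(i * K + k, j) = v;
    }
  return out;
}

// numerically stable per-channel softmax over the K neighbours
// [[Rcpp::export]]
NumericMatrix cpp_group_softmax(NumericMatrix S, int M, int K) {
  const int d = S.ncol();
  NumericMatrix W(M * K, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < M; ++i) {
      double mx = S(i * K, j);
      for (int k = 1; k < K; ++k) mx = std::max(mx, S(i * K + k, j));
      double den = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = std::exp(S(i * K + k, j) - mx);
        W(i * K + k, j) = e;
        den += e;
      }
      for (int k = 0; k < K; ++k) W(i * K + k, j) /= den;
    }
  return W;
}

// weighted sum over neighbours: out[i,j] = sum_k W[(i,k),j] * X[(i,k),j]
// [[Rcpp::export]]
NumericMatrix cpp_group_wsum(NumericMatrix W, NumericMatrix X, int M, int K) {
  const int d = X.ncol();
  NumericMatrix out(M, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < M; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += W(i * K + k, j) * X(i * K + k, j);
      out(i, j) = s;
    }
  return out;
}

// fused backward of the attention aggregation F = sum_k softmax(S)_k * X_k:
// given the softmax weights W, the neighbour features X and the upstream
// gradient dF (M x d), emits the gradient at the scores (dS) and the direct
// feature gradient (dX = W * expanded dF) in one pass.
// [[Rcpp::export]]
List cpp_attention_backward(NumericMatrix W, NumericMatrix X,
                            NumericMatrix dF, int M, int K) {
  const int d = X.ncol();
  NumericMatrix dS(M * K, d), dX(M * K, d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < M; ++i) {
      const double g = dF(i, j);
      double fatt = 0.0;
      for (int k = 0; k < K; ++k) fatt += W(i * K + k, j) * X(i * K + k, j);
      const double T = g * fatt;
      for (int k = 0; k < K; ++k) {
        const double w = W(i * K + k, j);
        dS(i * K + k, j) = w * (g * X(i * K + k, j) - T);
        dX(i * K + k, j) = w * g;
      }
    }
  return List::create(_["dS"] = dS, _["dX"] = dX);
}
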