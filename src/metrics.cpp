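#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted graph kernels for similarity-weighted (0 < w <= 1) adjacency
// matrices. Edge length for shortest paths is the reciprocal weight 1/w.
// Networks here are small (74 nodes) and moderately dense (10-40%), so
// Dijkstra uses the flat O(V^2) form on a dense length matrix, which
// beats heap-based variants at this size.

static const double INF = std::numeric_limits<double>::infinity();

// length matrix: L[i*n+j] = 1/w_ij, INF where no edge
static void length_matrix(const double* W, int n, std::vector<double>& L) {
  L.assign((size_t)n * n, INF);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = W[(size_t)j * n + i]; // column-major from R; symmetric anyway
      if (j != i && w > 0.0) L[(size_t)i * n + j] = 1.0 / w;
    }
}

static void dijkstra_dense(const std::vector<double>& L, int n, int s,
                           std::vector<double>& dist, std::vector<char>& done) {
  dist.assign(n, INF);
  done.assign(n, 0);
  dist[s] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1;
    double best = INF;
    for (int v = 0; v < n; ++v)
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    if (u < 0) break;
    done[u] = 1;
    const double* row = &L[(size_t)u * n];
    double du = dist[u];
    for (int v = 0; v < n; ++v) {
      if (done[v] || row[v] == INF) continue;
      double nd = du + row[v];
      if (nd < dist[v]) dist[v] = nd;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix dist_matrix_cpp(NumericMatrix W) {
  int n = W.nrow();
  std::vector<double> L;
  length_matrix(W.begin(), n, L);
  NumericMatrix D(n, n);
  std::vector<double> dist;
  std::vector<char> done;
  for (int i = 0; i < n; ++i) {
    dijkstra_dense(L, n, i, dist, done);
    for (int j = 0; j < n; ++j) D(i, j) = dist[j];
  }
  return D;
}

// one distance pass accumulating characteristic path length (mean over
// reachable ordered pairs; NA if none) and global efficiency (mean of
// 1/d over all ordered pairs, unreachable -> 0)
static void lp_eglob_dense(const std::vector<double>& L, int n,
                           double& lp, double& eglob) {
  double sd = 0.0, se = 0.0;
  long cnt = 0;
  std::vector<double> dist;
  std::vector<char> done;
  for (int i = 0; i < n; ++i) {
    dijkstra_dense(L, n, i, dist, done);
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] != INF) { sd += dist[j]; se += 1.0 / dist[j]; ++cnt; }
  }
  lp = (cnt == 0) ? NA_REAL : sd / (double)cnt;
  eglob = (n < 2) ? 0.0 : se / ((double)n * (n - 1));
}

// Per-node weighted clustering.
// variant 0: Onnela geometric-mean form on weights normalized by wmax
//            (cube roots cached in a matrix so the pair loop is cheap);
// variant 1: Barrat arithmetic form (raw weights and strengths).
static void clustering_dense(const double* W, int n, int variant,
                             std::vector<double>& out) {
  out.assign(n, 0.0);
  double wmax = 0.0;
  for (size_t e = 0; e < (size_t)n * n; ++e)
    if (W[e] > wmax) wmax = W[e];
  if (wmax <= 0.0) return;
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i && W[(size_t)j * n + i] > 0.0) nb[i].push_back(j);
  std::vector<double> B;
  if (variant == 0) {
    B.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double w = W[(size_t)j * n + i];
        if (w > 0.0) B[(size_t)i * n + j] = std::cbrt(w / wmax);
      }
  }
  for (int i = 0; i < n; ++i) {
    int k = (int)nb[i].size();
    if (k < 2) continue;
    double acc = 0.0;
    if (variant == 0) {
      const double* Bi = &B[(size_t)i * n];
      for (int a = 0; a < k; ++a) {
        int j = nb[i][a];
        const double* Bj = &B[(size_t)j * n];
        double bij = Bi[j];
        for (int b = a + 1; b < k; ++b) {
          int h = nb[i][b];
          double bjh = Bj[h];
          if (bjh > 0.0) acc += 2.0 * bij * Bi[h] * bjh;
        }
      }
      out[i] = acc / ((double)k * (k - 1));
    } else {
      double si = 0.0;
      for (int a = 0; a < k; ++a) si += W[(size_t)nb[i][a] * n + i];
      for (int a = 0; a < k; ++a) {
        int j = nb[i][a];
        double wij = W[(size_t)j * n + i];
        for (int b = a + 1; b < k; ++b) {
          int h = nb[i][b];
          if (W[(size_t)h * n + j] > 0.0)
            acc += wij + W[(size_t)h * n + i];
        }
      }
      out[i] = acc / (si * (k - 1));
    }
  }
}

// [[Rcpp::export]]
NumericVector clustering_cpp(NumericMatrix W, int variant) {
  std::vector<double> c;
  clustering_dense(W.begin(), W.nrow(), variant, c);
  return NumericVector(c.begin(), c.end());
}

// [[Rcpp::export]]
List global_metrics_cpp(NumericMatrix W, int variant) {
  int n = W.nrow();
  std::vector<double> L;
  length_matrix(W.begin(), n, L);
  double lp, eglob;
  lp_eglob_dense(L, n, lp, eglob);
  std::vector<double> c;
  clustering_dense(W.begin(), n, variant, c);
  double cp = 0.0;
  for (int i = 0; i < n; ++i) cp += c[i];
  cp /= (double)n;
  return List::create(_["cp"] = cp, _["lp"] = lp, _["eglob"] = eglob);
}

NumericVector local_efficiency_cpp(NumericMatrix W);

// Combined per-network metrics in one pass: a single all-sources
// distance sweep feeds Lp, Eglob, nodal path length (mean finite
// distance to reachable others, 0 if none) and nodal efficiency (mean
// inverse distance to all others). Clustering, strength/degree and
// (optionally) local efficiency are computed alongside.
// [[Rcpp::export]]
List graph_metrics_cpp(NumericMatrix W, int variant, bool nodal,
                       bool local_eff) {
  int n = W.nrow();
  const double* pW = W.begin();
  std::vector<double> L;
  length_matrix(pW, n, L);
  NumericVector path_len(n), nodal_eff(n), strength(n), degree(n);
  double sd_all = 0.0, se_all = 0.0;
  long cnt_all = 0;
  std::vector<double> dist;
  std::vector<char> done;
  for (int i = 0; i < n; ++i) {
    dijkstra_dense(L, n, i, dist, done);
    double sdi = 0.0, sei = 0.0;
    long ci = 0;
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] != INF) { sdi += dist[j]; sei += 1.0 / dist[j]; ++ci; }
    sd_all += sdi; se_all += sei; cnt_all += ci;
    if (nodal) {
      path_len[i] = (ci == 0) ? 0.0 : sdi / (double)ci;
      nodal_eff[i] = (n < 2) ? 0.0 : sei / (double)(n - 1);
    }
  }
  double lp = (cnt_all == 0) ? NA_REAL : sd_all / (double)cnt_all;
  double eglob = (n < 2) ? 0.0 : se_all / ((double)n * (n - 1));
  std::vector<double> c;
  clustering_dense(pW, n, variant, c);
  double cp = 0.0;
  for (int i = 0; i < n; ++i) cp += c[i];
  cp /= (double)n;
  List out = List::create(_["cp"] = cp, _["lp"] = lp, _["eglob"] = eglob,
                          _["clustering"] = NumericVector(c.begin(), c.end()));
  if (nodal) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0; int k = 0;
      for (int j = 0; j < n; ++j) {
        double w = pW[(size_t)j * n + i];
        if (j != i && w > 0.0) { s += w; ++k; }
      }
      strength[i] = s; degree[i] = k;
    }
    out["path_length"] = path_len;
    out["nodal_efficiency"] = nodal_eff;
    out["strength"] = strength;
    out["degree"] = degree;
  }
  if (local_eff) out["local_efficiency"] = local_efficiency_cpp(W);
  return out;
}

// [[Rcpp::export]]
NumericVector local_efficiency_cpp(NumericMatrix W) {
  int n = W.nrow();
  const double* pW = W.begin();
  NumericVector out(n);
  std::vector<int> nb;
  std::vector<double> Lsub, dist;
  std::vector<char> done;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && pW[(size_t)j * n + i] > 0.0) nb.push_back(j);
    int m = (int)nb.size();
    if (m < 2) { out[i] = 0.0; continue; }
    Lsub.assign((size_t)m * m, INF);
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b) {
        double w = pW[(size_t)nb[b] * n + nb[a]];
        if (w > 0.0) {
          Lsub[(size_t)a * m + b] = 1.0 / w;
          Lsub[(size_t)b * m + a] = 1.0 / w;
        }
      }
    double se = 0.0;
    for (int a = 0; a < m; ++a) {
      dijkstra_dense(Lsub, m, a, dist, done);
      for (int b = 0; b < m; ++b)
        if (b != a && dist[b] != INF) se += 1.0 / dist[b];
    }
    out[i] = se / ((double)m * (m - 1));
  }
  return out;
}

// ---- Maslov-Sneppen degree-preserving rewiring, weights travel with edges ----

struct EdgeGraph {
  int n;
  std::vector<int> eu, ev;
  std::vector<double> ew;
  std::vector<char> A; // n*n adjacency indicator
  bool has(int i, int j) const { return A[(size_t)i * n + j] != 0; }
  void set(int i, int j, char v) {
    A[(size_t)i * n + j] = v;
    A[(size_t)j * n + i] = v;
  }
};

static EdgeGraph edges_from_matrix(const NumericMatrix& W) {
  EdgeGraph g;
  g.n = W.nrow();
  g.A.assign((size_t)g.n * g.n, 0);
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (W(i, j) > 0.0) {
        g.eu.push_back(i);
        g.ev.push_back(j);
        g.ew.push_back(W(i, j));
        g.set(i, j, 1);
      }
  return g;
}

static void ms_rewire(EdgeGraph& g, long long attempts, std::mt19937_64& rng) {
  size_t m = g.eu.size();
  if (m < 2) return;
  for (long long t = 0; t < attempts; ++t) {
    size_t e1 = (size_t)(rng() % m);
    uint64_t r2 = rng();
    size_t e2 = (size_t)(r2 % m);
    if (e1 == e2) continue;
    int a = g.eu[e1], b = g.ev[e1];
    int c = g.eu[e2], d = g.ev[e2];
    if (r2 >> 63) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.set(a, b, 0); g.set(c, d, 0);
    g.set(a, d, 1); g.set(c, b, 1);
    g.eu[e1] = a; g.ev[e1] = d;
    g.eu[e2] = c; g.ev[e2] = b;
  }
}

static void edges_to_dense(const EdgeGraph& g, std::vector<double>& W) {
  W.assign((size_t)g.n * g.n, 0.0);
  for (size_t e = 0; e < g.eu.size(); ++e) {
    W[(size_t)g.eu[e] * g.n + g.ev[e]] = g.ew[e];
    W[(size_t)g.ev[e] * g.n + g.eu[e]] = g.ew[e];
  }
}

// [[Rcpp::export]]
NumericMatrix ms_rewire_cpp(NumericMatrix W, double swaps_per_edge, double seed) {
  EdgeGraph g = edges_from_matrix(W);
  std::mt19937_64 rng((uint64_t)seed);
  long long attempts = (long long)(swaps_per_edge * (double)g.eu.size() + 0.5);
  ms_rewire(g, attempts, rng);
  NumericMatrix out(g.n, g.n);
  for (size_t e = 0; e < g.eu.size(); ++e) {
    out(g.eu[e], g.ev[e]) = g.ew[e];
    out(g.ev[e], g.eu[e]) = g.ew[e];
  }
  return out;
}

// Null-ensemble mean clustering (Cp) and characteristic path length (Lp):
// each null is an independent Maslov-Sneppen rewiring of W. Returns an
// n_nulls x 2 matrix (columns Cp, Lp).
// [[Rcpp::export]]
NumericMatrix null_cp_lp_cpp(NumericMatrix W, int n_nulls, double swaps_per_edge,
                             double seed, int variant) {
  EdgeGraph base = edges_from_matrix(W);
  std::mt19937_64 rng((uint64_t)seed);
  long long attempts = (long long)(swaps_per_edge * (double)base.eu.size() + 0.5);
  NumericMatrix out(n_nulls, 2);
  int n = base.n;
  std::vector<double> Wd, L, c;
  for (int r = 0; r < n_nulls; ++r) {
    EdgeGraph g = base;
    ms_rewire(g, attempts, rng);
    edges_to_dense(g, Wd);
    clustering_dense(Wd.data(), n, variant, c);
    double cp = 0.0;
    for (int i = 0; i < n; ++i) cp += c[i];
    out(r, 0) = cp / (double)n;
    length_matrix(Wd.data(), n, L);
    double lp, eglob;
    lp_eglob_dense(L, n, lp, eglob);
    out(r, 1) = lp;
  }
  return out;
}
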