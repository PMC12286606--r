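#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Index helpers for a 3D array stored in R's column-major order with
// dims (d1, d2, d3).
static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// 26-connected (or 6-connected) labeling of a binary 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }

  int next_label = 0;
  std::vector<int> stack;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = idx3(i, j, k, d1, d2);
        if (mask[v] == 0 || lab[v] != 0) continue;
        ++next_label;
        lab[v] = next_label;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int ck = cur / (d1 * d2);
          int rem = cur - ck * d1 * d2;
          int cj = rem / d1;
          int ci = rem - cj * d1;
          for (size_t q = 0; q < nb.size(); ++q) {
            int ni = ci + nb[q][0], nj = cj + nb[q][1], nk = ck + nb[q][2];
            if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3)
              continue;
            int w = idx3(ni, nj, nk, d1, d2);
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher)
// with anisotropic sample spacing `h`.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      s = ((fq + h2 * q * q) - (fv + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (k > 0 && s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary 3D mask: distance (in
// physical units, using spacings sp1..sp3 for dims 1..3) from each
// foreground voxel to the nearest background voxel. Background maps to 0.
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dims,
                        double sp1, double sp2, double sp3) {
  const double BIG = 1e15; // finite sentinel for "no background seen yet"
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = mask[v] != 0 ? BIG : 0.0;

  std::vector<double> f(std::max(d1, std::max(d2, d3)));
  std::vector<double> d(std::max(d1, std::max(d2, d3)));

  // pass along dim 1
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) f[i] = out[idx3(i, j, k, d1, d2)];
      dt1d(f, d, d1, sp1);
      for (int i = 0; i < d1; ++i) out[idx3(i, j, k, d1, d2)] = d[i];
    }
  // pass along dim 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      for (int j = 0; j < d2; ++j) f[j] = out[idx3(i, j, k, d1, d2)];
      dt1d(f, d, d2, sp2);
      for (int j = 0; j < d2; ++j) out[idx3(i, j, k, d1, d2)] = d[j];
    }
  // pass along dim 3
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      for (int k = 0; k < d3; ++k) f[k] = out[idx3(i, j, k, d1, d2)];
      dt1d(f, d, d3, sp3);
      for (int k = 0; k < d3; ++k) out[idx3(i, j, k, d1, d2)] = d[k];
    }
  for (int v = 0; v < n; ++v) out[v] = std::sqrt(out[v]);
  out.attr("dim") = dims;
  return out;
}

// Marker-based watershed on a 3D mask: voxels are flooded from the seeds in
// order of decreasing elevation (typically the distance transform), so
// touching objects are split along the valley between their seeds.
// `seeds` carries positive integer labels at the seed voxels, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector elev, IntegerVector seeds,
                              IntegerVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);

  typedef std::pair<double, int> QE; // (elevation, voxel)
  std::priority_queue<QE> pq;
  for (int v = 0; v < n; ++v)
    if (seeds[v] > 0 && mask[v] != 0) {
      lab[v] = seeds[v];
      pq.push(QE(elev[v], v));
    }

  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    int cur = pq.top().second;
    pq.pop();
    int ck = cur / (d1 * d2);
    int rem = cur - ck * d1 * d2;
    int cj = rem / d1;
    int ci = rem - cj * d1;
    for (int q = 0; q < 6; ++q) {
      int ni = ci + di[q], nj = cj + dj[q], nk = ck + dk[q];
      if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3)
        continue;
      int w = idx3(ni, nj, nk, d1, d2);
      if (mask[w] != 0 && lab[w] == 0) {
        lab[w] = lab[cur];
        pq.push(QE(elev[w], w));
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Hungarian algorithm (Kuhn-Munkres with potentials, O(n^3)) on a square
// cost matrix. Returns, for each row, the 1-based assigned column.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  // 1-based internal arrays, classic formulation
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) {
            minv[j] = cur;
            way[j] = j0;
          }
          if (minv[j] < delta) {
            delta = minv[j];
            j1 = j;
          }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
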