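#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Index helpers: arrays are stored in R column-major order with dim (n0, n1, n2),
// i.e. the first dimension (z in this package's (z, y, x) convention) is fastest.

static inline int reflect_index(int i, int n) {
  // symmetric boundary: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector conv3d_axis_cpp(NumericVector vol, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int kr = kl / 2;
  const R_xlen_t N = (R_xlen_t)n0 * n1 * n2;
  if (vol.size() != N) stop("volume size does not match dims");
  NumericVector out(no_init(N));

  const int len = (axis == 0) ? n0 : (axis == 1 ? n1 : n2);
  const R_xlen_t s0 = 1, s1 = n0, s2 = (R_xlen_t)n0 * n1;
  const R_xlen_t stride = (axis == 0) ? s0 : (axis == 1 ? s1 : s2);

  std::vector<double> line(len);
  const double *v = vol.begin();
  double *o = out.begin();
  const double *k = kernel.begin();

  // iterate over the two non-axis dimensions
  int la = (axis == 0) ? n1 : n0;
  int lb = (axis == 2) ? n1 : n2;
  R_xlen_t sa = (axis == 0) ? s1 : s0;
  R_xlen_t sb = (axis == 2) ? s1 : s2;

  for (int b = 0; b < lb; ++b) {
    for (int a = 0; a < la; ++a) {
      R_xlen_t base = a * sa + b * sb;
      for (int i = 0; i < len; ++i) line[i] = v[base + i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        if (i >= kr && i + kr < len) {
          const double *lp = &line[i - kr];
          for (int t = 0; t < kl; ++t) acc += lp[t] * k[t];
        } else {
          for (int t = 0; t < kl; ++t)
            acc += line[reflect_index(i + t - kr, len)] * k[t];
        }
        o[base + i * stride] = acc;
      }
    }
  }
  return out;
}

// neighbor offsets for the requested connectivity (6 or 26)
static void neighbor_offsets(int connectivity, std::vector<int> &dz,
                             std::vector<int> &dy, std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t N = (R_xlen_t)n0 * n1 * n2;
  if (mask.size() != N) stop("mask size does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector labels(N, 0);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = dz.size();
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t start = 0; start < N; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = idx % n0;
      int y = (idx / n0) % n1;
      int x = idx / ((R_xlen_t)n0 * n1);
      for (int t = 0; t < nn; ++t) {
        int zz = z + dz[t], yy = y + dy[t], xx = x + dx[t];
        if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 || xx < 0 || xx >= n2)
          continue;
        R_xlen_t j = zz + (R_xlen_t)n0 * (yy + (R_xlen_t)n1 * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = current;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Voxels of `mask` reachable from any voxel of `seed` through `mask`
// under the given connectivity. `seed` need not be a subset of `mask`;
// only seed voxels that are also in `mask` start the fill.
// [[Rcpp::export]]
LogicalVector flood_reachable_cpp(LogicalVector mask, LogicalVector seed,
                                  IntegerVector dims, int connectivity) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t N = (R_xlen_t)n0 * n1 * n2;
  if (mask.size() != N || seed.size() != N) stop("size mismatch");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  LogicalVector reach(N, false);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = dz.size();
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < N; ++i)
    if (seed[i] && mask[i] && !reach[i]) {
      reach[i] = true;
      stack.push_back(i);
    }
  while (!stack.empty()) {
    R_xlen_t idx = stack.back();
    stack.pop_back();
    int z = idx % n0;
    int y = (idx / n0) % n1;
    int x = idx / ((R_xlen_t)n0 * n1);
    for (int t = 0; t < nn; ++t) {
      int zz = z + dz[t], yy = y + dy[t], xx = x + dx[t];
      if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 || xx < 0 || xx >= n2)
        continue;
      R_xlen_t j = zz + (R_xlen_t)n0 * (yy + (R_xlen_t)n1 * xx);
      if (mask[j] && !reach[j]) {
        reach[j] = true;
        stack.push_back(j);
      }
    }
  }
  return reach;
}

// Leading TRUE run length per (y, x) column of a (z, y, x) logical array:
// the number of consecutive TRUE voxels starting at z = 0.
// [[Rcpp::export]]
IntegerMatrix column_top_run_cpp(LogicalVector mask, IntegerVector dims) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  if (mask.size() != (R_xlen_t)n0 * n1 * n2) stop("size mismatch");
  IntegerMatrix run(n1, n2);
  for (int x = 0; x < n2; ++x)
    for (int y = 0; y < n1; ++y) {
      R_xlen_t base = (R_xlen_t)n0 * (y + (R_xlen_t)n1 * x);
      int r = 0;
      while (r < n0 && mask[base + r]) ++r;
      run(y, x) = r;
    }
  return run;
}

// Deepest TRUE voxel per (y, x) column (0-based z index), -1 if none.
// [[Rcpp::export]]
IntegerMatrix column_deepest_cpp(LogicalVector mask, IntegerVector dims) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  if (mask.size() != (R_xlen_t)n0 * n1 * n2) stop("size mismatch");
  IntegerMatrix deep(n1, n2);
  for (int x = 0; x < n2; ++x)
    for (int y = 0; y < n1; ++y) {
      R_xlen_t base = (R_xlen_t)n0 * (y + (R_xlen_t)n1 * x);
      int d = -1;
      for (int z = n0 - 1; z >= 0; --z)
        if (mask[base + z]) { d = z; break; }
      deep(y, x) = d;
    }
  return deep;
}

// Gaussian-discriminant class assignment: for each row x of X, maximize
// -0.5 (x - mu_k)' Q_k (x - mu_k) + const_k over classes k, where Q_k is the
// inverse covariance. Single pass, no large temporaries.
// [[Rcpp::export]]
IntegerVector gd_assign_cpp(NumericMatrix X, List means, List qmats,
                            NumericVector consts) {
  const int n = X.nrow(), p = X.ncol(), K = means.size();
  std::vector<std::vector<double> > mu(K), Q(K);
  for (int k = 0; k < K; ++k) {
    NumericVector m = means[k];
    NumericMatrix q = qmats[k];
    mu[k].assign(m.begin(), m.end());
    Q[k].assign(q.begin(), q.end());
  }
  IntegerVector out(n);
  std::vector<double> v(p);
  for (int i = 0; i < n; ++i) {
    double best = -std::numeric_limits<double>::infinity();
    int arg = 0;
    for (int k = 0; k < K; ++k) {
      const double *m = &mu[k][0], *q = &Q[k][0];
      for (int j = 0; j < p; ++j) v[j] = X(i, j) - m[j];
      double quad = 0.0;
      for (int a = 0; a < p; ++a) {
        double row = 0.0;
        for (int b = 0; b < p; ++b) row += q[a + p * b] * v[b];
        quad += v[a] * row;
      }
      double s = -0.5 * quad + consts[k];
      if (s > best) { best = s; arg = k; }
    }
    out[i] = arg + 1;  // 1-based class index
  }
  return out;
}
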