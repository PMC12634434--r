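#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as R arrays (column-major): linear index i + nx*(j + ny*k).

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// Offsets of the 26-neighbourhood (and first 6 entries are the face neighbours).
static const int OFF26[26][3] = {
  {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}, {0, 0, -1}, {0, 0, 1},
  {-1, -1, 0}, {-1, 1, 0}, {1, -1, 0}, {1, 1, 0},
  {-1, 0, -1}, {-1, 0, 1}, {1, 0, -1}, {1, 0, 1},
  {0, -1, -1}, {0, -1, 1}, {0, 1, -1}, {0, 1, 1},
  {-1, -1, -1}, {-1, -1, 1}, {-1, 1, -1}, {-1, 1, 1},
  {1, -1, -1}, {1, -1, 1}, {1, 1, -1}, {1, 1, 1}
};

// Label connected foreground components (26-connectivity), labels 1..K.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int v = lin(i, j, k, nx, ny);
    if (!mask[v] || lab[v] != 0) continue;
    ++next;
    lab[v] = next;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int ck = cur / (nx * ny);
      const int rem = cur - ck * nx * ny;
      const int cj = rem / nx;
      const int ci = rem - cj * nx;
      for (int o = 0; o < 26; ++o) {
        const int ii = ci + OFF26[o][0], jj = cj + OFF26[o][1], kk = ck + OFF26[o][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        const int w = lin(ii, jj, kk, nx, ny);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur with reflecting borders; sigma per axis in voxels.
static void blur_axis(std::vector<double> &img, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + r];
  }
  for (double &w : kern) w /= s;
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), out(len);
  const int n1 = axis == 0 ? ny : nx;
  const int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b) for (int a = 0; a < n1; ++a) {
    for (int t = 0; t < len; ++t) {
      int i, j, k;
      if (axis == 0) { i = t; j = a; k = b; }
      else if (axis == 1) { i = a; j = t; k = b; }
      else { i = a; j = b; k = t; }
      line[t] = img[lin(i, j, k, nx, ny)];
    }
    for (int t = 0; t < len; ++t) {
      double acc = 0.0;
      for (int u = -r; u <= r; ++u) {
        int p = t + u;
        if (p < 0) p = -p - 1;            // reflect
        if (p >= len) p = 2 * len - p - 1;
        if (p < 0) p = 0;
        if (p >= len) p = len - 1;
        acc += kern[u + r] * line[p];
      }
      out[t] = acc;
    }
    for (int t = 0; t < len; ++t) {
      int i, j, k;
      if (axis == 0) { i = t; j = a; k = b; }
      else if (axis == 1) { i = a; j = t; k = b; }
      else { i = a; j = b; k = t; }
      img[lin(i, j, k, nx, ny)] = out[t];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(img.begin(), img.end());
  blur_axis(buf, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(buf, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(buf, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(img.size());
  std::copy(buf.begin(), buf.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// 1-based linear indices of voxels >= all 26 neighbours and above threshold.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector img, IntegerVector dim,
                               double threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> idx;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int v = lin(i, j, k, nx, ny);
    const double val = img[v];
    if (val <= threshold) continue;
    bool is_max = true;
    for (int o = 0; o < 26 && is_max; ++o) {
      const int ii = i + OFF26[o][0], jj = j + OFF26[o][1], kk = k + OFF26[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      if (img[lin(ii, jj, kk, nx, ny)] > val) is_max = false;
    }
    if (is_max) idx.push_back(v + 1);
  }
  return wrap(idx);
}

// Meyer-style seeded watershed by priority flooding on `priority`
// (lower values flooded first), restricted to `mask`, 6-connectivity growth.
// `seeds` holds initial labels (0 elsewhere). Returns the filled label array.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = priority.size();
  IntegerVector lab(n);
  std::copy(seeds.begin(), seeds.end(), lab.begin());

  typedef std::pair<double, std::pair<long long, int> > QItem; // (prio, (order, voxel))
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  long long order = 0;

  for (R_xlen_t v = 0; v < n; ++v)
    if (lab[v] > 0 && mask[v]) pq.push(QItem(priority[v], std::make_pair(order++, (int)v)));

  while (!pq.empty()) {
    const int cur = pq.top().second.second;
    pq.pop();
    const int lc = lab[cur];
    const int ck = cur / (nx * ny);
    const int rem = cur - ck * nx * ny;
    const int cj = rem / nx;
    const int ci = rem - cj * nx;
    for (int o = 0; o < 6; ++o) {
      const int ii = ci + OFF26[o][0], jj = cj + OFF26[o][1], kk = ck + OFF26[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      const int w = lin(ii, jj, kk, nx, ny);
      if (!mask[w] || lab[w] != 0) continue;
      lab[w] = lc;
      pq.push(QItem(priority[w], std::make_pair(order++, w)));
    }
  }
  return lab;
}
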