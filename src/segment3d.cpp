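// 3D image primitives for the fibre segmentation chain: separable Gaussian
// blur, 3x3x3 median despeckling, connected-component labelling, and a
// seeded priority-flood watershed restricted to a foreground mask.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export(name = ".gaussian_blur_3d")]]
NumericVector gaussian_blur_3d(NumericVector img, IntegerVector dim,
                               NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(img);
  int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += kern[t + r];
    }
    for (double &w : kern) w /= sum;
    NumericVector out(cur.size());
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i, jj = j, kk = k;
            int *p = (axis == 0) ? &ii : (axis == 1) ? &jj : &kk;
            *p += t;
            // reflect at the borders
            if (*p < 0) *p = -*p;
            if (*p >= n[axis]) *p = 2 * n[axis] - 2 - *p;
            acc += kern[t + r] * cur[idx3(ii, jj, kk, nx, ny)];
          }
          out[idx3(i, j, k, nx, ny)] = acc;
        }
    cur = out;
  }
  return cur;
}

// [[Rcpp::export(name = ".median_filter_3d")]]
NumericVector median_filter_3d(NumericVector img, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(img.size());
  std::vector<double> buf;
  buf.reserve(27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 ||
                  ii >= nx || jj >= ny || kk >= nz) continue;
              buf.push_back(img[idx3(ii, jj, kk, nx, ny)]);
            }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.end());
          med = 0.5 * (med + buf[m - 1]);
        }
        out[idx3(i, j, k, nx, ny)] = med;
      }
  return out;
}

static void neighbours(int v, int nx, int ny, int nz, int conn,
                       std::vector<int> &out) {
  out.clear();
  int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (ad == 0) continue;
        if (conn == 6 && ad > 1) continue;
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || jj < 0 || kk < 0 ||
            ii >= nx || jj >= ny || kk >= nz) continue;
        out.push_back(idx3(ii, jj, kk, nx, ny));
      }
}

// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dim,
                                  int connectivity = 26) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nvox = nx * ny * nz;
  IntegerVector labels(nvox, 0);
  std::vector<int> stack, nb;
  int next = 0;
  for (int v = 0; v < nvox; ++v) {
    if (!mask[v] || labels[v] != 0) continue;
    ++next;
    stack.push_back(v);
    labels[v] = next;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      neighbours(u, nx, ny, nz, connectivity, nb);
      for (int w : nb) {
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

struct QItem {
  double priority;
  long long order;
  int voxel;
  int label;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;  // FIFO among equal priorities
  }
};

// Seeded watershed by priority flood: regions grow outward from the seed
// labels, always expanding through the currently brightest unassigned
// masked voxel, so region boundaries fall along intensity valleys.
// [[Rcpp::export(name = ".watershed_3d")]]
IntegerVector watershed_3d(NumericVector intensity, IntegerVector seeds,
                           LogicalVector mask, IntegerVector dim,
                           int connectivity = 26) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nvox = nx * ny * nz;
  IntegerVector labels(nvox, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  std::vector<char> queued(nvox, 0);
  std::vector<int> nb;
  long long order = 0;

  for (int v = 0; v < nvox; ++v) {
    if (seeds[v] > 0 && mask[v]) {
      pq.push({intensity[v], order++, v, seeds[v]});
      queued[v] = 1;
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    if (labels[it.voxel] != 0) continue;
    labels[it.voxel] = it.label;
    neighbours(it.voxel, nx, ny, nz, connectivity, nb);
    for (int w : nb) {
      if (mask[w] && labels[w] == 0 && !queued[w]) {
        pq.push({intensity[w], order++, w, it.label});
        queued[w] = 1;
      }
    }
  }
  return labels;
}
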