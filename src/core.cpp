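#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Arrays are dim = c(ny, nx, nz), column-major; linear index
// i = y + ny*(x + nx*z). 2D images have nz = 1, in which case the
// 26-neighbourhood degenerates to the 8-neighbourhood.

static inline void decode(int i, int ny, int nx, int &y, int &x, int &z) {
  y = i % ny;
  int r = i / ny;
  x = r % nx;
  z = r / nx;
}

// Collect linear indices of the (6 or 26) neighbours of voxel i.
static inline int neighbours(int i, int ny, int nx, int nz, int conn,
                             int *out) {
  int y, x, z;
  decode(i, ny, nx, y, x, z);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    int zz = z + dz;
    if (zz < 0 || zz >= nz) continue;
    for (int dx = -1; dx <= 1; ++dx) {
      int xx = x + dx;
      if (xx < 0 || xx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int man = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (conn == 6 && man != 1) continue;
        out[k++] = yy + ny * (xx + nx * zz);
      }
    }
  }
  return k;
}

// Connected-component labelling of a logical array.
// connectivity: 26 (default, 8 in 2D) or 6 (4 in 2D).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int n = ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int nb[26];
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int k = neighbours(v, ny, nx, nz, connectivity, nb);
      for (int j = 0; j < k; ++j) {
        int w = nb[j];
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

struct UF {
  std::vector<int> parent;
  int find(int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  }
};

// Plateau-aware local maxima by descending watershed flood with
// prominence-based merging.
//
// Voxels with mask && img > background are processed in decreasing
// intensity order. A voxel with no labelled neighbour starts a new peak;
// otherwise it joins the neighbouring peak with the highest summit. When
// two peaks first meet, the meeting intensity is the (highest) saddle of
// the lower peak; if summit - saddle < tolerance (<= when strict_merge,
// used for "prominence > p" counting) the lower peak is merged into the
// higher one, otherwise it survives with that prominence recorded.
// Equal-intensity plateaus resolve naturally: plateau fragments merge at
// prominence zero, so a plateau that is a true maximum yields exactly one
// peak and a shoulder plateau is absorbed by its higher neighbour.
//
// Returns labels (0 = unassigned) plus per-surviving-peak summaries.
// [[Rcpp::export]]
List find_peaks_cpp(NumericVector img, LogicalVector mask, IntegerVector dims,
                    double background, double tolerance, bool strict_merge) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int n = ny * nx * nz;
  std::vector<int> order;
  order.reserve(1024);
  for (int i = 0; i < n; ++i)
    if (mask[i] && img[i] > background) order.push_back(i);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (img[a] != img[b]) return img[a] > img[b];
    return a < b;
  });

  std::vector<int> lab(n, -1); // peak id per voxel
  UF uf;
  std::vector<double> summit;   // per peak id
  std::vector<double> minprom;  // smallest prominence at a survival decision
  std::vector<int> summit_vox;  // a voxel attaining the summit
  int nb[26];
  std::vector<int> roots;

  for (size_t t = 0; t < order.size(); ++t) {
    int v = order[t];
    int k = neighbours(v, ny, nx, nz, 26, nb);
    roots.clear();
    for (int j = 0; j < k; ++j) {
      int w = nb[j];
      if (lab[w] >= 0) {
        int r = uf.find(lab[w]);
        bool seen = false;
        for (int q : roots)
          if (q == r) { seen = true; break; }
        if (!seen) roots.push_back(r);
      }
    }
    if (roots.empty()) {
      int id = (int)summit.size();
      uf.parent.push_back(id);
      summit.push_back(img[v]);
      minprom.push_back(R_PosInf);
      summit_vox.push_back(v);
      lab[v] = id;
    } else {
      // winner = highest summit (ties: lower id, deterministic)
      int w = roots[0];
      for (int q : roots)
        if (summit[q] > summit[w] || (summit[q] == summit[w] && q < w)) w = q;
      lab[v] = w;
      for (int q : roots) {
        if (q == w) continue;
        double prom = summit[q] - img[v];
        bool merge = strict_merge ? (prom <= tolerance) : (prom < tolerance);
        if (merge) {
          uf.parent[q] = w;
        } else if (prom < minprom[q]) {
          minprom[q] = prom;
        }
      }
    }
  }

  // compress to surviving peaks, renumber 1..K
  int npk = (int)summit.size();
  std::vector<int> newid(npk, 0);
  int K = 0;
  for (int p = 0; p < npk; ++p)
    if (uf.find(p) == p) newid[p] = ++K;
  IntegerVector out(n, 0);
  for (int i = 0; i < n; ++i)
    if (lab[i] >= 0) out[i] = newid[uf.find(lab[i])];
  out.attr("dim") = dims;

  NumericVector pk_summit(K), pk_prom(K);
  IntegerVector pk_vox(K);
  for (int p = 0; p < npk; ++p) {
    if (uf.find(p) != p) continue;
    int id = newid[p] - 1;
    pk_summit[id] = summit[p];
    pk_prom[id] = minprom[p];
    pk_vox[id] = summit_vox[p] + 1; // 1-based for R
  }
  return List::create(_["labels"] = out, _["summit"] = pk_summit,
                      _["prominence"] = pk_prom, _["summit_voxel"] = pk_vox);
}

// Separable Gaussian blur with reflected boundaries; sigma is per axis in
// voxels, dims = c(ny, nx, nz). sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector img, IntegerVector dims,
                             NumericVector sigma) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int ext[3] = {ny, nx, nz};
  // strides along y, x, z
  int stride[3] = {1, ny, ny * nx};
  std::vector<double> a(img.begin(), img.end());
  std::vector<double> b(a.size());
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    int m = ext[ax];
    if (s <= 0 || m == 1) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    if (rad >= m) rad = m - 1;
    std::vector<double> ker(2 * rad + 1);
    double tot = 0;
    for (int j = -rad; j <= rad; ++j) {
      ker[j + rad] = std::exp(-0.5 * j * j / (s * s));
      tot += ker[j + rad];
    }
    for (double &w : ker) w /= tot;
    int st = stride[ax];
    // iterate over all lines along axis ax
    int n = ny * nx * nz;
    int nlines = n / m;
    int oth[2], osd[2], c = 0;
    for (int q = 0; q < 3; ++q)
      if (q != ax) { oth[c] = ext[q]; osd[c] = stride[q]; ++c; }
    for (int i1 = 0; i1 < oth[0]; ++i1) {
      for (int i2 = 0; i2 < oth[1]; ++i2) {
        int base = i1 * osd[0] + i2 * osd[1];
        for (int p = 0; p < m; ++p) {
          double acc = 0;
          for (int j = -rad; j <= rad; ++j) {
            int pp = p + j;
            if (pp < 0) pp = -pp - 1;          // reflect
            if (pp >= m) pp = 2 * m - pp - 1;  // reflect
            acc += ker[j + rad] * a[base + pp * st];
          }
          b[base + p * st] = acc;
        }
      }
    }
    (void)nlines;
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
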