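// 3D voxel primitives backing the segmentation pipeline.
// Arrays are R arrays with dim = c(nz, ny, nx); the z index varies fastest.
// All functions assume finite inputs; range checks happen on the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---- separable convolution with reflective boundaries ----------------------

// 1D convolution along one axis. kernel has odd length; reflective edges
// (scipy-style 'reflect'). Each line is copied into a padded contiguous
// buffer so the inner loop stays in L1 cache even for strided axes.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, int axis, const NumericVector& k) {
  int kl = k.size();
  int half = kl / 2;
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  R_xlen_t st = stride[axis];
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  std::vector<double> buf(len + 2 * half), res(len);
  const double* kp = &k[0];
  for (int a = 0; a < n[oa]; ++a) {
    for (int b = 0; b < n[ob]; ++b) {
      R_xlen_t base = stride[oa] * a + stride[ob] * b;
      for (int i = 0; i < len; ++i) buf[half + i] = in[base + st * i];
      for (int j = 0; j < half; ++j) {
        int pl = j;                       // maps to -1-j -> reflect j
        int pr = 2 * len - (len + j) - 1; // reflect len + j
        if (pl >= len) pl = len - 1;
        if (pr < 0) pr = 0;
        buf[half - 1 - j] = buf[half + pl];
        buf[half + len + j] = buf[half + pr];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        const double* bp = &buf[i];
        for (int j = 0; j < kl; ++j) acc += bp[j] * kp[j];
        res[i] = acc;
      }
      for (int i = 0; i < len; ++i) out[base + st * i] = res[i];
    }
  }
}

// [[Rcpp::export(name = ".conv_sep3")]]
NumericVector conv_sep3(NumericVector x, NumericVector kz, NumericVector ky,
                        NumericVector kx) {
  IntegerVector d = x.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nt = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(x.begin(), x.end()), b(nt);
  conv_axis(a, b, nz, ny, nx, 0, kz);
  conv_axis(b, a, nz, ny, nx, 1, ky);
  conv_axis(a, b, nz, ny, nx, 2, kx);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = d;
  return out;
}

// ---- emitter splatting ------------------------------------------------------

// Adds, for each emitter, brightness * (integrated separable Gaussian) to the
// grid. Voxel weights are integrals of the 1D Gaussian over the voxel extent,
// so a fully contained emitter deposits its brightness exactly.
// emitters: n x 4 matrix (z, y, x, brightness) in nm; origin = centre of
// voxel [1,1,1] in nm; spacing/sigma as (z, y, x) in nm.
// [[Rcpp::export(name = ".splat_gaussians")]]
NumericVector splat_gaussians(NumericVector grid, NumericMatrix emitters,
                              NumericVector spacing, NumericVector origin,
                              NumericVector sigma, double support) {
  IntegerVector d = grid.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  NumericVector out = clone(grid);
  const double s2 = std::sqrt(2.0);
  for (int e = 0; e < emitters.nrow(); ++e) {
    double pos[3] = {emitters(e, 0), emitters(e, 1), emitters(e, 2)};
    double bright = emitters(e, 3);
    if (bright <= 0) continue;
    int lo[3], hi[3];
    int n[3] = {nz, ny, nx};
    std::vector<std::vector<double>> w(3);
    for (int ax = 0; ax < 3; ++ax) {
      double c = (pos[ax] - origin[ax]) / spacing[ax];  // in voxel units
      double rad = support * sigma[ax] / spacing[ax];
      lo[ax] = std::max(0, (int)std::floor(c - rad));
      hi[ax] = std::min(n[ax] - 1, (int)std::ceil(c + rad));
      if (lo[ax] > hi[ax]) { lo[ax] = 0; hi[ax] = -1; }
      w[ax].resize(std::max(0, hi[ax] - lo[ax] + 1));
      for (int i = lo[ax]; i <= hi[ax]; ++i) {
        double a = origin[ax] + (i - 0.5) * spacing[ax];
        double b = a + spacing[ax];
        double za = (a - pos[ax]) / (sigma[ax] * s2);
        double zb = (b - pos[ax]) / (sigma[ax] * s2);
        w[ax][i - lo[ax]] = 0.5 * (std::erf(zb) - std::erf(za));
      }
    }
    for (int x = lo[2]; x <= hi[2]; ++x)
      for (int y = lo[1]; y <= hi[1]; ++y) {
        double wyx = w[2][x - lo[2]] * w[1][y - lo[1]];
        if (wyx == 0) continue;
        R_xlen_t base = idx3(0, y, x, nz, ny);
        for (int z = lo[0]; z <= hi[0]; ++z)
          out[base + z] += bright * wyx * w[0][z - lo[0]];
      }
  }
  out.attr("dim") = d;
  return out;
}

// ---- connected-component labelling (26-connectivity) ------------------------

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nt = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(nt, 0);
  lab.attr("dim") = d;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nt; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              continue;
            R_xlen_t q = idx3(z2, y2, x2, nz, ny);
            if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// ---- binary morphology with an explicit offset list --------------------------

// offsets: k x 3 integer matrix of (dz, dy, dx). For erosion, out-of-bounds
// neighbours count as foreground (no spurious border erosion); for dilation
// they count as background.
// [[Rcpp::export(name = ".morph3d")]]
LogicalVector morph3d(LogicalVector mask, IntegerMatrix offsets, bool dilate) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nt = (R_xlen_t)nz * ny * nx;
  LogicalVector out(nt);
  out.attr("dim") = d;
  int k = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool v = dilate ? false : true;
        for (int j = 0; j < k; ++j) {
          int z2 = z + offsets(j, 0), y2 = y + offsets(j, 1), x2 = x + offsets(j, 2);
          bool inb = z2 >= 0 && z2 < nz && y2 >= 0 && y2 < ny && x2 >= 0 && x2 < nx;
          bool m = inb ? (bool)mask[idx3(z2, y2, x2, nz, ny)] : false;
          if (dilate) { if (m) { v = true; break; } }
          else { if (!(inb ? m : true)) { v = false; break; } }
        }
        out[idx3(z, y, x, nz, ny)] = v;
      }
  return out;
}

// ---- hole filling ------------------------------------------------------------

// 3D: background voxels 6-connected to the array border stay background,
// every other voxel becomes foreground.
// [[Rcpp::export(name = ".fill_holes3d")]]
LogicalVector fill_holes3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nt = (R_xlen_t)nz * ny * nx;
  std::vector<char> outside(nt, 0);
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z && z != nz - 1 && y && y != ny - 1 && x && x != nx - 1) continue;
        R_xlen_t p = idx3(z, y, x, nz, ny);
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  const int dz6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t p = stack.back(); stack.pop_back();
    int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
    for (int j = 0; j < 6; ++j) {
      int z2 = z + dz6[j], y2 = y + dy6[j], x2 = x + dx6[j];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
      R_xlen_t q = idx3(z2, y2, x2, nz, ny);
      if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(nt);
  out.attr("dim") = d;
  for (R_xlen_t p = 0; p < nt; ++p) out[p] = mask[p] || !outside[p];
  return out;
}

// 2D hole filling applied to every slice perpendicular to `axis`
// (0 = z slices are ny*nx planes, etc.). 4-connectivity in-plane.
// [[Rcpp::export(name = ".fill_holes_slices")]]
LogicalVector fill_holes_slices(LogicalVector mask, int axis) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  int n[3] = {nz, ny, nx};
  R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  int na = n[oa], nb = n[ob];
  LogicalVector out = clone(mask);
  std::vector<char> outside((R_xlen_t)na * nb);
  std::vector<int> stack;
  for (int s = 0; s < n[axis]; ++s) {
    R_xlen_t base = stride[axis] * s;
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nb; ++b) {
        if (a && a != na - 1 && b && b != nb - 1) continue;
        R_xlen_t p = base + stride[oa] * a + stride[ob] * b;
        int f = a * nb + b;
        if (!mask[p] && !outside[f]) { outside[f] = 1; stack.push_back(f); }
      }
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      int a = f / nb, b = f % nb;
      const int da[4] = {1, -1, 0, 0}, db[4] = {0, 0, 1, -1};
      for (int j = 0; j < 4; ++j) {
        int a2 = a + da[j], b2 = b + db[j];
        if (a2 < 0 || a2 >= na || b2 < 0 || b2 >= nb) continue;
        int f2 = a2 * nb + b2;
        R_xlen_t p2 = base + stride[oa] * a2 + stride[ob] * b2;
        if (!mask[p2] && !outside[f2]) { outside[f2] = 1; stack.push_back(f2); }
      }
    }
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nb; ++b)
        if (!outside[a * nb + b])
          out[base + stride[oa] * a + stride[ob] * b] = true;
  }
  return out;
}

// ---- local maxima and seeded watershed ---------------------------------------

// A foreground voxel is a local maximum if no 26-neighbour inside the
// foreground has a strictly greater value. Plateaus yield several marks;
// the R side collapses touching marks into one seed.
// [[Rcpp::export(name = ".local_maxima")]]
LogicalVector local_maxima(NumericVector v, LogicalVector mask) {
  IntegerVector d = v.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nt = (R_xlen_t)nz * ny * nx;
  LogicalVector out(nt);
  out.attr("dim") = d;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t p = idx3(z, y, x, nz, ny);
        if (!mask[p]) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dz && !dy && !dx) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
                continue;
              R_xlen_t q = idx3(z2, y2, x2, nz, ny);
              if (mask[q] && v[q] > v[p]) { ismax = false; break; }
            }
        out[p] = ismax;
      }
  return out;
}

// Watershed by descending region growing: voxels are claimed from the seed
// fronts in order of decreasing landscape value, so labels meet at the
// intensity minima between peaks. Restricted to the foreground mask.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerVector watershed_seeded(NumericVector v, LogicalVector mask,
                               IntegerVector seeds) {
  IntegerVector d = v.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nt = (R_xlen_t)nz * ny * nx;
  IntegerVector lab = clone(seeds);
  lab.attr("dim") = d;
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node> pq;  // max-heap on value
  for (R_xlen_t p = 0; p < nt; ++p)
    if (lab[p] > 0 && mask[p]) pq.push(Node(v[p], p));
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    R_xlen_t p = nd.second;
    int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
    int l = lab[p];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z2 = z + dz, y2 = y + dy, x2 = x + dx;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          R_xlen_t q = idx3(z2, y2, x2, nz, ny);
          if (mask[q] && lab[q] == 0) {
            lab[q] = l;
            pq.push(Node(v[q], q));
          }
        }
  }
  return lab;
}
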