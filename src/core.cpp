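#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest sampling of a 3-D array at continuous ZERO-based voxel
// coordinates. Coordinates outside the grid return `fill`. For trilinear
// interpolation a coordinate counts as inside when it lies within the convex
// hull of voxel centers ([0, n-1] per axis).
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector data, IntegerVector dims,
                                NumericMatrix coords, int linear, double fill) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *d = REAL(data);
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  for (R_xlen_t i = 0; i < n; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (linear) {
      if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
        out[i] = fill;
        continue;
      }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
      if (x0 == n1 - 1) x0--;
      if (y0 == n2 - 1) y0--;
      if (z0 == n3 - 1) z0--;
      if (x0 < 0) x0 = 0;
      if (y0 < 0) y0 = 0;
      if (z0 < 0) z0 = 0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      R_xlen_t base = x0 + (R_xlen_t)y0 * s2 + (R_xlen_t)z0 * s3;
      double c000 = d[base],           c100 = d[base + 1];
      double c010 = d[base + s2],      c110 = d[base + s2 + 1];
      double c001 = d[base + s3],      c101 = d[base + s3 + 1];
      double c011 = d[base + s2 + s3], c111 = d[base + s2 + s3 + 1];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[i] = c0 * (1 - fz) + c1 * fz;
    } else {
      long xi = (long)std::lround(x), yi = (long)std::lround(y), zi = (long)std::lround(z);
      if (xi < 0 || yi < 0 || zi < 0 || xi >= n1 || yi >= n2 || zi >= n3) {
        out[i] = fill;
      } else {
        out[i] = d[xi + (R_xlen_t)yi * s2 + (R_xlen_t)zi * s3];
      }
    }
  }
  return out;
}

// Resample a moving volume onto an output grid. A is a 3x4 affine taking
// ZERO-based output voxel indices to ZERO-based continuous moving voxel
// coordinates.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector mov, IntegerVector mdims,
                           IntegerVector odims, NumericMatrix A,
                           int linear, double fill) {
  const int o1 = odims[0], o2 = odims[1], o3 = odims[2];
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  const double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2), a14 = A(0,3);
  const double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2), a24 = A(1,3);
  const double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2), a34 = A(2,3);
  NumericMatrix c(1, 3);
  const int n1 = mdims[0], n2 = mdims[1], n3 = mdims[2];
  const double *d = REAL(mov);
  double *po = REAL(out);
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  R_xlen_t idx = 0;
  for (int k = 0; k < o3; ++k) {
    for (int j = 0; j < o2; ++j) {
      double xj = a12 * j + a13 * k + a14;
      double yj = a22 * j + a23 * k + a24;
      double zj = a32 * j + a33 * k + a34;
      for (int i = 0; i < o1; ++i, ++idx) {
        double x = a11 * i + xj, y = a21 * i + yj, z = a31 * i + zj;
        if (linear) {
          if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
            po[idx] = fill;
            continue;
          }
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
          if (x0 == n1 - 1) x0--;
          if (y0 == n2 - 1) y0--;
          if (z0 == n3 - 1) z0--;
          double fx = x - x0, fy = y - y0, fz = z - z0;
          R_xlen_t base = x0 + (R_xlen_t)y0 * s2 + (R_xlen_t)z0 * s3;
          double c00 = d[base] * (1 - fx) + d[base + 1] * fx;
          double c10 = d[base + s2] * (1 - fx) + d[base + s2 + 1] * fx;
          double c01 = d[base + s3] * (1 - fx) + d[base + s3 + 1] * fx;
          double c11 = d[base + s2 + s3] * (1 - fx) + d[base + s2 + s3 + 1] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          po[idx] = c0 * (1 - fz) + c1 * fz;
        } else {
          long xi = (long)std::lround(x), yi = (long)std::lround(y), zi = (long)std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= n1 || yi >= n2 || zi >= n3) {
            po[idx] = fill;
          } else {
            po[idx] = d[xi + (R_xlen_t)yi * s2 + (R_xlen_t)zi * s3];
          }
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary volume (values 0/1) under 6- or
// 26-connectivity. Labels are 1..K in scan order of the first voxel seen.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector labels(n);
  const int *m = INTEGER(mask);
  int *lab = INTEGER(labels);

  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nn = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!m[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      int rem = (int)(v % ((R_xlen_t)n1 * n2));
      int j = rem / n1, i = rem % n1;
      for (int q = 0; q < nn; ++q) {
        int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
        R_xlen_t w = ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2;
        if (m[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Background voxels (mask==0) reachable from the array border under
// 6-connectivity; used for 3-D hole filling.
// [[Rcpp::export]]
LogicalVector cpp_border_background(IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector reach(n);
  const int *m = INTEGER(mask);
  int *r = LOGICAL(reach);
  std::vector<R_xlen_t> stack;

  auto push = [&](int i, int j, int k) {
    R_xlen_t v = i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
    if (!m[v] && !r[v]) { r[v] = 1; stack.push_back(v); }
  };
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      push(0, j, k); push(n1 - 1, j, k);
    }
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      push(i, 0, k); push(i, n2 - 1, k);
    }
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      push(i, j, 0); push(i, j, n3 - 1);
    }

  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int k = (int)(v / ((R_xlen_t)n1 * n2));
    int rem = (int)(v % ((R_xlen_t)n1 * n2));
    int j = rem / n1, i = rem % n1;
    for (int q = 0; q < 6; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
      R_xlen_t w = ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2;
      if (!m[w] && !r[w]) { r[w] = 1; stack.push_back(w); }
    }
  }
  return reach;
}

// Binary erosion (op=0) or dilation (op=1) with an explicit offset list
// (K x 3, voxel offsets). Outside-of-grid neighbours count as background.
// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerVector dims,
                               IntegerMatrix offsets, int op) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(n);
  const int *m = INTEGER(mask);
  int *o = INTEGER(out);
  const int K = offsets.nrow();
  std::vector<int> ox(K), oy(K), oz(K);
  for (int q = 0; q < K; ++q) { ox[q] = offsets(q,0); oy[q] = offsets(q,1); oz[q] = offsets(q,2); }

  R_xlen_t v = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++v) {
        if (op == 0) {
          // erosion: all neighbours (including implicit out-of-grid = 0) must be 1
          if (!m[v]) { o[v] = 0; continue; }
          int keep = 1;
          for (int q = 0; q < K; ++q) {
            int ii = i + ox[q], jj = j + oy[q], kk = k + oz[q];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) { keep = 0; break; }
            if (!m[ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2]) { keep = 0; break; }
          }
          o[v] = keep;
        } else {
          // dilation: any neighbour 1 sets the voxel
          if (m[v]) { o[v] = 1; continue; }
          int hit = 0;
          for (int q = 0; q < K; ++q) {
            int ii = i + ox[q], jj = j + oy[q], kk = k + oz[q];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
            if (m[ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2]) { hit = 1; break; }
          }
          o[v] = hit;
        }
      }
  return out;
}

// Weighted tabulate: sums weights into 1-based integer bins.
// [[Rcpp::export]]
NumericVector cpp_weighted_tab(IntegerVector idx, NumericVector w, int nbins) {
  NumericVector out(nbins);
  double *o = REAL(out);
  const int *pi = INTEGER(idx);
  const double *pw = REAL(w);
  const R_xlen_t n = idx.size();
  for (R_xlen_t t = 0; t < n; ++t) {
    int b = pi[t];
    if (b >= 1 && b <= nbins) o[b - 1] += pw[t];
  }
  return out;
}

// Separable box SUM over a w^3 window (w odd). Border handling: the returned
// count array gives the number of in-grid voxels in each window so callers can
// normalise to a mean.
// [[Rcpp::export]]
List cpp_box_sum(NumericVector data, IntegerVector dims, int w) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const int h = w / 2;
  NumericVector acc = clone(data);
  NumericVector cnt(n, 1.0);

  auto pass = [&](NumericVector &src, int axis) {
    NumericVector dst(n);
    double *ps = REAL(src), *pd = REAL(dst);
    int len = (axis == 0) ? n1 : (axis == 1 ? n2 : n3);
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1 ? n1 : (R_xlen_t)n1 * n2);
    // iterate over all lines along `axis`
    for (int k = 0; k < (axis == 2 ? 1 : n3); ++k)
      for (int j = 0; j < (axis == 1 ? 1 : n2); ++j)
        for (int i = 0; i < (axis == 0 ? 1 : n1); ++i) {
          R_xlen_t base;
          if (axis == 0) base = (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
          else if (axis == 1) base = i + (R_xlen_t)k * n1 * n2;
          else base = i + (R_xlen_t)j * n1;
          // prefix sums along the line
          double run = 0;
          std::vector<double> pre(len + 1, 0.0);
          for (int t = 0; t < len; ++t) {
            run += ps[base + (R_xlen_t)t * stride];
            pre[t + 1] = run;
          }
          for (int t = 0; t < len; ++t) {
            int lo = t - h; if (lo < 0) lo = 0;
            int hi = t + h; if (hi > len - 1) hi = len - 1;
            pd[base + (R_xlen_t)t * stride] = pre[hi + 1] - pre[lo];
          }
        }
    src = dst;
  };

  for (int axis = 0; axis < 3; ++axis) {
    pass(acc, axis);
    pass(cnt, axis);
  }
  return List::create(_["sum"] = acc, _["count"] = cnt);
}
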