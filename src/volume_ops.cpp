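#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D array with per-axis sigma in voxel
// units. Reflecting boundary. Kernel truncated at 4 sigma. Axes with
// sigma <= 0 are passed through.
// [[Rcpp::export(name = ".gauss_smooth3d")]]
NumericVector gauss_smooth3d(NumericVector vol, NumericVector sigma) {
  IntegerVector dim = vol.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;

  std::vector<double> src(vol.begin(), vol.end());
  std::vector<double> dst(n);

  const int strides[3] = {1, nx, nx * ny};
  const int extents[3] = {nx, ny, nz};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (double &v : k) v /= ksum;

    const int len = extents[ax];
    const int stride = strides[ax];
    // iterate over all lines along axis `ax`
    const int oa = (ax == 0) ? 1 : 0;           // first other axis
    const int ob = (ax == 2) ? 1 : 2;           // second other axis
    const int la = extents[oa], lb = extents[ob];
    const int sa = strides[oa], sb = strides[ob];
    for (int b = 0; b < lb; ++b) {
      for (int a = 0; a < la; ++a) {
        const int base = a * sa + b * sb;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int idx = i + j;
            // mirror boundary, iterated so kernels wider than the axis
            // still reflect correctly
            while (idx < 0 || idx >= len) {
              if (idx < 0) idx = -idx - 1;
              if (idx >= len) idx = 2 * len - idx - 1;
            }
            acc += k[j + r] * src[base + idx * stride];
          }
          dst[base + i * stride] = acc;
        }
      }
    }
    std::swap(src, dst);
  }

  NumericVector out(src.begin(), src.end());
  out.attr("dim") = dim;
  return out;
}

// In-place painting of gray values / labels at linear voxel indices
// (1-based). The scene arrays are owned solely by the generator's scene
// environment, so in-place modification is safe and avoids a full-array
// copy per stamped primitive.
// [[Rcpp::export(name = ".paint_gray")]]
void paint_gray(NumericVector img, IntegerVector idx, double value) {
  for (R_xlen_t m = 0; m < idx.size(); ++m) img[idx[m] - 1] = value;
}

// [[Rcpp::export(name = ".paint_label")]]
void paint_label(IntegerVector lab, IntegerVector idx, int value) {
  for (R_xlen_t m = 0; m < idx.size(); ++m) lab[idx[m] - 1] = value;
}

// 3D connected-component labelling of a logical mask with 6- or
// 26-connectivity. Breadth-first search; labels assigned in column-major
// scan order of the first foreground voxel of each component.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const size_t nn = offx.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t m = 0; m < nn; ++m) {
        int x = cx + offx[m], y = cy + offy[m], z = cz + offz[m];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// Binary closing of a mask along all axes by a 6-connected structuring
// element applied `iter` times (dilate then erode). Used to bridge the
// synaptic cleft between pre- and postsynaptic densities when the
// threshold leaves them disconnected.
// [[Rcpp::export(name = ".binary_close3d")]]
LogicalVector binary_close3d(LogicalVector mask, int iter) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> a(mask.begin(), mask.end()), b(n);

  auto pass = [&](std::vector<char> &in, std::vector<char> &out, bool dilate) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
          char v = in[i];
          for (int m = 0; m < 6 && (dilate ? !v : v); ++m) {
            static const int dx[6] = {1,-1,0,0,0,0};
            static const int dy[6] = {0,0,1,-1,0,0};
            static const int dz[6] = {0,0,0,0,1,-1};
            int X = x + dx[m], Y = y + dy[m], Z = z + dz[m];
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            char u = in[(R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X];
            if (dilate && u) v = 1;
            if (!dilate && !u) v = 0;
          }
          out[i] = v;
        }
  };

  for (int it = 0; it < iter; ++it) { pass(a, b, true);  std::swap(a, b); }
  for (int it = 0; it < iter; ++it) { pass(a, b, false); std::swap(a, b); }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i] != 0;
  out.attr("dim") = dim;
  return out;
}
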