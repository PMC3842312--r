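#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Separable 1D convolution along one axis of a 3D array, with the truncated
// kernel renormalised at the edges so that constant fields are preserved.
static void conv_axis(std::vector<double> &a, const int nx, const int ny,
                      const int nz, const NumericVector &k, const int axis) {
  const int hw = (k.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const int len = n[axis];
  std::vector<double> line(len), out(len);
  // strides of a flat x-fastest layout
  const int sx = 1, sy = nx, sz = nx * ny;
  const int stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z) {
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y) {
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        const int base = x * sx + y * sy + z * sz;
        for (int i = 0; i < len; ++i) line[i] = a[base + i * stride];
        for (int i = 0; i < len; ++i) {
          double acc = 0.0, wsum = 0.0;
          const int j0 = std::max(0, i - hw), j1 = std::min(len - 1, i + hw);
          for (int j = j0; j <= j1; ++j) {
            const double w = k[j - i + hw];
            acc += w * line[j];
            wsum += w;
          }
          out[i] = acc / wsum;
        }
        for (int i = 0; i < len; ++i) a[base + i * stride] = out[i];
      }
    }
  }
}

// [[Rcpp::export(name = ".smooth3d_c")]]
NumericVector smooth3d_c(NumericVector arr, IntegerVector dim,
                         NumericVector kx, NumericVector ky, NumericVector kz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvol = arr.size() / (nx * ny * nz);
  NumericVector res(arr.size());
  std::vector<double> a((size_t)nx * ny * nz);
  for (int v = 0; v < nvol; ++v) {
    const size_t off = (size_t)v * nx * ny * nz;
    for (size_t i = 0; i < a.size(); ++i) a[i] = arr[off + i];
    if (kx.size() > 1) conv_axis(a, nx, ny, nz, kx, 0);
    if (ky.size() > 1) conv_axis(a, nx, ny, nz, ky, 1);
    if (kz.size() > 1) conv_axis(a, nx, ny, nz, kz, 2);
    for (size_t i = 0; i < a.size(); ++i) res[off + i] = a[i];
  }
  res.attr("dim") = arr.attr("dim");
  return res;
}

// Connected components of a 3D logical grid under 6/18/26 connectivity.
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export(name = ".label_components_c")]]
IntegerVector label_components_c(LogicalVector supra, IntegerVector dim,
                                 int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(supra.size(), 0);
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  int next = 0;
  std::queue<int> q;
  for (int idx = 0; idx < supra.size(); ++idx) {
    if (!supra[idx] || lab[idx] != 0) continue;
    lab[idx] = ++next;
    q.push(idx);
    while (!q.empty()) {
      const int cur = q.front(); q.pop();
      const int cz = cur / (nx * ny), cy = (cur / nx) % ny, cx = cur % nx;
      for (size_t k = 0; k < dxs.size(); ++k) {
        const int x = cx + dxs[k], y = cy + dys[k], z = cz + dzs[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const int nb = x + nx * (y + ny * z);
        if (supra[nb] && lab[nb] == 0) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
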