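#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// reflect index i (0-based) into [0, n)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2D median filter with w x w window and reflected borders,
// applied to a depth map (surface z-coordinates).
// [[Rcpp::export]]
NumericMatrix cpp_median2d(NumericMatrix z, int w) {
  int ny = z.nrow(), nx = z.ncol(), h = w / 2;
  NumericMatrix out(ny, nx);
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      buf.clear();
      for (int dx = -h; dx <= h; ++dx) {
        int xx = reflect(x + dx, nx);
        for (int dy = -h; dy <= h; ++dy) {
          buf.push_back(z(reflect(y + dy, ny), xx));
        }
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m - 1]);
      }
      out(y, x) = med;
    }
  }
  return out;
}

// 3D median filter (window w^3, borders clipped to the volume) applied
// only at voxels with z >= zsurf(y, x); voxels above the surface are
// copied unchanged. vol has dim (nz, ny, nx), z fastest.
// [[Rcpp::export]]
NumericVector cpp_median3d_below(NumericVector vol, IntegerVector dim,
                                 NumericMatrix zsurf, int w) {
  int nz = dim[0], ny = dim[1], nx = dim[2], h = w / 2;
  NumericVector out(clone(vol));
  std::vector<double> buf;
  buf.reserve((size_t)w * w * w);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      int z0 = (int)zsurf(y, x) - 1;  // first filtered depth, 0-based
      if (z0 < 0) z0 = 0;
      if (z0 >= nz) continue;
      for (int z = z0; z < nz; ++z) {
        buf.clear();
        int xa = std::max(0, x - h), xb = std::min(nx - 1, x + h);
        int ya = std::max(0, y - h), yb = std::min(ny - 1, y + h);
        int za = std::max(0, z - h), zb = std::min(nz - 1, z + h);
        for (int xx = xa; xx <= xb; ++xx)
          for (int yy = ya; yy <= yb; ++yy) {
            const double *col = v + ((size_t)xx * ny + yy) * nz;
            for (int zz = za; zz <= zb; ++zz) buf.push_back(col[zz]);
          }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1,
                           buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        o[((size_t)x * ny + y) * nz + z] = med;
      }
    }
  }
  return out;
}

// Per-column first threshold crossing scanning downward from zstart.
// rising: first z with I >= thr; falling: first z with I <= thr.
// Columns with no crossing get the deepest scanned index and found=false.
// [[Rcpp::export]]
List cpp_first_crossing(NumericVector vol, IntegerVector dim, double thr,
                        bool rising, IntegerMatrix zstart) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerMatrix zout(ny, nx);
  LogicalMatrix found(ny, nx);
  const double *v = vol.begin();
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      int z0 = zstart(y, x) - 1;  // to 0-based
      if (z0 < 0) z0 = 0;
      if (z0 > nz - 1) z0 = nz - 1;
      const double *col = v + ((size_t)x * ny + y) * nz;
      int hit = -1;
      for (int z = z0; z < nz; ++z) {
        double I = col[z];
        if ((rising && I >= thr) || (!rising && I <= thr)) { hit = z; break; }
      }
      if (hit >= 0) {
        zout(y, x) = hit + 1;
        found(y, x) = true;
      } else {
        zout(y, x) = nz;
        found(y, x) = false;
      }
    }
  }
  return List::create(_["z"] = zout, _["found"] = found);
}
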