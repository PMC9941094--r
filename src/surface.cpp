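#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope scan; distances in voxel units squared.

static const double DT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// seed: logical, TRUE where distance is zero; returns squared distance (voxel units)
static void edt3d(std::vector<double>& g, int n) {
  std::vector<double> f(n), d(n);
  // along x
  for (int z = 0; z < n; ++z)
    for (int y = 0; y < n; ++y) {
      double* row = &g[(size_t)z * n * n + (size_t)y * n];
      for (int x = 0; x < n; ++x) f[x] = row[x];
      dt1d(f, d, n);
      for (int x = 0; x < n; ++x) row[x] = d[x];
    }
  // along y
  for (int z = 0; z < n; ++z)
    for (int x = 0; x < n; ++x) {
      for (int y = 0; y < n; ++y) f[y] = g[(size_t)z * n * n + (size_t)y * n + x];
      dt1d(f, d, n);
      for (int y = 0; y < n; ++y) g[(size_t)z * n * n + (size_t)y * n + x] = d[y];
    }
  // along z
  for (int y = 0; y < n; ++y)
    for (int x = 0; x < n; ++x) {
      for (int z = 0; z < n; ++z) f[z] = g[(size_t)z * n * n + (size_t)y * n + x];
      dt1d(f, d, n);
      for (int z = 0; z < n; ++z) g[(size_t)z * n * n + (size_t)y * n + x] = d[z];
    }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector seed, int n, double spacing) {
  std::vector<double> g((size_t)n * n * n);
  for (size_t i = 0; i < g.size(); ++i) g[i] = seed[i] ? 0.0 : DT_INF;
  edt3d(g, n);
  NumericVector out((size_t)n * n * n);
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]) * spacing;
  return out;
}

// Solvent-excluded volume on a cubic grid.
// Two passes: (1) inflate each atom by the probe radius and mark covered voxels,
// (2) erode by the probe: voxels closer than the probe radius to any voxel
// outside the inflated volume are solvent-reachable and removed.
// Grid: n points per axis, voxel i at origin + i*spacing (same on all axes).
// [[Rcpp::export]]
List cpp_ses(NumericMatrix coords, NumericVector radii, int n, double spacing,
             double origin, double probe) {
  const size_t n3 = (size_t)n * n * n;
  std::vector<char> inflated(n3, 0);
  const int natom = coords.nrow();
  for (int a = 0; a < natom; ++a) {
    const double R = radii[a] + probe;
    const double R2 = R * R;
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ilo = std::max(0, (int)std::ceil((ax - R - origin) / spacing));
    int ihi = std::min(n - 1, (int)std::floor((ax + R - origin) / spacing));
    int jlo = std::max(0, (int)std::ceil((ay - R - origin) / spacing));
    int jhi = std::min(n - 1, (int)std::floor((ay + R - origin) / spacing));
    int klo = std::max(0, (int)std::ceil((az - R - origin) / spacing));
    int khi = std::min(n - 1, (int)std::floor((az + R - origin) / spacing));
    for (int k = klo; k <= khi; ++k) {
      double dz = origin + k * spacing - az;
      for (int j = jlo; j <= jhi; ++j) {
        double dy = origin + j * spacing - ay;
        double dyz = dy * dy + dz * dz;
        if (dyz > R2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          double dx = origin + i * spacing - ax;
          if (dx * dx + dyz <= R2)
            inflated[(size_t)k * n * n + (size_t)j * n + i] = 1;
        }
      }
    }
  }
  // squared distance (voxel units) to nearest voxel outside the inflated volume
  std::vector<double> g(n3);
  for (size_t i = 0; i < n3; ++i) g[i] = inflated[i] ? DT_INF : 0.0;
  edt3d(g, n);
  const double probe_vox2 = (probe / spacing) * (probe / spacing);
  LogicalVector interior(n3), infl(n3);
  for (size_t i = 0; i < n3; ++i) {
    infl[i] = inflated[i] != 0;
    interior[i] = inflated[i] && g[i] > probe_vox2;
  }
  return List::create(_["interior"] = interior, _["inflated"] = infl);
}
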