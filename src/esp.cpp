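#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// e^2 / (eps0 * kB * 298 K) expressed in Angstrom; with this constant the
// potential of a unit charge in a uniform dielectric eps is
//   u(r) = ESP_CONST / (4 * pi * eps * r)   [kT/e, r in Angstrom]
// (Bjerrum length in water ~ 7 A falls out as ESP_CONST / (4 pi * 80)).
static const double ESP_CONST = 7046.20;
static const double FOURPI = 12.566370614359172;

// Debye-Hueckel / screened-Coulomb superposition over point charges.
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix coords, NumericVector charges, int n,
                        double spacing, double origin, double eps_out,
                        double kappa, double clamp) {
  const size_t n3 = (size_t)n * n * n;
  NumericVector phi(n3);
  const int natom = coords.nrow();
  for (int a = 0; a < natom; ++a) {
    const double q = charges[a];
    if (q == 0.0) continue;
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double pref = ESP_CONST * q / (FOURPI * eps_out);
    size_t idx = 0;
    for (int k = 0; k < n; ++k) {
      double dz = origin + k * spacing - az, dz2 = dz * dz;
      for (int j = 0; j < n; ++j) {
        double dy = origin + j * spacing - ay, dyz = dy * dy + dz2;
        for (int i = 0; i < n; ++i, ++idx) {
          double dx = origin + i * spacing - ax;
          double r = std::sqrt(dx * dx + dyz);
          if (r < clamp) r = clamp;
          phi[idx] += (kappa > 0.0) ? pref * std::exp(-kappa * r) / r : pref / r;
        }
      }
    }
  }
  return phi;
}

static inline double bc_value(const NumericMatrix& coords, const NumericVector& charges,
                              double x, double y, double z, double eps_out,
                              double kappa, double clamp) {
  double u = 0.0;
  for (int a = 0; a < coords.nrow(); ++a) {
    if (charges[a] == 0.0) continue;
    double dx = x - coords(a, 0), dy = y - coords(a, 1), dz = z - coords(a, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < clamp) r = clamp;
    double v = ESP_CONST * charges[a] / (FOURPI * eps_out * r);
    if (kappa > 0.0) v *= std::exp(-kappa * r);
    u += v;
  }
  return u;
}

// Finite-difference linearized Poisson-Boltzmann:
//   div(eps grad u) - eps_bar kappa^2 u = -ESP_CONST * sum q_i delta(r - r_i)
// u in kT/e.  7-point stencil, harmonic-mean face dielectric from the
// interior/exterior map, trilinear charge spreading, Debye-Hueckel Dirichlet
// boundary, SOR iteration.  kappa applies on solvent (exterior) nodes only.
// [[Rcpp::export]]
List cpp_pb_solve(NumericMatrix coords, NumericVector charges, LogicalVector interior,
                  int n, double spacing, double origin, double eps_in, double eps_out,
                  double kappa, double tol, int maxit) {
  const size_t n3 = (size_t)n * n * n;
  const size_t nn = (size_t)n * n;
  const double h = spacing;

  // node dielectric
  std::vector<double> eps(n3);
  for (size_t i = 0; i < n3; ++i) eps[i] = interior[i] ? eps_in : eps_out;

  // trilinear charge spreading -> source term b = ESP_CONST * q_vox / h
  std::vector<double> b(n3, 0.0);
  double bnorm = 0.0;
  for (int a = 0; a < coords.nrow(); ++a) {
    double q = charges[a];
    if (q == 0.0) continue;
    double fx = (coords(a, 0) - origin) / h;
    double fy = (coords(a, 1) - origin) / h;
    double fz = (coords(a, 2) - origin) / h;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= n - 1 || j0 >= n - 1 || k0 >= n - 1)
      stop("charge outside the grid");
    double wx = fx - i0, wy = fy - j0, wz = fz - k0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
          b[(size_t)(k0 + dk) * nn + (size_t)(j0 + dj) * n + (i0 + di)] +=
            ESP_CONST * q * w / h;
        }
  }
  for (size_t i = 0; i < n3; ++i) bnorm += std::fabs(b[i]);
  if (bnorm == 0.0) bnorm = 1.0;

  // solution with Dirichlet boundary
  std::vector<double> u(n3, 0.0);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        if (i > 0 && i < n - 1 && j > 0 && j < n - 1 && k > 0 && k < n - 1) continue;
        u[(size_t)k * nn + (size_t)j * n + i] =
          bc_value(coords, charges, origin + i * h, origin + j * h, origin + k * h,
                   eps_out, kappa, 0.5 * h);
      }

  const double k2h2 = kappa * kappa * h * h;
  const double omega = 2.0 / (1.0 + std::sin(M_PI / n));
  double resid = R_PosInf;
  int it = 0;
  bool converged = false;
  auto hm = [](double a, double bb) { return 2.0 * a * bb / (a + bb); };
  while (it < maxit) {
    ++it;
    for (int k = 1; k < n - 1; ++k)
      for (int j = 1; j < n - 1; ++j)
        for (int i = 1; i < n - 1; ++i) {
          size_t id = (size_t)k * nn + (size_t)j * n + i;
          double e0 = eps[id];
          double exm = hm(e0, eps[id - 1]), exp_ = hm(e0, eps[id + 1]);
          double eym = hm(e0, eps[id - n]), eyp = hm(e0, eps[id + n]);
          double ezm = hm(e0, eps[id - nn]), ezp = hm(e0, eps[id + nn]);
          double ion = interior[id] ? 0.0 : e0 * k2h2;
          double num = exm * u[id - 1] + exp_ * u[id + 1] + eym * u[id - n] +
                       eyp * u[id + n] + ezm * u[id - nn] + ezp * u[id + nn] + b[id];
          double den = exm + exp_ + eym + eyp + ezm + ezp + ion;
          u[id] += omega * (num / den - u[id]);
        }
    if (it % 10 == 0 || it == maxit) {
      double r1 = 0.0;
      for (int k = 1; k < n - 1; ++k)
        for (int j = 1; j < n - 1; ++j)
          for (int i = 1; i < n - 1; ++i) {
            size_t id = (size_t)k * nn + (size_t)j * n + i;
            double e0 = eps[id];
            double exm = hm(e0, eps[id - 1]), exp_ = hm(e0, eps[id + 1]);
            double eym = hm(e0, eps[id - n]), eyp = hm(e0, eps[id + n]);
            double ezm = hm(e0, eps[id - nn]), ezp = hm(e0, eps[id + nn]);
            double ion = interior[id] ? 0.0 : e0 * k2h2;
            double res = exm * u[id - 1] + exp_ * u[id + 1] + eym * u[id - n] +
                         eyp * u[id + n] + ezm * u[id - nn] + ezp * u[id + nn] +
                         b[id] - (exm + exp_ + eym + eyp + ezm + ezp + ion) * u[id];
            r1 += std::fabs(res);
          }
      resid = r1 / bnorm;
      if (resid < tol) { converged = true; break; }
    }
  }
  NumericVector phi(n3);
  for (size_t i = 0; i < n3; ++i) phi[i] = u[i];
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = resid, _["converged"] = converged);
}

// Sum of atom-centered Gaussians exp(-r^2 / width^2), unit height, cutoff 3*width.
// [[Rcpp::export]]
NumericVector cpp_gaussian_density(NumericMatrix coords, NumericVector widths, int n,
                                   double spacing, double origin) {
  const size_t n3 = (size_t)n * n * n;
  NumericVector dens(n3);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double w = widths[a];
    if (w <= 0) continue;
    const double cut = 3.0 * w, cut2 = cut * cut, inv_w2 = 1.0 / (w * w);
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ilo = std::max(0, (int)std::ceil((ax - cut - origin) / spacing));
    int ihi = std::min(n - 1, (int)std::floor((ax + cut - origin) / spacing));
    int jlo = std::max(0, (int)std::ceil((ay - cut - origin) / spacing));
    int jhi = std::min(n - 1, (int)std::floor((ay + cut - origin) / spacing));
    int klo = std::max(0, (int)std::ceil((az - cut - origin) / spacing));
    int khi = std::min(n - 1, (int)std::floor((az + cut - origin) / spacing));
    for (int k = klo; k <= khi; ++k) {
      double dz = origin + k * spacing - az, dz2 = dz * dz;
      for (int j = jlo; j <= jhi; ++j) {
        double dy = origin + j * spacing - ay, dyz = dy * dy + dz2;
        if (dyz > cut2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          double dx = origin + i * spacing - ax;
          double r2 = dx * dx + dyz;
          if (r2 <= cut2)
            dens[(size_t)k * n * n + (size_t)j * n + i] += std::exp(-r2 * inv_w2);
        }
      }
    }
  }
  return dens;
}
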