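#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Per-atom, per-axis phase-factor tables exp(2*pi*i * m * xfrac_axis) for
// integer index m in [-mmax, mmax]. Turns the per-(atom, reflection) phase
// into three complex multiplications instead of a sin/cos pair.
struct PhaseTables {
  int na;
  int mmax[3];
  std::vector<double> re[3], im[3];  // na x (2*mmax+1), column-major by m
  void build(const NumericMatrix& H, const NumericMatrix& xfrac) {
    na = xfrac.nrow();
    for (int ax = 0; ax < 3; ++ax) {
      int mm = 0;
      for (int h = 0; h < H.nrow(); ++h) {
        int v = (int)std::lround(std::fabs(H(h, ax)));
        if (v > mm) mm = v;
      }
      mmax[ax] = mm;
      const int nm = 2 * mm + 1;
      re[ax].assign((size_t)na * nm, 0.0);
      im[ax].assign((size_t)na * nm, 0.0);
      for (int i = 0; i < na; ++i) {
        const double c1 = std::cos(2.0 * M_PI * xfrac(i, ax));
        const double s1 = std::sin(2.0 * M_PI * xfrac(i, ax));
        double cr = 1.0, ci = 0.0;  // m = 0
        at(ax, i, 0) = 1.0;
        ati(ax, i, 0) = 0.0;
        for (int m = 1; m <= mm; ++m) {
          const double nr_ = cr * c1 - ci * s1;
          ci = cr * s1 + ci * c1;
          cr = nr_;
          at(ax, i, m) = cr;  ati(ax, i, m) = ci;
          at(ax, i, -m) = cr; ati(ax, i, -m) = -ci;
        }
      }
    }
  }
  inline double& at(int ax, int i, int m) {
    return re[ax][(size_t)(m + mmax[ax]) * na + i];
  }
  inline double& ati(int ax, int i, int m) {
    return im[ax][(size_t)(m + mmax[ax]) * na + i];
  }
  inline const double* col_re(int ax, int m) const {
    return &re[ax][(size_t)(m + mmax[ax]) * na];
  }
  inline const double* col_im(int ax, int m) const {
    return &im[ax][(size_t)(m + mmax[ax]) * na];
  }
};

// Direct-summation structure factors in P1.
// H: nrefl x 3 Miller indices (double), xfrac: natoms x 3 fractional coords,
// W: natoms x nrefl per-atom/per-reflection weights occ * f_elem(s) * exp(-B s^2/4).
// [[Rcpp::export]]
ComplexVector cpp_structure_factors(NumericMatrix H, NumericMatrix xfrac,
                                    NumericMatrix W) {
  const int nr = H.nrow(), na = xfrac.nrow();
  PhaseTables pt;
  pt.build(H, xfrac);
  ComplexVector F(nr);
  for (int h = 0; h < nr; ++h) {
    const int h1 = (int)std::lround(H(h, 0));
    const int h2 = (int)std::lround(H(h, 1));
    const int h3 = (int)std::lround(H(h, 2));
    const double *ar = pt.col_re(0, h1), *ai = pt.col_im(0, h1);
    const double *br = pt.col_re(1, h2), *bi = pt.col_im(1, h2);
    const double *cr = pt.col_re(2, h3), *ci = pt.col_im(2, h3);
    double re = 0.0, im = 0.0;
    for (int i = 0; i < na; ++i) {
      const double tr = ar[i] * br[i] - ai[i] * bi[i];
      const double ti = ar[i] * bi[i] + ai[i] * br[i];
      re += W(i, h) * (tr * cr[i] - ti * ci[i]);
      im += W(i, h) * (tr * ci[i] + ti * cr[i]);
    }
    F[h].r = re;
    F[h].i = im;
  }
  return F;
}

// Least-squares amplitude target and its analytic coordinate gradient.
//   E = w_xray * sum_target (fobs - k |F|)^2,  k fitted over target reflections.
// Gcart: nrefl x 3, row h = 2*pi * t(Mfrac) %*% h (gradient of the phase wrt
// Cartesian coordinates). target: logical, which reflections enter the target
// (work set). The scale k minimises E so treating it constant in the gradient
// is exact (envelope theorem).
// [[Rcpp::export]]
List cpp_xray_energy_forces(NumericMatrix H, NumericMatrix Gcart,
                            NumericMatrix xfrac, NumericMatrix W,
                            NumericVector fobs, LogicalVector target,
                            double w_xray) {
  const int nr = H.nrow(), na = xfrac.nrow();
  std::vector<double> C((size_t)na * nr), S((size_t)na * nr);
  PhaseTables pt;
  pt.build(H, xfrac);
  NumericVector Fre(nr), Fim(nr), Fabs(nr);
  for (int h = 0; h < nr; ++h) {
    const int h1 = (int)std::lround(H(h, 0));
    const int h2 = (int)std::lround(H(h, 1));
    const int h3 = (int)std::lround(H(h, 2));
    const double *ar = pt.col_re(0, h1), *ai = pt.col_im(0, h1);
    const double *br = pt.col_re(1, h2), *bi = pt.col_im(1, h2);
    const double *cr = pt.col_re(2, h3), *ci = pt.col_im(2, h3);
    double re = 0.0, im = 0.0;
    const size_t off = (size_t)h * na;
    for (int i = 0; i < na; ++i) {
      const double tr = ar[i] * br[i] - ai[i] * bi[i];
      const double ti = ar[i] * bi[i] + ai[i] * br[i];
      const double c = tr * cr[i] - ti * ci[i];
      const double s = tr * ci[i] + ti * cr[i];
      C[off + i] = c;
      S[off + i] = s;
      re += W(i, h) * c;
      im += W(i, h) * s;
    }
    Fre[h] = re;
    Fim[h] = im;
    Fabs[h] = std::sqrt(re * re + im * im);
  }
  double num = 0.0, den = 0.0;
  for (int h = 0; h < nr; ++h) {
    if (target[h]) {
      num += fobs[h] * Fabs[h];
      den += Fabs[h] * Fabs[h];
    }
  }
  if (den <= 0.0) stop("all calculated amplitudes are zero; cannot scale");
  const double k = num / den;
  double E = 0.0;
  NumericMatrix forces(na, 3);
  for (int h = 0; h < nr; ++h) {
    if (!target[h]) continue;
    const double r = fobs[h] - k * Fabs[h];
    E += r * r;
    if (Fabs[h] < 1e-12) continue;
    // dE/dx_i = -2 w k r d|F|/dx_i ; d|F|/dx_i = -W_ih sin(phi_ih - psi_h) g_h
    const double coef = 2.0 * w_xray * k * r / Fabs[h];
    const double g1 = Gcart(h, 0), g2 = Gcart(h, 1), g3 = Gcart(h, 2);
    const size_t off = (size_t)h * na;
    for (int i = 0; i < na; ++i) {
      // sin(phi - psi) |F| = S*Re(F) - C*Im(F)
      const double t = coef * W(i, h) * (S[off + i] * Fre[h] - C[off + i] * Fim[h]);
      // force = -dE/dx = -t * g  (t already carries the sign chain)
      forces(i, 0) -= t * g1;
      forces(i, 1) -= t * g2;
      forces(i, 2) -= t * g3;
    }
  }
  ComplexVector F(nr);
  for (int h = 0; h < nr; ++h) { F[h].r = Fre[h]; F[h].i = Fim[h]; }
  return List::create(_["energy"] = w_xray * E, _["forces"] = forces,
                      _["scale"] = k, _["f_calc"] = F);
}

// Work-set residual and analytic per-atom B gradient at fixed coordinates.
// fa: natoms x nrefl (occ * f_elem(s)); Cm/Sm: cos/sin of atomic phases;
// s2: nrefl vector of (1/d)^2.
// [[Rcpp::export]]
List cpp_bfactor_residual(NumericMatrix fa, NumericMatrix Cm, NumericMatrix Sm,
                          NumericVector s2, NumericVector B,
                          NumericVector fobs, LogicalVector target) {
  const int na = fa.nrow(), nr = fa.ncol();
  NumericVector Fre(nr), Fim(nr), Fabs(nr);
  std::vector<double> Wm((size_t)na * nr);
  for (int h = 0; h < nr; ++h) {
    double re = 0.0, im = 0.0;
    const size_t off = (size_t)h * na;
    for (int i = 0; i < na; ++i) {
      const double w = fa(i, h) * std::exp(-B[i] * s2[h] * 0.25);
      Wm[off + i] = w;
      re += w * Cm(i, h);
      im += w * Sm(i, h);
    }
    Fre[h] = re; Fim[h] = im;
    Fabs[h] = std::sqrt(re * re + im * im);
  }
  double num = 0.0, den = 0.0;
  for (int h = 0; h < nr; ++h)
    if (target[h]) { num += fobs[h] * Fabs[h]; den += Fabs[h] * Fabs[h]; }
  if (den <= 0.0) stop("all calculated amplitudes are zero; cannot scale");
  const double k = num / den;
  double E = 0.0;
  NumericVector grad(na);
  for (int h = 0; h < nr; ++h) {
    if (!target[h]) continue;
    const double r = fobs[h] - k * Fabs[h];
    E += r * r;
    if (Fabs[h] < 1e-12) continue;
    const double coef = -2.0 * k * r / Fabs[h] * (-s2[h] * 0.25);
    const size_t off = (size_t)h * na;
    for (int i = 0; i < na; ++i) {
      // d|F|/dB_i = Re(conj(F)/|F| dF/dB_i), dF/dB_i = -s2/4 W_ih e^{i phi}
      grad[i] += coef * Wm[off + i] * (Cm(i, h) * Fre[h] + Sm(i, h) * Fim[h]);
    }
  }
  return List::create(_["energy"] = E, _["grad"] = grad, _["scale"] = k);
}

// DEN elastic network: E = w_den * sum (d_ij - d0_ij)^2 over restrained pairs.
// ii, jj are 1-based atom indices.
// [[Rcpp::export]]
List cpp_den_energy_forces(IntegerVector ii, IntegerVector jj, NumericVector d0,
                           NumericMatrix xyz, double w_den) {
  const int n = ii.size(), na = xyz.nrow();
  double E = 0.0;
  NumericMatrix forces(na, 3);
  for (int p = 0; p < n; ++p) {
    const int i = ii[p] - 1, j = jj[p] - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-8) stop("coincident restrained atoms (singular geometry)");
    const double dev = d - d0[p];
    E += dev * dev;
    const double c = -2.0 * w_den * dev / d;  // force = -dE/dx
    forces(i, 0) += c * dx; forces(i, 1) += c * dy; forces(i, 2) += c * dz;
    forces(j, 0) -= c * dx; forces(j, 1) -= c * dy; forces(j, 2) -= c * dz;
  }
  return List::create(_["energy"] = w_den * E, _["forces"] = forces);
}

// Current distances of restrained pairs.
// [[Rcpp::export]]
NumericVector cpp_pair_distances(IntegerVector ii, IntegerVector jj,
                                 NumericMatrix xyz) {
  const int n = ii.size();
  NumericVector d(n);
  for (int p = 0; p < n; ++p) {
    const int i = ii[p] - 1, j = jj[p] - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    d[p] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return d;
}

// Simplified stereochemical term: harmonic bonds and angles plus a purely
// repulsive quartic contact term for non-excluded pairs closer than their
// contact radius. bonds: nb x 2 (1-based); angles: nang x 3, middle atom is
// the vertex. rcon: per-atom repulsion radius; pair contact radius is
// rfac * (rcon_i + rcon_j). excl: ne x 2 pairs exempt from repulsion.
// [[Rcpp::export]]
List cpp_geom_energy_forces(NumericMatrix xyz,
                            IntegerMatrix bonds, NumericVector b0, NumericVector kb,
                            IntegerMatrix angles, NumericVector a0, NumericVector ka,
                            NumericVector rcon, double rfac, double krep,
                            IntegerMatrix excl) {
  const int na = xyz.nrow();
  double E = 0.0;
  NumericMatrix forces(na, 3);

  for (int p = 0; p < bonds.nrow(); ++p) {
    const int i = bonds(p, 0) - 1, j = bonds(p, 1) - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-8) stop("coincident bonded atoms");
    const double dev = d - b0[p];
    E += kb[p] * dev * dev;
    const double c = -2.0 * kb[p] * dev / d;
    forces(i, 0) += c * dx; forces(i, 1) += c * dy; forces(i, 2) += c * dz;
    forces(j, 0) -= c * dx; forces(j, 1) -= c * dy; forces(j, 2) -= c * dz;
  }

  for (int p = 0; p < angles.nrow(); ++p) {
    const int i = angles(p, 0) - 1, j = angles(p, 1) - 1, k = angles(p, 2) - 1;
    double ux = xyz(i, 0) - xyz(j, 0), uy = xyz(i, 1) - xyz(j, 1), uz = xyz(i, 2) - xyz(j, 2);
    double vx = xyz(k, 0) - xyz(j, 0), vy = xyz(k, 1) - xyz(j, 1), vz = xyz(k, 2) - xyz(j, 2);
    const double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    const double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-8 || nv < 1e-8) stop("degenerate angle geometry");
    double cth = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    const double th = std::acos(cth);
    const double dev = th - a0[p];
    E += ka[p] * dev * dev;
    double sth = std::sqrt(1.0 - cth * cth);
    if (sth < 1e-8) sth = 1e-8;
    const double coef = 2.0 * ka[p] * dev / sth;  // -dE/dtheta * (-1/sin)
    // dcos/dri = v/(nu nv) - cth u/nu^2 ; dtheta/dri = -(1/sth) dcos/dri
    const double gix = coef * (vx / (nu * nv) - cth * ux / (nu * nu));
    const double giy = coef * (vy / (nu * nv) - cth * uy / (nu * nu));
    const double giz = coef * (vz / (nu * nv) - cth * uz / (nu * nu));
    const double gkx = coef * (ux / (nu * nv) - cth * vx / (nv * nv));
    const double gky = coef * (uy / (nu * nv) - cth * vy / (nv * nv));
    const double gkz = coef * (uz / (nu * nv) - cth * vz / (nv * nv));
    forces(i, 0) += gix; forces(i, 1) += giy; forces(i, 2) += giz;
    forces(k, 0) += gkx; forces(k, 1) += gky; forces(k, 2) += gkz;
    forces(j, 0) -= gix + gkx; forces(j, 1) -= giy + gky; forces(j, 2) -= giz + gkz;
  }

  std::unordered_set<long long> ex;
  ex.reserve((size_t)excl.nrow() * 2);
  for (int p = 0; p < excl.nrow(); ++p) {
    long long i = excl(p, 0) - 1, j = excl(p, 1) - 1;
    if (i > j) std::swap(i, j);
    ex.insert(i * (long long)na + j);
  }
  for (int i = 0; i < na; ++i) {
    for (int j = i + 1; j < na; ++j) {
      const double rc = rfac * (rcon[i] + rcon[j]);
      const double dx = xyz(i, 0) - xyz(j, 0);
      if (std::fabs(dx) > rc) continue;
      const double dy = xyz(i, 1) - xyz(j, 1);
      if (std::fabs(dy) > rc) continue;
      const double dz = xyz(i, 2) - xyz(j, 2);
      if (std::fabs(dz) > rc) continue;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= rc * rc) continue;
      if (ex.count((long long)i * na + j)) continue;
      const double d = std::sqrt(d2);
      if (d < 1e-8) stop("coincident nonbonded atoms");
      const double gap = rc - d;
      E += krep * gap * gap * gap * gap;
      const double c = 4.0 * krep * gap * gap * gap / d;  // -dE/dd = +4 krep gap^3
      forces(i, 0) += c * dx; forces(i, 1) += c * dy; forces(i, 2) += c * dz;
      forces(j, 0) -= c * dx; forces(j, 1) -= c * dy; forces(j, 2) -= c * dz;
    }
  }
  return List::create(_["energy"] = E, _["forces"] = forces);
}
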