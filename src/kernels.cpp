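// Force and constraint kernels for the coarse-grained MD engine.
//
// Units: kcal/mol, Angstrom, ps, g/mol, elementary charges. The Coulomb
// prefactor (332.063713 kcal A / mol e^2) is passed in from R so that the
// single named constant lives in one place.
//
// Conventions: orthorhombic periodic boxes with minimum-image convention;
// site indices are 0-based throughout this file (R wrappers convert).
// The scalar virial W accumulated here is Tr(sum r x F), so that
// P = (2K + W) / (3V).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline double mimg(double d, double L) { return d - L * std::round(d / L); }

// x^e for small positive integer e (exponentiation by squaring)
static inline double ipow(double x, int e) {
  double r = 1.0;
  while (e) { if (e & 1) r *= x; x *= x; e >>= 1; }
  return r;
}

static inline std::uint64_t pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (std::uint64_t)i * (std::uint64_t)n + (std::uint64_t)j;
}

// ---------------------------------------------------------------------------
// Verlet neighbour list: all pairs within rlist (cutoff + skin).
// O(N^2) scan; systems handled here are a few thousand sites.
// [[Rcpp::export]]
IntegerMatrix cg_nblist(NumericMatrix pos, NumericVector box, double rlist) {
  const int n = pos.nrow();
  const double r2 = rlist * rlist;
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double* X = REAL(pos);
  const double* Y = X + n;
  const double* Z = Y + n;
  std::vector<int> ii, jj;
  ii.reserve(n * 32); jj.reserve(n * 32);
  // coordinates are never wrapped during dynamics, so the exact (round-based)
  // minimum image is required here, not a single fold
  for (int i = 0; i < n - 1; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = mimg(X[j] - xi, Lx);
      if (dx > rlist || dx < -rlist) continue;
      const double dy = mimg(Y[j] - yi, Ly);
      const double dz = mimg(Z[j] - zi, Lz);
      if (dx * dx + dy * dy + dz * dz < r2) { ii.push_back(i); jj.push_back(j); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise Mie + real-space (erfc-screened) Coulomb over a neighbour list,
// with intramolecular exclusions, optional 1-4 scaling, and the Ewald
// exclusion corrections (which must be applied independent of the cutoff).
//
// excl and pairs14 are 0-based two-column matrices. If ewald is false the
// Coulomb term is plain truncated 1/r (no corrections needed).
// [[Rcpp::export]]
List cg_pair_forces(NumericMatrix pos, NumericVector box,
                    IntegerVector type, NumericVector charge,
                    NumericMatrix epsM, NumericMatrix nM, NumericMatrix mM,
                    NumericMatrix r0M, NumericMatrix shiftM,
                    NumericMatrix fshiftM,
                    double cutoff, int trunc_mode,
                    IntegerMatrix pairs,
                    IntegerMatrix excl, IntegerMatrix pairs14, double scale14,
                    bool ewald, double alpha, double coulomb_const,
                    double min_sep) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double rc2 = cutoff * cutoff;
  const double two_over_sqrtpi = 2.0 / std::sqrt(M_PI);

  std::unordered_set<std::uint64_t> exset;
  std::unordered_set<std::uint64_t> set14;
  for (int k = 0; k < excl.nrow(); ++k)
    exset.insert(pair_key(excl(k, 0), excl(k, 1), n));
  for (int k = 0; k < pairs14.nrow(); ++k)
    set14.insert(pair_key(pairs14(k, 0), pairs14(k, 1), n));

  NumericMatrix F(n, 3);
  double e_mie = 0.0, e_real = 0.0, e_corr = 0.0, W = 0.0;

  for (int k = 0; k < pairs.nrow(); ++k) {
    const int i = pairs(k, 0), j = pairs(k, 1);
    double dx = mimg(pos(j, 0) - pos(i, 0), Lx);
    double dy = mimg(pos(j, 1) - pos(i, 1), Ly);
    double dz = mimg(pos(j, 2) - pos(i, 2), Lz);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rc2) continue;
    std::uint64_t key = pair_key(i, j, n);
    if (exset.count(key)) continue;
    double s = set14.count(key) ? scale14 : 1.0;
    if (s == 0.0) continue;
    const double r = std::sqrt(r2);
    if (r < min_sep)
      stop("overlapping sites: pair (%d, %d) at r = %g A", i + 1, j + 1, r);

    const int ti = type[i], tj = type[j];
    double dUdr = 0.0;
    const double eps = epsM(ti, tj);
    if (eps > 0.0) {
      const double nn = nM(ti, tj), mm = mM(ti, tj), r0 = r0M(ti, tj);
      const double C = eps / (nn - mm);
      const int ni = (int)nn, mi = (int)mm;
      const double rat = r0 / r;
      double sn, sm;
      if (nn == ni && mm == mi) { sn = ipow(rat, ni); sm = ipow(rat, mi); }
      else { sn = std::pow(rat, nn); sm = std::pow(rat, mm); }
      double u = C * (mm * sn - nn * sm);
      double du = -C * nn * mm * (sn - sm) / r;
      if (trunc_mode >= 1) u -= shiftM(ti, tj);
      if (trunc_mode == 2) {   // shifted-force: remove the force discontinuity
        u -= (r - cutoff) * fshiftM(ti, tj);
        du -= fshiftM(ti, tj);
      }
      e_mie += s * u;
      dUdr += s * du;
    }
    const double qq = charge[i] * charge[j];
    if (qq != 0.0) {
      const double pref = coulomb_const * qq;
      if (ewald) {
        const double er = std::erfc(alpha * r);
        e_real += s * pref * er / r;
        dUdr += s * pref * (-er / r2 - two_over_sqrtpi * alpha *
                            std::exp(-alpha * alpha * r2) / r);
      } else {
        e_real += s * pref / r;
        dUdr += s * (-pref / r2);
      }
    }
    // F_j = -dU/dr * rhat_ij (d points i -> j)
    const double fr = -dUdr / r;
    F(i, 0) -= fr * dx; F(i, 1) -= fr * dy; F(i, 2) -= fr * dz;
    F(j, 0) += fr * dx; F(j, 1) += fr * dy; F(j, 2) += fr * dz;
    W += -dUdr * r;
  }

  // Ewald corrections: the reciprocal sum contains every pair, so excluded
  // (or scaled) intramolecular pairs must have their erf-screened part
  // removed. Applied without cutoff (the pairs are bonded neighbours).
  if (ewald) {
    auto correct = [&](int i, int j, double want) {
      const double qq = charge[i] * charge[j];
      if (qq == 0.0) return;
      double dx = mimg(pos(j, 0) - pos(i, 0), Lx);
      double dy = mimg(pos(j, 1) - pos(i, 1), Ly);
      double dz = mimg(pos(j, 2) - pos(i, 2), Lz);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r = std::sqrt(r2);
      const double pref = coulomb_const * qq * (want - 1.0);
      const double er = std::erf(alpha * r);
      e_corr += pref * er / r;
      const double dUdr = pref * (-er / r2 + two_over_sqrtpi * alpha *
                                  std::exp(-alpha * alpha * r2) / r);
      const double fr = -dUdr / r;
      F(i, 0) -= fr * dx; F(i, 1) -= fr * dy; F(i, 2) -= fr * dz;
      F(j, 0) += fr * dx; F(j, 1) += fr * dy; F(j, 2) += fr * dz;
      W += -dUdr * r;
    };
    for (int k = 0; k < excl.nrow(); ++k) correct(excl(k, 0), excl(k, 1), 0.0);
    if (scale14 != 1.0)
      for (int k = 0; k < pairs14.nrow(); ++k)
        correct(pairs14(k, 0), pairs14(k, 1), scale14);
  }

  return List::create(_["e_mie"] = e_mie, _["e_real"] = e_real,
                      _["e_corr"] = e_corr, _["forces"] = F, _["virial"] = W);
}

// ---------------------------------------------------------------------------
// Reciprocal-space Ewald sum.
// E = (C 2 pi / V) sum_{k != 0} exp(-k^2/4a^2)/k^2 |S(k)|^2 over the half
// space (doubled), with S(k) = sum_i q_i exp(i k . r_i).
// [[Rcpp::export]]
List cg_ewald_recip(NumericMatrix pos, NumericVector q, NumericVector box,
                    double alpha, IntegerVector kmax, double coulomb_const) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double V = Lx * Ly * Lz;
  const int kx_max = kmax[0], ky_max = kmax[1], kz_max = kmax[2];
  const double twopi = 2.0 * M_PI;

  // exp(i 2 pi n x / L) tables built by recursion
  auto build = [&](int dim, int km, double L,
                   std::vector<double>& re, std::vector<double>& im) {
    re.assign((size_t)(km + 1) * n, 0.0);
    im.assign((size_t)(km + 1) * n, 0.0);
    for (int i = 0; i < n; ++i) { re[i] = 1.0; im[i] = 0.0; }
    if (km >= 1) {
      for (int i = 0; i < n; ++i) {
        const double a = twopi * pos(i, dim) / L;
        re[n + i] = std::cos(a); im[n + i] = std::sin(a);
      }
      for (int kk = 2; kk <= km; ++kk)
        for (int i = 0; i < n; ++i) {
          const size_t p = (size_t)kk * n + i, p1 = (size_t)(kk - 1) * n + i;
          re[p] = re[p1] * re[n + i] - im[p1] * im[n + i];
          im[p] = re[p1] * im[n + i] + im[p1] * re[n + i];
        }
    }
  };
  std::vector<double> exr, exi, eyr, eyi, ezr, ezi;
  build(0, kx_max, Lx, exr, exi);
  build(1, ky_max, Ly, eyr, eyi);
  build(2, kz_max, Lz, ezr, ezi);

  NumericMatrix F(n, 3);
  double* F0 = REAL(F);               // column-major: F0, F0+n, F0+2n
  std::vector<double> qv(n), exyr(n), exyi(n), fr(n), fi(n);
  std::vector<double> fx_acc(n, 0.0), fy_acc(n, 0.0), fz_acc(n, 0.0);
  for (int i = 0; i < n; ++i) qv[i] = q[i];
  double E = 0.0, W = 0.0;
  const double a2 = alpha * alpha;
  const double prefE = coulomb_const * twopi / V;
  // spherical reciprocal cutoff matching the rectangular kmax limits
  const double gmax = std::max(std::max(twopi * kx_max / Lx,
                                        twopi * ky_max / Ly),
                               twopi * kz_max / Lz);
  const double g2max = gmax * gmax * 1.0000001;

  for (int kx = 0; kx <= kx_max; ++kx) {
    const double gx = twopi * kx / Lx;
    const double* xr = &exr[(size_t)kx * n];
    const double* xi = &exi[(size_t)kx * n];
    for (int ky = (kx == 0 ? 0 : -ky_max); ky <= ky_max; ++ky) {
      const double gy = twopi * ky / Ly;
      if (gx * gx + gy * gy > g2max) continue;
      const int aky = std::abs(ky);
      const double ysign = (ky < 0) ? -1.0 : 1.0;
      const double* yr = &eyr[(size_t)aky * n];
      const double* yi = &eyi[(size_t)aky * n];
      for (int i = 0; i < n; ++i) {
        const double i2 = ysign * yi[i];
        exyr[i] = xr[i] * yr[i] - xi[i] * i2;
        exyi[i] = xr[i] * i2 + xi[i] * yr[i];
      }
      for (int kz = ((kx == 0 && ky == 0) ? 1 : -kz_max); kz <= kz_max; ++kz) {
        const double gz = twopi * kz / Lz;
        const double k2 = gx * gx + gy * gy + gz * gz;
        if (k2 > g2max) continue;
        const double A = std::exp(-k2 / (4.0 * a2)) / k2;
        if (A < 1e-14) continue;

        const int akz = std::abs(kz);
        const double zsign = (kz < 0) ? -1.0 : 1.0;
        const double* zr = &ezr[(size_t)akz * n];
        const double* zi = &ezi[(size_t)akz * n];
        double Sr = 0.0, Si = 0.0;
        for (int i = 0; i < n; ++i) {
          const double i3 = zsign * zi[i];
          const double er = exyr[i] * zr[i] - exyi[i] * i3;
          const double ei = exyr[i] * i3 + exyi[i] * zr[i];
          fr[i] = er; fi[i] = ei;
          Sr += qv[i] * er; Si += qv[i] * ei;
        }
        const double s2 = Sr * Sr + Si * Si;
        const double Ek = 2.0 * prefE * A * s2;   // half-space doubling
        E += Ek;
        W += Ek * (1.0 - k2 / (2.0 * a2));
        const double fpref = 4.0 * prefE * A;     // dE/dS * half-space
        for (int i = 0; i < n; ++i) {
          // Im(conj(S) * e^{ik r_i}) = Sr*fi - Si*fr
          const double c = fpref * qv[i] * (Sr * fi[i] - Si * fr[i]);
          fx_acc[i] += c * gx; fy_acc[i] += c * gy; fz_acc[i] += c * gz;
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    F0[i] = fx_acc[i]; F0[n + i] = fy_acc[i]; F0[2 * n + i] = fz_acc[i];
  }
  return List::create(_["energy"] = E, _["forces"] = F, _["virial"] = W);
}

// ---------------------------------------------------------------------------
// Bonded terms: harmonic bonds/bends and cosine dihedrals.
// bonds: (i, j, k, r0); bends: (i, j, k, ktheta, theta0);
// dihedrals: (i, j, k, l, amp, mult, delta). Indices 0-based (stored as
// doubles in the matrices). Geometry uses minimum-image displacements.
// [[Rcpp::export]]
List cg_bonded(NumericMatrix pos, NumericVector box,
               NumericMatrix bonds, NumericMatrix bends, NumericMatrix dihs) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  NumericMatrix F(n, 3);
  double e_bond = 0.0, e_bend = 0.0, e_dih = 0.0, W = 0.0;

  auto delta = [&](int i, int j, double* d) {  // r_j - r_i, min image
    d[0] = mimg(pos(j, 0) - pos(i, 0), Lx);
    d[1] = mimg(pos(j, 1) - pos(i, 1), Ly);
    d[2] = mimg(pos(j, 2) - pos(i, 2), Lz);
  };

  for (int t = 0; t < bonds.nrow(); ++t) {
    const int i = (int)bonds(t, 0), j = (int)bonds(t, 1);
    const double kf = bonds(t, 2), r0 = bonds(t, 3);
    double d[3]; delta(i, j, d);
    const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    const double dr = r - r0;
    e_bond += 0.5 * kf * dr * dr;
    const double dUdr = kf * dr;
    const double fr = -dUdr / r;
    F(i, 0) -= fr * d[0]; F(i, 1) -= fr * d[1]; F(i, 2) -= fr * d[2];
    F(j, 0) += fr * d[0]; F(j, 1) += fr * d[1]; F(j, 2) += fr * d[2];
    W += -dUdr * r;
  }

  for (int t = 0; t < bends.nrow(); ++t) {
    const int i = (int)bends(t, 0), j = (int)bends(t, 1), k = (int)bends(t, 2);
    const double kt = bends(t, 3), th0 = bends(t, 4);
    double u[3], v[3];
    delta(j, i, u);  // j -> i
    delta(j, k, v);  // j -> k
    const double lu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    const double lv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
    double c = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (lu * lv);
    c = std::max(-1.0, std::min(1.0, c));
    const double th = std::acos(c);
    const double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
    const double dUdth = kt * (th - th0);
    e_bend += 0.5 * kt * (th - th0) * (th - th0);
    // dtheta/dr_i = -1/(lu * s) * (v/lv - c*u/lu), etc.
    double fi[3], fk[3];
    for (int a = 0; a < 3; ++a) {
      fi[a] = -dUdth * (-1.0 / (lu * s)) * (v[a] / lv - c * u[a] / lu);
      fk[a] = -dUdth * (-1.0 / (lv * s)) * (u[a] / lu - c * v[a] / lv);
    }
    for (int a = 0; a < 3; ++a) {
      F(i, a) += fi[a];
      F(k, a) += fk[a];
      F(j, a) -= fi[a] + fk[a];
    }
    // virial from local coordinates (u at i, v at k, origin at j)
    W += fi[0]*u[0]+fi[1]*u[1]+fi[2]*u[2] + fk[0]*v[0]+fk[1]*v[1]+fk[2]*v[2];
  }

  for (int t = 0; t < dihs.nrow(); ++t) {
    const int i = (int)dihs(t, 0), j = (int)dihs(t, 1);
    const int k = (int)dihs(t, 2), l = (int)dihs(t, 3);
    const double amp = dihs(t, 4), mult = dihs(t, 5), del = dihs(t, 6);
    double b1[3], b2[3], b3[3];
    delta(i, j, b1); delta(j, k, b2); delta(k, l, b3);
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
    const double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    const double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    const double lb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;  // colinear: torsion undefined, zero force
    double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2], n1[0]*b2[1]-n1[1]*b2[0] };
    const double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    const double y = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / lb2;
    const double phi = std::atan2(y, x);
    e_dih += amp * (1.0 + std::cos(mult * phi - del));
    const double dUdphi = -amp * mult * std::sin(mult * phi - del);
    // standard torsion force distribution
    double f1[3], f4[3];
    for (int a = 0; a < 3; ++a) {
      f1[a] = -dUdphi * lb2 / n1sq * n1[a];
      f4[a] =  dUdphi * lb2 / n2sq * n2[a];
    }
    const double tc = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (lb2 * lb2);
    const double td = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (lb2 * lb2);
    double f2[3], f3[3];
    for (int a = 0; a < 3; ++a) {
      f2[a] = -(1.0 + tc) * f1[a] + td * f4[a];
      f3[a] = tc * f1[a] - (1.0 + td) * f4[a];
    }
    for (int a = 0; a < 3; ++a) {
      F(i, a) += f1[a]; F(j, a) += f2[a]; F(k, a) += f3[a]; F(l, a) += f4[a];
    }
    // virial via local coordinates relative to site j
    double ri[3] = { -b1[0], -b1[1], -b1[2] };
    double rk[3] = { b2[0], b2[1], b2[2] };
    double rl[3] = { b2[0]+b3[0], b2[1]+b3[1], b2[2]+b3[2] };
    for (int a = 0; a < 3; ++a)
      W += f1[a]*ri[a] + f3[a]*rk[a] + f4[a]*rl[a];
  }

  return List::create(_["e_bond"] = e_bond, _["e_bend"] = e_bend,
                      _["e_dih"] = e_dih, _["forces"] = F, _["virial"] = W);
}

// ---------------------------------------------------------------------------
// SHAKE for rigid 3-site waters: restores the two O-H distances and the H-H
// distance. pos_old is the pre-step (constraint-satisfying) configuration
// whose bond vectors direct the corrections; pass pos_old = pos_new for a
// pure iterative projection. If dt > 0 velocities receive dr/dt.
// [[Rcpp::export]]
List cg_shake_waters(NumericMatrix pos_new, NumericMatrix pos_old,
                     NumericMatrix vel, IntegerMatrix waters,
                     NumericVector mass, NumericVector box,
                     double dOH, double dHH, double tol, int maxit, double dt,
                     double acc_conv) {
  NumericMatrix p = clone(pos_new);
  NumericMatrix v = clone(vel);
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const int nw = waters.nrow();
  int iter = 0;
  bool converged = (nw == 0);
  double Wc = 0.0;   // constraint virial, Tr(sum r x F_constraint)

  for (iter = 0; iter < maxit && !converged; ++iter) {
    double worst = 0.0;
    for (int w = 0; w < nw; ++w) {
      const int idx[3] = { waters(w, 0), waters(w, 1), waters(w, 2) };
      const int ca[3] = { idx[0], idx[0], idx[1] };
      const int cb[3] = { idx[1], idx[2], idx[2] };
      const double dref[3] = { dOH, dOH, dHH };
      for (int c = 0; c < 3; ++c) {
        const int a = ca[c], b = cb[c];
        double d[3], d0[3];
        for (int x = 0; x < 3; ++x) d[x] = p(b, x) - p(a, x);
        d[0] = mimg(d[0], Lx); d[1] = mimg(d[1], Ly); d[2] = mimg(d[2], Lz);
        for (int x = 0; x < 3; ++x) d0[x] = pos_old(b, x) - pos_old(a, x);
        d0[0] = mimg(d0[0], Lx); d0[1] = mimg(d0[1], Ly); d0[2] = mimg(d0[2], Lz);
        const double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
        const double diff = r2 - dref[c] * dref[c];
        worst = std::max(worst, std::fabs(std::sqrt(r2) - dref[c]));
        const double dot = d[0]*d0[0]+d[1]*d0[1]+d[2]*d0[2];
        const double inv = 1.0 / mass[a] + 1.0 / mass[b];
        const double g = diff / (2.0 * inv * dot);
        for (int x = 0; x < 3; ++x) {
          const double corr = g * d0[x];
          p(a, x) += corr / mass[a];
          p(b, x) -= corr / mass[b];
          if (dt > 0.0) {
            v(a, x) += corr / mass[a] / dt;
            v(b, x) -= corr / mass[b] / dt;
          }
        }
        // equivalent constraint force on a is 2 g d0 / (dt^2 acc); its pair
        // virial is f_a . (r_a - r_b) = -(2 g / (dt^2 acc)) (d0 . d)
        if (dt > 0.0)
          Wc += -2.0 * g * dot / (dt * dt * acc_conv);
      }
    }
    if (worst < tol) { converged = true; break; }
  }
  return List::create(_["pos"] = p, _["vel"] = v,
                      _["iterations"] = iter + 1, _["converged"] = converged,
                      _["virial"] = Wc);
}

// RATTLE velocity stage: project relative velocities along constrained bonds.
// [[Rcpp::export]]
List cg_rattle_vel(NumericMatrix pos, NumericMatrix vel, IntegerMatrix waters,
                   NumericVector mass, NumericVector box,
                   double tol, int maxit) {
  NumericMatrix v = clone(vel);
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const int nw = waters.nrow();
  bool converged = (nw == 0);
  int iter = 0;
  for (iter = 0; iter < maxit && !converged; ++iter) {
    double worst = 0.0;
    for (int w = 0; w < nw; ++w) {
      const int idx[3] = { waters(w, 0), waters(w, 1), waters(w, 2) };
      const int ca[3] = { idx[0], idx[0], idx[1] };
      const int cb[3] = { idx[1], idx[2], idx[2] };
      for (int c = 0; c < 3; ++c) {
        const int a = ca[c], b = cb[c];
        double d[3], dv[3];
        for (int x = 0; x < 3; ++x) d[x] = pos(b, x) - pos(a, x);
        d[0] = mimg(d[0], Lx); d[1] = mimg(d[1], Ly); d[2] = mimg(d[2], Lz);
        for (int x = 0; x < 3; ++x) dv[x] = v(b, x) - v(a, x);
        const double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
        const double dot = dv[0]*d[0]+dv[1]*d[1]+dv[2]*d[2];
        worst = std::max(worst, std::fabs(dot) / std::sqrt(r2));
        const double inv = 1.0 / mass[a] + 1.0 / mass[b];
        const double g = dot / (inv * r2);
        for (int x = 0; x < 3; ++x) {
          v(a, x) += g * d[x] / mass[a];
          v(b, x) -= g * d[x] / mass[b];
        }
      }
    }
    if (worst < tol) { converged = true; break; }
  }
  return List::create(_["vel"] = v, _["iterations"] = iter + 1,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Minimum site-site distance under PBC via a cell list (audit helper).
// [[Rcpp::export]]
double cg_min_distance(NumericMatrix pos, NumericVector box) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  if (n < 2) return R_PosInf;
  // target cell size ~3 A, at least 3 cells a side for correctness
  int nx = std::max(1, (int)(Lx / 3.0));
  int ny = std::max(1, (int)(Ly / 3.0));
  int nz = std::max(1, (int)(Lz / 3.0));
  if (nx < 3 || ny < 3 || nz < 3 || (double)n < 500.0) {
    double best = R_PosInf;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = mimg(pos(j,0)-pos(i,0), Lx);
        double dy = mimg(pos(j,1)-pos(i,1), Ly);
        double dz = mimg(pos(j,2)-pos(i,2), Lz);
        best = std::min(best, dx*dx+dy*dy+dz*dz);
      }
    return std::sqrt(best);
  }
  std::vector<std::vector<int>> cells((size_t)nx * ny * nz);
  auto wrap = [](double x, double L) { return x - L * std::floor(x / L); };
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = std::min(nx - 1, (int)(wrap(pos(i,0), Lx) / Lx * nx));
    cy[i] = std::min(ny - 1, (int)(wrap(pos(i,1), Ly) / Ly * ny));
    cz[i] = std::min(nz - 1, (int)(wrap(pos(i,2), Lz) / Lz * nz));
    cells[(size_t)(cx[i] * ny + cy[i]) * nz + cz[i]].push_back(i);
  }
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int ddx = -1; ddx <= 1; ++ddx)
      for (int ddy = -1; ddy <= 1; ++ddy)
        for (int ddz = -1; ddz <= 1; ++ddz) {
          int ux = (cx[i] + ddx + nx) % nx;
          int uy = (cy[i] + ddy + ny) % ny;
          int uz = (cz[i] + ddz + nz) % nz;
          for (int j : cells[(size_t)(ux * ny + uy) * nz + uz]) {
            if (j <= i) continue;
            double dx = mimg(pos(j,0)-pos(i,0), Lx);
            double dy = mimg(pos(j,1)-pos(i,1), Ly);
            double dz = mimg(pos(j,2)-pos(i,2), Lz);
            best = std::min(best, dx*dx+dy*dy+dz*dz);
          }
        }
  }
  return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// Pair distances between two site selections within rmax (RDF helper).
// sel_a / sel_b are 0-based site indices; if same_set, unordered pairs are
// counted once.
// [[Rcpp::export]]
NumericVector cg_pair_distances(NumericMatrix pos, NumericVector box,
                                IntegerVector sel_a, IntegerVector sel_b,
                                double rmax, bool same_set) {
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double r2max = rmax * rmax;
  std::vector<double> out;
  out.reserve(sel_a.size() * 8);
  for (int ia = 0; ia < sel_a.size(); ++ia) {
    const int i = sel_a[ia];
    const int jb0 = same_set ? ia + 1 : 0;
    for (int jb = jb0; jb < sel_b.size(); ++jb) {
      const int j = sel_b[jb];
      if (i == j) continue;
      double dx = mimg(pos(j,0)-pos(i,0), Lx);
      double dy = mimg(pos(j,1)-pos(i,1), Ly);
      double dz = mimg(pos(j,2)-pos(i,2), Lz);
      const double r2 = dx*dx+dy*dy+dz*dz;
      if (r2 < r2max) out.push_back(std::sqrt(r2));
    }
  }
  return NumericVector(out.begin(), out.end());
}
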