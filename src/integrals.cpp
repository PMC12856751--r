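// Gaussian one- and two-electron integrals over contracted cartesian
// Gaussians (McMurchie-Davidson scheme). Supports arbitrary angular momentum
// in principle; exercised for s and p shells (minimal / split-valence bases).
// Units: Bohr throughout.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

// Boys function F_m(T) for m = 0..mmax, downward recursion.
// Series for small/moderate T, asymptotic for large T.
void boys(int mmax, double T, std::vector<double>& F) {
  F.assign(mmax + 1, 0.0);
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / T);
    for (int m = 1; m <= mmax; ++m)
      F[m] = F[m - 1] * (2.0 * m - 1.0) / (2.0 * T);
    return;
  }
  // series for F_mmax, then downward
  double s = 1.0 / (2.0 * mmax + 1.0), term = s;
  for (int k = 1; k < 200; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    s += term;
    if (term < 1e-17 * s) break;
  }
  double eT = std::exp(-T);
  F[mmax] = s * eT;
  for (int m = mmax - 1; m >= 0; --m)
    F[m] = (2.0 * T * F[m + 1] + eT) / (2.0 * m + 1.0);
}

// Hermite expansion coefficient E_t^{ij} (one dimension).
double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (j == 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b)
         - (q * Qx / a)      * Ecoef(i - 1, j, t,     Qx, a, b)
         + (t + 1.0)         * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b)
       + (q * Qx / b)      * Ecoef(i, j - 1, t,     Qx, a, b)
       + (t + 1.0)         * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// Hermite Coulomb integral R^0_{tuv}
double Rtuv(int t, int u, int v, int n, double p, double PCx, double PCy,
            double PCz, const std::vector<double>& F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    double fac = std::pow(-2.0 * p, n);
    return fac * val;
  }
  if (t > 0)
    return (t - 1.0) * Rtuv(t - 2, u, v, n + 1, p, PCx, PCy, PCz, F)
         + PCx * Rtuv(t - 1, u, v, n + 1, p, PCx, PCy, PCz, F);
  if (u > 0)
    return (u - 1.0) * Rtuv(t, u - 2, v, n + 1, p, PCx, PCy, PCz, F)
         + PCy * Rtuv(t, u - 1, v, n + 1, p, PCx, PCy, PCz, F);
  return (v - 1.0) * Rtuv(t, u, v - 2, n + 1, p, PCx, PCy, PCz, F)
       + PCz * Rtuv(t, u, v - 1, n + 1, p, PCx, PCy, PCz, F);
}

struct Prim { double a, c; };          // exponent, (normalized) coefficient
struct BF {                            // one contracted cartesian function
  double x, y, z;
  int lx, ly, lz;
  std::vector<Prim> prims;
};

double prim_norm(double a, int lx, int ly, int lz) {
  auto dfact = [](int n) { double r = 1; for (int k = n; k > 1; k -= 2) r *= k; return r; };
  int L = lx + ly + lz;
  double num = std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * L);
  double den = std::sqrt(dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1));
  return num / den;
}

// primitive overlap (unnormalized coefficients applied outside)
double Sprim(double a, const double* A, int la[3], double b, const double* B,
             int lb[3]) {
  double p = a + b;
  double s = std::pow(PI / p, 1.5);
  for (int d = 0; d < 3; ++d)
    s *= Ecoef(la[d], lb[d], 0, A[d] - B[d], a, b);
  return s;
}

double Tprim(double a, const double* A, int la[3], double b, const double* B,
             int lb[3]) {
  int l2 = lb[0], m2 = lb[1], n2 = lb[2];
  double term0 = b * (2.0 * (l2 + m2 + n2) + 3.0) * Sprim(a, A, la, b, B, lb);
  double term1 = 0.0, term2 = 0.0;
  int lb2[3];
  for (int d = 0; d < 3; ++d) {
    lb2[0] = lb[0]; lb2[1] = lb[1]; lb2[2] = lb[2];
    lb2[d] += 2;
    term1 += Sprim(a, A, la, b, B, lb2);
  }
  term1 *= -2.0 * b * b;
  for (int d = 0; d < 3; ++d) {
    if (lb[d] >= 2) {
      lb2[0] = lb[0]; lb2[1] = lb[1]; lb2[2] = lb[2];
      lb2[d] -= 2;
      term2 += lb[d] * (lb[d] - 1.0) * Sprim(a, A, la, b, B, lb2);
    }
  }
  term2 *= -0.5;
  return term0 + term1 + term2;
}

double Vprim(double a, const double* A, int la[3], double b, const double* B,
             int lb[3], const double* C) {
  double p = a + b;
  double P[3];
  for (int d = 0; d < 3; ++d) P[d] = (a * A[d] + b * B[d]) / p;
  double PC[3] = {P[0] - C[0], P[1] - C[1], P[2] - C[2]};
  double T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  int Lt = la[0] + lb[0], Lu = la[1] + lb[1], Lv = la[2] + lb[2];
  std::vector<double> F;
  boys(Lt + Lu + Lv, T, F);
  double val = 0.0;
  for (int t = 0; t <= Lt; ++t) {
    double Et = Ecoef(la[0], lb[0], t, A[0] - B[0], a, b);
    if (Et == 0.0) continue;
    for (int u = 0; u <= Lu; ++u) {
      double Eu = Ecoef(la[1], lb[1], u, A[1] - B[1], a, b);
      if (Eu == 0.0) continue;
      for (int v = 0; v <= Lv; ++v) {
        double Ev = Ecoef(la[2], lb[2], v, A[2] - B[2], a, b);
        if (Ev == 0.0) continue;
        val += Et * Eu * Ev * Rtuv(t, u, v, 0, p, PC[0], PC[1], PC[2], F);
      }
    }
  }
  return val * 2.0 * PI / p;
}

std::vector<BF> build_bfs(List shells) {
  std::vector<BF> bfs;
  int ns = shells.size();
  for (int s = 0; s < ns; ++s) {
    List sh = shells[s];
    NumericVector ctr = sh["center"];
    int l = as<int>(sh["l"]);
    NumericVector ex = sh["exponents"], co = sh["coefficients"];
    // cartesian components in canonical order (x first)
    std::vector<std::array<int, 3>> comps;
    for (int lx = l; lx >= 0; --lx)
      for (int ly = l - lx; ly >= 0; --ly)
        comps.push_back({lx, ly, l - lx - ly});
    for (auto& cmp : comps) {
      BF f;
      f.x = ctr[0]; f.y = ctr[1]; f.z = ctr[2];
      f.lx = cmp[0]; f.ly = cmp[1]; f.lz = cmp[2];
      for (int k = 0; k < ex.size(); ++k) {
        Prim p;
        p.a = ex[k];
        p.c = co[k] * prim_norm(ex[k], f.lx, f.ly, f.lz);
        f.prims.push_back(p);
      }
      // normalize the contraction
      double A[3] = {f.x, f.y, f.z};
      int la[3] = {f.lx, f.ly, f.lz};
      double ss = 0.0;
      for (auto& pi : f.prims)
        for (auto& pj : f.prims)
          ss += pi.c * pj.c * Sprim(pi.a, A, la, pj.a, A, la);
      double scal = 1.0 / std::sqrt(ss);
      for (auto& pi : f.prims) pi.c *= scal;
      bfs.push_back(f);
    }
  }
  return bfs;
}

} // namespace

// [[Rcpp::export(name = ".int1e_cpp")]]
List int1e_cpp(List shells, NumericMatrix atom_xyz, NumericVector atom_Z,
               NumericMatrix charge_xyz, NumericVector charge_q) {
  std::vector<BF> bfs = build_bfs(shells);
  int n = bfs.size();
  NumericMatrix S(n, n), T(n, n), V(n, n), Dx(n, n), Dy(n, n), Dz(n, n);
  for (int i = 0; i < n; ++i) {
    double A[3] = {bfs[i].x, bfs[i].y, bfs[i].z};
    int la[3] = {bfs[i].lx, bfs[i].ly, bfs[i].lz};
    for (int j = 0; j <= i; ++j) {
      double B[3] = {bfs[j].x, bfs[j].y, bfs[j].z};
      int lb[3] = {bfs[j].lx, bfs[j].ly, bfs[j].lz};
      double s = 0, t = 0, v = 0, dx = 0, dy = 0, dz = 0;
      for (auto& pi : bfs[i].prims)
        for (auto& pj : bfs[j].prims) {
          double cc = pi.c * pj.c;
          s += cc * Sprim(pi.a, A, la, pj.a, B, lb);
          t += cc * Tprim(pi.a, A, la, pj.a, B, lb);
          double p = pi.a + pj.a;
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (pi.a * A[d] + pj.a * B[d]) / p;
          double pref = std::pow(PI / p, 1.5);
          // dipole about the origin: <x> etc.
          double E0[3], E1[3];
          for (int d = 0; d < 3; ++d) {
            E0[d] = Ecoef(la[d], lb[d], 0, A[d] - B[d], pi.a, pj.a);
            E1[d] = Ecoef(la[d], lb[d], 1, A[d] - B[d], pi.a, pj.a);
          }
          dx += cc * pref * (E1[0] + P[0] * E0[0]) * E0[1] * E0[2];
          dy += cc * pref * E0[0] * (E1[1] + P[1] * E0[1]) * E0[2];
          dz += cc * pref * E0[0] * E0[1] * (E1[2] + P[2] * E0[2]);
          // nuclear attraction (nuclei + external point charges)
          for (int a2 = 0; a2 < atom_xyz.nrow(); ++a2) {
            double C[3] = {atom_xyz(a2, 0), atom_xyz(a2, 1), atom_xyz(a2, 2)};
            v -= cc * atom_Z[a2] * Vprim(pi.a, A, la, pj.a, B, lb, C);
          }
          for (int c2 = 0; c2 < charge_xyz.nrow(); ++c2) {
            double C[3] = {charge_xyz(c2, 0), charge_xyz(c2, 1), charge_xyz(c2, 2)};
            v -= cc * charge_q[c2] * Vprim(pi.a, A, la, pj.a, B, lb, C);
          }
        }
      S(i, j) = S(j, i) = s;
      T(i, j) = T(j, i) = t;
      V(i, j) = V(j, i) = v;
      Dx(i, j) = Dx(j, i) = dx;
      Dy(i, j) = Dy(j, i) = dy;
      Dz(i, j) = Dz(j, i) = dz;
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["dip"] = List::create(Dx, Dy, Dz), _["nbf"] = n);
}

namespace {
double eri_bf(const BF& a, const BF& b, const BF& c, const BF& d) {
  double A[3] = {a.x, a.y, a.z}, B[3] = {b.x, b.y, b.z};
  double C[3] = {c.x, c.y, c.z}, D[3] = {d.x, d.y, d.z};
  int la[3] = {a.lx, a.ly, a.lz}, lb[3] = {b.lx, b.ly, b.lz};
  int lc[3] = {c.lx, c.ly, c.lz}, ld[3] = {d.lx, d.ly, d.lz};
  int L1[3], L2[3];
  for (int dd = 0; dd < 3; ++dd) { L1[dd] = la[dd] + lb[dd]; L2[dd] = lc[dd] + ld[dd]; }
  double val = 0.0;
  std::vector<double> F;
  for (auto& p1 : a.prims) for (auto& p2 : b.prims) {
    double p = p1.a + p2.a;
    double P[3];
    for (int dd = 0; dd < 3; ++dd) P[dd] = (p1.a * A[dd] + p2.a * B[dd]) / p;
    double E1x[3 + 1][3]; // E_t for each dim, t up to L1[dim] (max l sum 2 for sp)
    std::vector<std::vector<double>> Ea(3);
    for (int dd = 0; dd < 3; ++dd) {
      Ea[dd].resize(L1[dd] + 1);
      for (int t = 0; t <= L1[dd]; ++t)
        Ea[dd][t] = Ecoef(la[dd], lb[dd], t, A[dd] - B[dd], p1.a, p2.a);
    }
    (void)E1x;
    for (auto& p3 : c.prims) for (auto& p4 : d.prims) {
      double q = p3.a + p4.a;
      double Q[3];
      for (int dd = 0; dd < 3; ++dd) Q[dd] = (p3.a * C[dd] + p4.a * D[dd]) / q;
      std::vector<std::vector<double>> Eb(3);
      for (int dd = 0; dd < 3; ++dd) {
        Eb[dd].resize(L2[dd] + 1);
        for (int t = 0; t <= L2[dd]; ++t)
          Eb[dd][t] = Ecoef(lc[dd], ld[dd], t, C[dd] - D[dd], p3.a, p4.a);
      }
      double alpha = p * q / (p + q);
      double PQ[3] = {P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]};
      double Tb = alpha * (PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2]);
      int Ltot = L1[0] + L1[1] + L1[2] + L2[0] + L2[1] + L2[2];
      boys(Ltot, Tb, F);
      double sum = 0.0;
      for (int t = 0; t <= L1[0]; ++t) for (int u = 0; u <= L1[1]; ++u)
      for (int v = 0; v <= L1[2]; ++v) {
        double E1 = Ea[0][t] * Ea[1][u] * Ea[2][v];
        if (E1 == 0.0) continue;
        for (int tt = 0; tt <= L2[0]; ++tt) for (int uu = 0; uu <= L2[1]; ++uu)
        for (int vv = 0; vv <= L2[2]; ++vv) {
          double E2 = Eb[0][tt] * Eb[1][uu] * Eb[2][vv];
          if (E2 == 0.0) continue;
          double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
          sum += E1 * E2 * sgn *
                 Rtuv(t + tt, u + uu, v + vv, 0, alpha, PQ[0], PQ[1], PQ[2], F);
        }
      }
      double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
      val += p1.c * p2.c * p3.c * p4.c * pref * sum;
    }
  }
  return val;
}
} // namespace

// [[Rcpp::export(name = ".int2e_cpp")]]
NumericVector int2e_cpp(List shells) {
  std::vector<BF> bfs = build_bfs(shells);
  int n = bfs.size();
  NumericVector out((double)n * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  auto idx = [n](int i, int j, int k, int l) {
    return ((double)i) + n * (j + (double)n * (k + (double)n * l));
  };
  for (int i = 0; i < n; ++i)
  for (int j = 0; j <= i; ++j) {
    for (int k = 0; k <= i; ++k)
    for (int l = 0; l <= (k == i ? j : k); ++l) {
      double g = eri_bf(bfs[i], bfs[j], bfs[k], bfs[l]);
      // chemist notation (ij|kl), 8-fold symmetry
      double v = g;
      out[idx(i, j, k, l)] = v; out[idx(j, i, k, l)] = v;
      out[idx(i, j, l, k)] = v; out[idx(j, i, l, k)] = v;
      out[idx(k, l, i, j)] = v; out[idx(l, k, i, j)] = v;
      out[idx(k, l, j, i)] = v; out[idx(l, k, j, i)] = v;
    }
  }
  return out;
}
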