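// Gaussian integral engine: McMurchie-Davidson scheme over contracted
// Cartesian shells with l <= 1 (s and p).  All quantities in atomic units.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int TMAX = 10;   // Hermite order bound (l<=1 everywhere)
static const int IJMAX = 6;   // angular momentum index bound (l+2 for kinetic)

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(double T, int mmax, double *F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T > 30.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T) * std::erf(std::sqrt(T));
    double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  // series for F_mmax, then downward recursion (stable)
  double sum = 1.0 / (2.0 * mmax + 1.0);
  double term = sum;
  for (int k = 1; k < 500; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  double eT = std::exp(-T);
  F[mmax] = eT * sum;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// ------------------------------------------------- Hermite expansion E_t^{ij}
// E[i][j][t] for one Cartesian direction.
static void efill(int imax, int jmax, double a, double b, double AB,
                  double E[IJMAX][IJMAX][TMAX]) {
  double p = a + b, mu = a * b / p;
  double PA = -b * AB / p, PB = a * AB / p;  // AB = Ax - Bx
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j)
      for (int t = 0; t < TMAX; ++t) E[i][j][t] = 0.0;
  E[0][0][0] = std::exp(-mu * AB * AB);
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double v = 0.0;
      if (t > 0) v += E[i - 1][0][t - 1] / (2.0 * p);
      v += PA * E[i - 1][0][t];
      if (t + 1 <= i - 1) v += (t + 1.0) * E[i - 1][0][t + 1];
      E[i][0][t] = v;
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double v = 0.0;
        if (t > 0) v += E[i][j - 1][t - 1] / (2.0 * p);
        v += PB * E[i][j - 1][t];
        if (t + 1 <= i + j - 1) v += (t + 1.0) * E[i][j - 1][t + 1];
        E[i][j][t] = v;
      }
}

// ------------------------------------------ Hermite Coulomb integrals R_{tuv}
static void hermite_R(int tmax, int umax, int vmax, double alpha,
                      double X, double Y, double Z,
                      double R0[TMAX][TMAX][TMAX]) {
  int ntot = tmax + umax + vmax;
  double R2 = X * X + Y * Y + Z * Z;
  double F[3 * TMAX + 2];
  boys(alpha * R2, ntot, F);
  // Rn[n][t][u][v] built by recursion; keep full box per auxiliary level
  static double Rn[3 * TMAX + 1][TMAX][TMAX][TMAX];
  for (int n = 0; n <= ntot; ++n) {
    double f = std::pow(-2.0 * alpha, n) * F[n];
    Rn[n][0][0][0] = f;
  }
  for (int n = ntot - 1; n >= 0; --n) {
    for (int t = 0; t <= tmax; ++t)
      for (int u = 0; u <= umax; ++u)
        for (int v = 0; v <= vmax; ++v) {
          if (t + u + v == 0 || t + u + v > ntot - n) continue;
          double val;
          if (t > 0) {
            val = X * Rn[n + 1][t - 1][u][v];
            if (t > 1) val += (t - 1.0) * Rn[n + 1][t - 2][u][v];
          } else if (u > 0) {
            val = Y * Rn[n + 1][t][u - 1][v];
            if (u > 1) val += (u - 1.0) * Rn[n + 1][t][u - 2][v];
          } else {
            val = Z * Rn[n + 1][t][u][v - 1];
            if (v > 1) val += (v - 1.0) * Rn[n + 1][t][u][v - 2];
          }
          Rn[n][t][u][v] = val;
        }
  }
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v = 0; v <= vmax; ++v) R0[t][u][v] = Rn[0][t][u][v];
}

// cartesian components for shell of angular momentum l (s, p supported)
static int ncart(int l) { return (l + 1) * (l + 2) / 2; }
static void cart_comps(int l, int comp, int *lx, int *ly, int *lz) {
  if (l == 0) { *lx = *ly = *lz = 0; return; }
  if (l == 1) {
    *lx = (comp == 0); *ly = (comp == 1); *lz = (comp == 2);
    return;
  }
  stop("only s and p shells are supported");
}

struct ShellSet {
  std::vector<int> l, pstart, pn;
  std::vector<double> cx, cy, cz, pexp, pcoef;
  std::vector<int> ao_off;
  int nao;
};

static ShellSet unpack(List shells) {
  ShellSet s;
  s.l = as<std::vector<int> >(shells["l"]);
  s.pstart = as<std::vector<int> >(shells["pstart"]);
  s.pn = as<std::vector<int> >(shells["pn"]);
  s.cx = as<std::vector<double> >(shells["cx"]);
  s.cy = as<std::vector<double> >(shells["cy"]);
  s.cz = as<std::vector<double> >(shells["cz"]);
  s.pexp = as<std::vector<double> >(shells["pexp"]);
  s.pcoef = as<std::vector<double> >(shells["pcoef"]);
  int off = 0;
  for (size_t i = 0; i < s.l.size(); ++i) {
    if (s.l[i] > 1) stop("only s and p shells are supported");
    s.ao_off.push_back(off);
    off += ncart(s.l[i]);
  }
  s.nao = off;
  return s;
}

// 1D overlap table S1(i,j) = E_0^{ij} for one primitive pair and direction
struct Pair1D { double E[IJMAX][IJMAX][TMAX]; };

// ------------------------------------------------------------ one-electron
// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericMatrix nuc_xyz, NumericVector nuc_q) {
  ShellSet S = unpack(shells);
  int n = S.nao;
  NumericMatrix Smat(n, n), Tmat(n, n), Vmat(n, n);
  int nnuc = nuc_xyz.nrow();
  double Ex[IJMAX][IJMAX][TMAX], Ey[IJMAX][IJMAX][TMAX], Ez[IJMAX][IJMAX][TMAX];
  double R0[TMAX][TMAX][TMAX];

  int nsh = S.l.size();
  for (int A = 0; A < nsh; ++A)
    for (int B = A; B < nsh; ++B) {
      int la = S.l[A], lb = S.l[B];
      int nca = ncart(la), ncb = ncart(lb);
      double ABx = S.cx[A] - S.cx[B], ABy = S.cy[A] - S.cy[B], ABz = S.cz[A] - S.cz[B];
      std::vector<double> sblk(nca * ncb, 0.0), tblk(nca * ncb, 0.0), vblk(nca * ncb, 0.0);
      for (int ia = 0; ia < S.pn[A]; ++ia)
        for (int ib = 0; ib < S.pn[B]; ++ib) {
          double a = S.pexp[S.pstart[A] + ia], b = S.pexp[S.pstart[B] + ib];
          double ca = S.pcoef[S.pstart[A] + ia], cb = S.pcoef[S.pstart[B] + ib];
          double p = a + b;
          double mu = a * b / p;
          double r2 = ABx * ABx + ABy * ABy + ABz * ABz;
          if (mu * r2 > 46.0) continue;  // exp(-46) ~ 1e-20
          double cc = ca * cb;
          efill(la + 2, lb + 2, a, b, ABx, Ex);
          efill(la + 2, lb + 2, a, b, ABy, Ey);
          efill(la + 2, lb + 2, a, b, ABz, Ez);
          double Px = (a * S.cx[A] + b * S.cx[B]) / p;
          double Py = (a * S.cy[A] + b * S.cy[B]) / p;
          double Pz = (a * S.cz[A] + b * S.cz[B]) / p;
          double pref = std::pow(M_PI / p, 1.5);
          for (int ca_i = 0; ca_i < nca; ++ca_i) {
            int ax, ay, az; cart_comps(la, ca_i, &ax, &ay, &az);
            for (int cb_i = 0; cb_i < ncb; ++cb_i) {
              int bx, by, bz; cart_comps(lb, cb_i, &bx, &by, &bz);
              double sx = Ex[ax][bx][0], sy = Ey[ay][by][0], sz = Ez[az][bz][0];
              // overlap
              sblk[ca_i + nca * cb_i] += cc * pref * sx * sy * sz;
              // kinetic: 1D kinetic integral built from shifted overlaps
              double tx = -2.0 * b * b * Ex[ax][bx + 2][0]
                          + b * (2.0 * bx + 1.0) * Ex[ax][bx][0]
                          - 0.5 * bx * (bx - 1.0) * (bx >= 2 ? Ex[ax][bx - 2][0] : 0.0);
              double ty = -2.0 * b * b * Ey[ay][by + 2][0]
                          + b * (2.0 * by + 1.0) * Ey[ay][by][0]
                          - 0.5 * by * (by - 1.0) * (by >= 2 ? Ey[ay][by - 2][0] : 0.0);
              double tz = -2.0 * b * b * Ez[az][bz + 2][0]
                          + b * (2.0 * bz + 1.0) * Ez[az][bz][0]
                          - 0.5 * bz * (bz - 1.0) * (bz >= 2 ? Ez[az][bz - 2][0] : 0.0);
              tblk[ca_i + nca * cb_i] +=
                cc * pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              // nuclear attraction (returned as +sum_A Z_A <mu|1/r_A|nu>)
              double vsum = 0.0;
              for (int q = 0; q < nnuc; ++q) {
                hermite_R(ax + bx, ay + by, az + bz, p,
                          Px - nuc_xyz(q, 0), Py - nuc_xyz(q, 1), Pz - nuc_xyz(q, 2), R0);
                double acc = 0.0;
                for (int t = 0; t <= ax + bx; ++t)
                  for (int u = 0; u <= ay + by; ++u)
                    for (int v = 0; v <= az + bz; ++v)
                      acc += Ex[ax][bx][t] * Ey[ay][by][u] * Ez[az][bz][v] * R0[t][u][v];
                vsum += nuc_q[q] * acc;
              }
              vblk[ca_i + nca * cb_i] += cc * (2.0 * M_PI / p) * vsum;
            }
          }
        }
      for (int ca_i = 0; ca_i < nca; ++ca_i)
        for (int cb_i = 0; cb_i < ncb; ++cb_i) {
          int mu_i = S.ao_off[A] + ca_i, nu_i = S.ao_off[B] + cb_i;
          Smat(mu_i, nu_i) = Smat(nu_i, mu_i) = sblk[ca_i + nca * cb_i];
          Tmat(mu_i, nu_i) = Tmat(nu_i, mu_i) = tblk[ca_i + nca * cb_i];
          Vmat(mu_i, nu_i) = Vmat(nu_i, mu_i) = vblk[ca_i + nca * cb_i];
        }
    }
  return List::create(_["S"] = Smat, _["T"] = Tmat, _["V"] = Vmat);
}

// overlap between two different shell sets (for IAO reference bases)
// [[Rcpp::export]]
NumericMatrix cpp_overlap_cross(List shells1, List shells2) {
  ShellSet S1 = unpack(shells1), S2 = unpack(shells2);
  NumericMatrix Smat(S1.nao, S2.nao);
  double Ex[IJMAX][IJMAX][TMAX], Ey[IJMAX][IJMAX][TMAX], Ez[IJMAX][IJMAX][TMAX];
  for (size_t A = 0; A < S1.l.size(); ++A)
    for (size_t B = 0; B < S2.l.size(); ++B) {
      int la = S1.l[A], lb = S2.l[B];
      int nca = ncart(la), ncb = ncart(lb);
      double ABx = S1.cx[A] - S2.cx[B], ABy = S1.cy[A] - S2.cy[B], ABz = S1.cz[A] - S2.cz[B];
      for (int ia = 0; ia < S1.pn[A]; ++ia)
        for (int ib = 0; ib < S2.pn[B]; ++ib) {
          double a = S1.pexp[S1.pstart[A] + ia], b = S2.pexp[S2.pstart[B] + ib];
          double cc = S1.pcoef[S1.pstart[A] + ia] * S2.pcoef[S2.pstart[B] + ib];
          double p = a + b;
          efill(la, lb, a, b, ABx, Ex);
          efill(la, lb, a, b, ABy, Ey);
          efill(la, lb, a, b, ABz, Ez);
          double pref = std::pow(M_PI / p, 1.5);
          for (int ca_i = 0; ca_i < nca; ++ca_i) {
            int ax, ay, az; cart_comps(la, ca_i, &ax, &ay, &az);
            for (int cb_i = 0; cb_i < ncb; ++cb_i) {
              int bx, by, bz; cart_comps(lb, cb_i, &bx, &by, &bz);
              Smat(S1.ao_off[A] + ca_i, S2.ao_off[B] + cb_i) +=
                cc * pref * Ex[ax][bx][0] * Ey[ay][by][0] * Ez[az][bz][0];
            }
          }
        }
    }
  return Smat;
}

// electrostatic integrals of external point charges:
// returns sum_q q_k <mu| 1/|r - R_k| |nu>   (positive-kernel convention)
// [[Rcpp::export]]
NumericMatrix cpp_point_charge_ints(List shells, NumericMatrix chg_xyz,
                                    NumericVector chg_q) {
  List oe = cpp_one_electron(shells, chg_xyz, chg_q);
  return as<NumericMatrix>(oe["V"]);
}

// dipole moment integrals <mu| r - O |nu>
// [[Rcpp::export]]
List cpp_dipole(List shells, NumericVector origin) {
  ShellSet S = unpack(shells);
  int n = S.nao;
  NumericMatrix Dx(n, n), Dy(n, n), Dz(n, n);
  double Ex[IJMAX][IJMAX][TMAX], Ey[IJMAX][IJMAX][TMAX], Ez[IJMAX][IJMAX][TMAX];
  int nsh = S.l.size();
  for (int A = 0; A < nsh; ++A)
    for (int B = A; B < nsh; ++B) {
      int la = S.l[A], lb = S.l[B];
      int nca = ncart(la), ncb = ncart(lb);
      double ABx = S.cx[A] - S.cx[B], ABy = S.cy[A] - S.cy[B], ABz = S.cz[A] - S.cz[B];
      std::vector<double> bx_(nca * ncb, 0.0), by_(nca * ncb, 0.0), bz_(nca * ncb, 0.0);
      for (int ia = 0; ia < S.pn[A]; ++ia)
        for (int ib = 0; ib < S.pn[B]; ++ib) {
          double a = S.pexp[S.pstart[A] + ia], b = S.pexp[S.pstart[B] + ib];
          double cc = S.pcoef[S.pstart[A] + ia] * S.pcoef[S.pstart[B] + ib];
          double p = a + b;
          efill(la, lb + 1, a, b, ABx, Ex);
          efill(la, lb + 1, a, b, ABy, Ey);
          efill(la, lb + 1, a, b, ABz, Ez);
          double pref = std::pow(M_PI / p, 1.5) * cc;
          double BOx = S.cx[B] - origin[0], BOy = S.cy[B] - origin[1],
                 BOz = S.cz[B] - origin[2];
          for (int ca_i = 0; ca_i < nca; ++ca_i) {
            int ax, ay, az; cart_comps(la, ca_i, &ax, &ay, &az);
            for (int cb_i = 0; cb_i < ncb; ++cb_i) {
              int bxc, byc, bzc; cart_comps(lb, cb_i, &bxc, &byc, &bzc);
              double sx = Ex[ax][bxc][0], sy = Ey[ay][byc][0], sz = Ez[az][bzc][0];
              double mx = Ex[ax][bxc + 1][0] + BOx * sx;
              double my = Ey[ay][byc + 1][0] + BOy * sy;
              double mz = Ez[az][bzc + 1][0] + BOz * sz;
              bx_[ca_i + nca * cb_i] += pref * mx * sy * sz;
              by_[ca_i + nca * cb_i] += pref * sx * my * sz;
              bz_[ca_i + nca * cb_i] += pref * sx * sy * mz;
            }
          }
        }
      for (int ca_i = 0; ca_i < nca; ++ca_i)
        for (int cb_i = 0; cb_i < ncb; ++cb_i) {
          int mu_i = S.ao_off[A] + ca_i, nu_i = S.ao_off[B] + cb_i;
          Dx(mu_i, nu_i) = Dx(nu_i, mu_i) = bx_[ca_i + nca * cb_i];
          Dy(mu_i, nu_i) = Dy(nu_i, mu_i) = by_[ca_i + nca * cb_i];
          Dz(mu_i, nu_i) = Dz(nu_i, mu_i) = bz_[ca_i + nca * cb_i];
        }
    }
  return List::create(_["x"] = Dx, _["y"] = Dy, _["z"] = Dz);
}

// ------------------------------------------------------------ two-electron
// full (mu nu | la si) tensor in chemists' notation, column-major n^4 vector
// [[Rcpp::export]]
NumericVector cpp_eri(List shells) {
  ShellSet S = unpack(shells);
  int n = S.nao;
  NumericVector out((R_xlen_t)n * n * n * n);
  double *G = REAL(out);
  double Ex[IJMAX][IJMAX][TMAX], Ey[IJMAX][IJMAX][TMAX], Ez[IJMAX][IJMAX][TMAX];
  double Fx[IJMAX][IJMAX][TMAX], Fy[IJMAX][IJMAX][TMAX], Fz[IJMAX][IJMAX][TMAX];
  double R0[TMAX][TMAX][TMAX];
  int nsh = S.l.size();

  for (int A = 0; A < nsh; ++A)
  for (int B = A; B < nsh; ++B)
  for (int C = 0; C < nsh; ++C)
  for (int D = C; D < nsh; ++D) {
    // canonical quartet ordering: (AB) <= (CD)
    int ab = A * nsh + B, cd = C * nsh + D;
    if (ab > cd) continue;
    int la = S.l[A], lb = S.l[B], lc = S.l[C], ld = S.l[D];
    int nca = ncart(la), ncb = ncart(lb), ncc = ncart(lc), ncd = ncart(ld);
    double ABx = S.cx[A] - S.cx[B], ABy = S.cy[A] - S.cy[B], ABz = S.cz[A] - S.cz[B];
    double CDx = S.cx[C] - S.cx[D], CDy = S.cy[C] - S.cy[D], CDz = S.cz[C] - S.cz[D];
    std::vector<double> blk(nca * ncb * ncc * ncd, 0.0);
    for (int ia = 0; ia < S.pn[A]; ++ia)
    for (int ib = 0; ib < S.pn[B]; ++ib) {
      double a = S.pexp[S.pstart[A] + ia], b = S.pexp[S.pstart[B] + ib];
      double p = a + b;
      double mu_ab = a * b / p;
      if (mu_ab * (ABx * ABx + ABy * ABy + ABz * ABz) > 46.0) continue;
      efill(la, lb, a, b, ABx, Ex);
      efill(la, lb, a, b, ABy, Ey);
      efill(la, lb, a, b, ABz, Ez);
      double Px = (a * S.cx[A] + b * S.cx[B]) / p;
      double Py = (a * S.cy[A] + b * S.cy[B]) / p;
      double Pz = (a * S.cz[A] + b * S.cz[B]) / p;
      double cab = S.pcoef[S.pstart[A] + ia] * S.pcoef[S.pstart[B] + ib];
      for (int ic = 0; ic < S.pn[C]; ++ic)
      for (int id = 0; id < S.pn[D]; ++id) {
        double c = S.pexp[S.pstart[C] + ic], d = S.pexp[S.pstart[D] + id];
        double q = c + d;
        double mu_cd = c * d / q;
        if (mu_cd * (CDx * CDx + CDy * CDy + CDz * CDz) > 46.0) continue;
        efill(lc, ld, c, d, CDx, Fx);
        efill(lc, ld, c, d, CDy, Fy);
        efill(lc, ld, c, d, CDz, Fz);
        double Qx = (c * S.cx[C] + d * S.cx[D]) / q;
        double Qy = (c * S.cy[C] + d * S.cy[D]) / q;
        double Qz = (c * S.cz[C] + d * S.cz[D]) / q;
        double alpha = p * q / (p + q);
        double ccd = S.pcoef[S.pstart[C] + ic] * S.pcoef[S.pstart[D] + id];
        double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
        hermite_R(la + lb + lc + ld, la + lb + lc + ld, la + lb + lc + ld,
                  alpha, Px - Qx, Py - Qy, Pz - Qz, R0);
        int idx = 0;
        for (int dd = 0; dd < ncd; ++dd)
        for (int ccc = 0; ccc < ncc; ++ccc)
        for (int bb = 0; bb < ncb; ++bb)
        for (int aa = 0; aa < nca; ++aa) {
          int axc, ayc, azc, bxc, byc, bzc, cxc, cyc, czc, dxc, dyc, dzc;
          cart_comps(la, aa, &axc, &ayc, &azc);
          cart_comps(lb, bb, &bxc, &byc, &bzc);
          cart_comps(lc, ccc, &cxc, &cyc, &czc);
          cart_comps(ld, dd, &dxc, &dyc, &dzc);
          double acc = 0.0;
          for (int t = 0; t <= axc + bxc; ++t)
          for (int u = 0; u <= ayc + byc; ++u)
          for (int v = 0; v <= azc + bzc; ++v) {
            double eb = Ex[axc][bxc][t] * Ey[ayc][byc][u] * Ez[azc][bzc][v];
            if (eb == 0.0) continue;
            for (int tt = 0; tt <= cxc + dxc; ++tt)
            for (int uu = 0; uu <= cyc + dyc; ++uu)
            for (int vv = 0; vv <= czc + dzc; ++vv) {
              double ek = Fx[cxc][dxc][tt] * Fy[cyc][dyc][uu] * Fz[czc][dzc][vv];
              if (ek == 0.0) continue;
              double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
              acc += eb * ek * sgn * R0[t + tt][u + uu][v + vv];
            }
          }
          blk[idx++] += cab * ccd * pref * acc;
        }
      }
    }
    // scatter with 8-fold permutational symmetry
    for (int dd = 0; dd < ncd; ++dd)
    for (int ccc = 0; ccc < ncc; ++ccc)
    for (int bb = 0; bb < ncb; ++bb)
    for (int aa = 0; aa < nca; ++aa) {
      double val = blk[aa + nca * (bb + ncb * (ccc + ncc * dd))];
      R_xlen_t i = S.ao_off[A] + aa, j = S.ao_off[B] + bb,
               k = S.ao_off[C] + ccc, l = S.ao_off[D] + dd;
      R_xlen_t nn = n;
      R_xlen_t perms[8][4] = {
        {i, j, k, l}, {j, i, k, l}, {i, j, l, k}, {j, i, l, k},
        {k, l, i, j}, {l, k, i, j}, {k, l, j, i}, {l, k, j, i}};
      for (int pgi = 0; pgi < 8; ++pgi) {
        R_xlen_t off = perms[pgi][0] + nn * (perms[pgi][1] +
                        nn * (perms[pgi][2] + nn * perms[pgi][3]));
        G[off] = val;
      }
    }
  }
  return out;
}

// ------------------------------------------------- AO values on grid points
// returns list of npts x nao matrices: values and x/y/z derivatives
// [[Rcpp::export]]
List cpp_ao_eval(List shells, NumericMatrix pts) {
  ShellSet S = unpack(shells);
  int n = S.nao, npts = pts.nrow();
  NumericMatrix ao(npts, n), aox(npts, n), aoy(npts, n), aoz(npts, n);
  int nsh = S.l.size();
  for (int A = 0; A < nsh; ++A) {
    int la = S.l[A];
    for (int ptn = 0; ptn < npts; ++ptn) {
      double x = pts(ptn, 0) - S.cx[A], y = pts(ptn, 1) - S.cy[A],
             z = pts(ptn, 2) - S.cz[A];
      double r2 = x * x + y * y + z * z;
      double rad = 0.0, radp = 0.0;  // R(r) and R'(r)/r-type factor
      for (int ip = 0; ip < S.pn[A]; ++ip) {
        double aexp = S.pexp[S.pstart[A] + ip];
        double e = aexp * r2 > 46.0 ? 0.0 : std::exp(-aexp * r2);
        double ce = S.pcoef[S.pstart[A] + ip] * e;
        rad += ce;
        radp += -2.0 * aexp * ce;
      }
      if (la == 0) {
        ao(ptn, S.ao_off[A]) = rad;
        aox(ptn, S.ao_off[A]) = x * radp;
        aoy(ptn, S.ao_off[A]) = y * radp;
        aoz(ptn, S.ao_off[A]) = z * radp;
      } else {
        int o = S.ao_off[A];
        ao(ptn, o) = x * rad;  ao(ptn, o + 1) = y * rad;  ao(ptn, o + 2) = z * rad;
        aox(ptn, o) = rad + x * x * radp;
        aoy(ptn, o) = x * y * radp;
        aoz(ptn, o) = x * z * radp;
        aox(ptn, o + 1) = y * x * radp;
        aoy(ptn, o + 1) = rad + y * y * radp;
        aoz(ptn, o + 1) = y * z * radp;
        aox(ptn, o + 2) = z * x * radp;
        aoy(ptn, o + 2) = z * y * radp;
        aoz(ptn, o + 2) = rad + z * z * radp;
      }
    }
  }
  return List::create(_["ao"] = ao, _["x"] = aox, _["y"] = aoy, _["z"] = aoz);
}
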