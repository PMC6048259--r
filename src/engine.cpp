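// Langevin (BAOAB) dynamics engine for coarse-grained bead systems, with
// optional Gaussian-accelerated boosting of the total potential and
// adaptive-bias (flooding) sampling along one or two collective variables.
//
// Units: kcal/mol, Angstrom, amu, fs, Kelvin. Harmonic terms use the
// 0.5*k*(x-x0)^2 convention. All randomness comes from R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 1.9872e-3;       // kcal/(mol K)
static const double ACC = 4.184e-4;       // (kcal/mol/A/amu) -> A/fs^2
static const double RAD2DEG = 57.29577951308232;

struct System {
  int n;
  std::vector<double> mass;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  // nonbonded pair list (pre-excluded)
  std::vector<int> pi, pj;
  std::vector<double> peps, psig, pqq;
  double screen;
  // positional restraints
  std::vector<int> ri;
  std::vector<double> rk, rx, ry, rz;
  // externals: each row: type, bead, p1..p7
  NumericMatrix ext;
  std::vector<bool> frozen;
};

static System unpack(const List& pack) {
  System s;
  s.n = as<int>(pack["n"]);
  s.mass = as<std::vector<double>>(pack["mass"]);
  IntegerVector bi = pack["bond_i"], bj = pack["bond_j"];
  s.bi.assign(bi.begin(), bi.end());
  s.bj.assign(bj.begin(), bj.end());
  s.bk = as<std::vector<double>>(pack["bond_k"]);
  s.br0 = as<std::vector<double>>(pack["bond_r0"]);
  IntegerVector pi = pack["pair_i"], pj = pack["pair_j"];
  s.pi.assign(pi.begin(), pi.end());
  s.pj.assign(pj.begin(), pj.end());
  s.peps = as<std::vector<double>>(pack["pair_eps"]);
  s.psig = as<std::vector<double>>(pack["pair_sig"]);
  s.pqq = as<std::vector<double>>(pack["pair_qq"]);
  s.screen = as<double>(pack["screen"]);
  IntegerVector ri = pack["restr_bead"];
  s.ri.assign(ri.begin(), ri.end());
  s.rk = as<std::vector<double>>(pack["restr_k"]);
  s.rx = as<std::vector<double>>(pack["restr_x"]);
  s.ry = as<std::vector<double>>(pack["restr_y"]);
  s.rz = as<std::vector<double>>(pack["restr_z"]);
  s.ext = as<NumericMatrix>(pack["ext"]);
  s.frozen = as<std::vector<bool>>(pack["frozen"]);
  return s;
}

// potential energy and forces; returns energy, fills f (n x 3, flattened
// row-major x1,y1,z1,...)
static double energy_forces(const System& s, const std::vector<double>& x,
                            std::vector<double>& f, double* terms) {
  const int n = s.n;
  std::fill(f.begin(), f.end(), 0.0);
  double eb = 0, evdw = 0, ecoul = 0, er = 0, ee = 0;
  for (size_t b = 0; b < s.bi.size(); ++b) {
    int i = s.bi[b], j = s.bj[b];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-10) stop("singularity: bonded beads %d and %d coincide", i + 1, j + 1);
    double d = r - s.br0[b];
    eb += 0.5 * s.bk[b] * d * d;
    double fmag = -s.bk[b] * d / r;   // dE/dr = k d; force along -grad
    f[3*i]   += fmag * dx; f[3*i+1] += fmag * dy; f[3*i+2] += fmag * dz;
    f[3*j]   -= fmag * dx; f[3*j+1] -= fmag * dy; f[3*j+2] -= fmag * dz;
  }
  for (size_t p = 0; p < s.pi.size(); ++p) {
    int i = s.pi[p], j = s.pj[p];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 < 1e-12) stop("singularity: beads %d and %d overlap at zero distance", i + 1, j + 1);
    double r = std::sqrt(r2);
    double dEdr = 0.0;
    if (s.peps[p] != 0.0) {
      double sr = s.psig[p] / r;
      double sr6 = sr*sr*sr; sr6 *= sr6;
      double sr12 = sr6 * sr6;
      evdw += 4.0 * s.peps[p] * (sr12 - sr6);
      dEdr += 4.0 * s.peps[p] * (-12.0 * sr12 + 6.0 * sr6) / r;
    }
    if (s.pqq[p] != 0.0) {
      double sc = std::exp(-r / s.screen);
      ecoul += s.pqq[p] * sc / r;
      dEdr += -s.pqq[p] * sc * (1.0 / r2 + 1.0 / (s.screen * r));
    }
    double fmag = -dEdr / r;
    f[3*i]   += fmag * dx; f[3*i+1] += fmag * dy; f[3*i+2] += fmag * dz;
    f[3*j]   -= fmag * dx; f[3*j+1] -= fmag * dy; f[3*j+2] -= fmag * dz;
  }
  for (size_t m = 0; m < s.ri.size(); ++m) {
    int i = s.ri[m];
    double dx = x[3*i] - s.rx[m], dy = x[3*i+1] - s.ry[m], dz = x[3*i+2] - s.rz[m];
    er += 0.5 * s.rk[m] * (dx*dx + dy*dy + dz*dz);
    f[3*i]   -= s.rk[m] * dx;
    f[3*i+1] -= s.rk[m] * dy;
    f[3*i+2] -= s.rk[m] * dz;
  }
  for (int e = 0; e < s.ext.nrow(); ++e) {
    int type = (int)s.ext(e, 0), bead = (int)s.ext(e, 1);
    if (type == 1) { // harmonic: kx,ky,kz, cx,cy,cz
      for (int k = 0; k < 3; ++k) {
        double kk = s.ext(e, 2 + k), d = x[3*bead + k] - s.ext(e, 5 + k);
        ee += 0.5 * kk * d * d;
        f[3*bead + k] -= kk * d;
      }
    } else if (type == 2) { // double well on one axis: axis, h, a
      int ax = (int)s.ext(e, 2);
      double h = s.ext(e, 3), a = s.ext(e, 4);
      double u = x[3*bead + ax] / a;
      double q = u*u - 1.0;
      ee += h * q * q;
      f[3*bead + ax] -= h * 4.0 * q * u / a;
    }
  }
  if (terms) { terms[0] = eb; terms[1] = evdw; terms[2] = ecoul; terms[3] = er; terms[4] = ee; }
  return eb + evdw + ecoul + er + ee;
}

// [[Rcpp::export]]
List cpp_energy(List pack, NumericMatrix pos) {
  System s = unpack(pack);
  std::vector<double> x(3 * s.n), f(3 * s.n);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i + k] = pos(i, k);
  double terms[5];
  double e = energy_forces(s, x, f, terms);
  NumericMatrix fo(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) fo(i, k) = f[3*i + k];
  return List::create(_["energy"] = e,
                      _["terms"] = NumericVector::create(
                        _["bond"] = terms[0], _["vdw"] = terms[1],
                        _["coulomb"] = terms[2], _["restraint"] = terms[3],
                        _["external"] = terms[4]),
                      _["forces"] = fo);
}

// ---------------- collective variables ---------------------------------

struct CVDef {
  int kind;                       // 0 distance, 1 angle, 2 torsion
  std::vector<int> T, U, W, X;    // 0-based bead groups
};

static void group_com(const std::vector<double>& x, const std::vector<double>& mass,
                      const std::vector<int>& g, double* c) {
  double M = 0; c[0] = c[1] = c[2] = 0;
  for (int i : g) {
    M += mass[i];
    for (int k = 0; k < 3; ++k) c[k] += mass[i] * x[3*i + k];
  }
  for (int k = 0; k < 3; ++k) c[k] /= M;
}

// evaluate cv and accumulate dcv/dx (in cv units per Angstrom) into grad
static double eval_cv_grad(const CVDef& cv, const std::vector<double>& x,
                           const std::vector<double>& mass,
                           std::vector<double>* grad) {
  auto add_group = [&](const std::vector<int>& g, const double* d) {
    if (!grad) return;
    double M = 0; for (int i : g) M += mass[i];
    for (int i : g)
      for (int k = 0; k < 3; ++k) (*grad)[3*i + k] += mass[i] / M * d[k];
  };
  if (cv.kind == 0) {
    std::vector<int> TU(cv.T), WX(cv.W);
    TU.insert(TU.end(), cv.U.begin(), cv.U.end());
    WX.insert(WX.end(), cv.X.begin(), cv.X.end());
    double p1[3], p2[3];
    group_com(x, mass, TU, p1); group_com(x, mass, WX, p2);
    double d[3] = {p1[0]-p2[0], p1[1]-p2[1], p1[2]-p2[2]};
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r < 1e-9) stop("undefined CV: coincident group centres");
    double g1[3] = {d[0]/r, d[1]/r, d[2]/r};
    double g2[3] = {-g1[0], -g1[1], -g1[2]};
    add_group(TU, g1); add_group(WX, g2);
    return r;
  } else if (cv.kind == 1) {
    // angle T-U-Y (vertex U), Y = CoM(W u X); degrees
    std::vector<int> WX(cv.W);
    WX.insert(WX.end(), cv.X.begin(), cv.X.end());
    double A[3], B[3], C[3];
    group_com(x, mass, cv.T, A); group_com(x, mass, cv.U, B);
    group_com(x, mass, WX, C);
    double u[3], v[3];
    double lu = 0, lv = 0;
    for (int k = 0; k < 3; ++k) { u[k] = A[k]-B[k]; v[k] = C[k]-B[k]; }
    for (int k = 0; k < 3; ++k) { lu += u[k]*u[k]; lv += v[k]*v[k]; }
    lu = std::sqrt(lu); lv = std::sqrt(lv);
    if (lu < 1e-9 || lv < 1e-9) stop("undefined CV: coincident group centres");
    double cth = 0;
    for (int k = 0; k < 3; ++k) cth += (u[k]/lu) * (v[k]/lv);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double sth = std::sqrt(std::max(1e-12, 1.0 - cth*cth));
    double dA[3], dC[3], dB[3];
    for (int k = 0; k < 3; ++k) {
      dA[k] = (cth * u[k]/lu - v[k]/lv) / (lu * sth) * RAD2DEG;
      dC[k] = (cth * v[k]/lv - u[k]/lu) / (lv * sth) * RAD2DEG;
      dB[k] = -dA[k] - dC[k];
    }
    add_group(cv.T, dA); add_group(cv.U, dB); add_group(WX, dC);
    return th * RAD2DEG;
  } else {
    // torsion over centres of T, U, W, X; degrees in (-180, 180]
    double P[4][3];
    group_com(x, mass, cv.T, P[0]); group_com(x, mass, cv.U, P[1]);
    group_com(x, mass, cv.W, P[2]); group_com(x, mass, cv.X, P[3]);
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = P[1][k]-P[0][k]; b2[k] = P[2][k]-P[1][k]; b3[k] = P[3][k]-P[2][k];
    }
    auto cross = [](const double* a, const double* b, double* c) {
      c[0] = a[1]*b[2]-a[2]*b[1]; c[1] = a[2]*b[0]-a[0]*b[2]; c[2] = a[0]*b[1]-a[1]*b[0];
    };
    auto dot = [](const double* a, const double* b) {
      return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
    };
    double n1[3], n2[3];
    cross(b1, b2, n1); cross(b2, b3, n2);
    double ln1 = dot(n1, n1), ln2 = dot(n2, n2), lb2 = std::sqrt(dot(b2, b2));
    if (ln1 < 1e-12 || ln2 < 1e-12 || lb2 < 1e-9)
      stop("undefined CV: degenerate torsion geometry");
    double m1[3];
    cross(n1, b2, m1);
    double xcomp = dot(n1, n2);
    double ycomp = dot(m1, n2) / lb2;
    double phi = std::atan2(ycomp, xcomp); // radians
    double dA[3], dB[3], dC[3], dD[3];
    for (int k = 0; k < 3; ++k) {
      dA[k] = -lb2 / ln1 * n1[k];
      dD[k] =  lb2 / ln2 * n2[k];
    }
    // projection coefficients of the central-bond lever arms; the returned
    // angle is the negative of the convention the classic end-point
    // gradients assume, hence the overall sign below
    double c12 = dot(b1, b2) / (lb2*lb2), c32 = dot(b3, b2) / (lb2*lb2);
    for (int k = 0; k < 3; ++k) {
      dB[k] = (-c12 - 1.0) * dA[k] + c32 * dD[k];
      dC[k] = (-c32 - 1.0) * dD[k] + c12 * dA[k];
    }
    for (int k = 0; k < 3; ++k) {
      dA[k] *= -RAD2DEG; dB[k] *= -RAD2DEG; dC[k] *= -RAD2DEG; dD[k] *= -RAD2DEG;
    }
    add_group(cv.T, dA); add_group(cv.U, dB);
    add_group(cv.W, dC); add_group(cv.X, dD);
    return phi * RAD2DEG; // cis = 0, range (-180, 180]
  }
}

// [[Rcpp::export]]
double cpp_eval_cv(NumericMatrix pos, NumericVector mass, int kind,
                   IntegerVector T, IntegerVector U, IntegerVector W,
                   IntegerVector X) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), m(mass.begin(), mass.end());
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i + k] = pos(i, k);
  CVDef cv;
  cv.kind = kind;
  cv.T.assign(T.begin(), T.end()); cv.U.assign(U.begin(), U.end());
  cv.W.assign(W.begin(), W.end()); cv.X.assign(X.begin(), X.end());
  return eval_cv_grad(cv, x, m, nullptr);
}

// [[Rcpp::export]]
List cpp_eval_cv_grad(NumericMatrix pos, NumericVector mass, int kind,
                      IntegerVector T, IntegerVector U, IntegerVector W,
                      IntegerVector X) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), m(mass.begin(), mass.end());
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i + k] = pos(i, k);
  CVDef cv;
  cv.kind = kind;
  cv.T.assign(T.begin(), T.end()); cv.U.assign(U.begin(), U.end());
  cv.W.assign(W.begin(), W.end()); cv.X.assign(X.begin(), X.end());
  std::vector<double> g(3 * n, 0.0);
  double val = eval_cv_grad(cv, x, m, &g);
  NumericMatrix go(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) go(i, k) = g[3*i + k];
  return List::create(_["value"] = val, _["grad"] = go);
}

// ---------------- bias grid ---------------------------------------------

struct BiasGrid {
  int ncv;
  double lo[2], hi[2], h[2];
  int nc[2];
  std::vector<double> B;         // nc1 (*nc2) node values at cell centres
  double halfwidth[2];           // kernel half-width in cv units
  inline int idx(int i, int j) const { return ncv == 1 ? i : i * nc[1] + j; }
};

// one (possibly mirrored) kernel centre per dimension; the kernel mass
// clipped by a grid edge is reflected back inside so boundary nodes fill at
// the same rate as interior nodes (consistent with the reflective walls)
static void deposit_centre(BiasGrid& g, const double* c, double w) {
  int i0[2], i1[2];
  for (int d = 0; d < g.ncv; ++d) {
    i0[d] = std::max(0, (int)std::floor((c[d] - g.halfwidth[d] - g.lo[d]) / g.h[d]));
    i1[d] = std::min(g.nc[d] - 1, (int)std::ceil((c[d] + g.halfwidth[d] - g.lo[d]) / g.h[d]));
  }
  if (g.ncv == 1) {
    for (int i = i0[0]; i <= i1[0]; ++i) {
      double u = (g.lo[0] + (i + 0.5) * g.h[0] - c[0]) / g.halfwidth[0];
      if (std::fabs(u) < 1.0) {
        double q = 1.0 - u*u;
        g.B[i] += w * q * q;
      }
    }
  } else {
    for (int i = i0[0]; i <= i1[0]; ++i) {
      double u = (g.lo[0] + (i + 0.5) * g.h[0] - c[0]) / g.halfwidth[0];
      if (std::fabs(u) >= 1.0) continue;
      double qu = 1.0 - u*u; qu *= qu;
      for (int j = i0[1]; j <= i1[1]; ++j) {
        double v = (g.lo[1] + (j + 0.5) * g.h[1] - c[1]) / g.halfwidth[1];
        if (std::fabs(v) >= 1.0) continue;
        double qv = 1.0 - v*v; qv *= qv;
        g.B[g.idx(i, j)] += w * qu * qv;
      }
    }
  }
}

static void deposit(BiasGrid& g, const double* cv, double w) {
  for (int d = 0; d < g.ncv; ++d)
    if (cv[d] < g.lo[d] || cv[d] > g.hi[d]) return; // outside: rejected
  // reflection images per dimension (0 = none, -1 = low edge, +1 = high edge)
  int refl[2][3]; int nrefl[2];
  for (int d = 0; d < g.ncv; ++d) {
    nrefl[d] = 1; refl[d][0] = 0;
    if (cv[d] - g.lo[d] < g.halfwidth[d]) refl[d][nrefl[d]++] = -1;
    if (g.hi[d] - cv[d] < g.halfwidth[d]) refl[d][nrefl[d]++] = +1;
  }
  double c[2];
  for (int a = 0; a < nrefl[0]; ++a) {
    c[0] = refl[0][a] == 0 ? cv[0] :
      (refl[0][a] < 0 ? 2 * g.lo[0] - cv[0] : 2 * g.hi[0] - cv[0]);
    if (g.ncv == 1) { deposit_centre(g, c, w); continue; }
    for (int b = 0; b < nrefl[1]; ++b) {
      c[1] = refl[1][b] == 0 ? cv[1] :
        (refl[1][b] < 0 ? 2 * g.lo[1] - cv[1] : 2 * g.hi[1] - cv[1]);
      deposit_centre(g, c, w);
    }
  }
}

// dB/dcv_d at cv by finite difference on linear interpolation
static void bias_grad(const BiasGrid& g, const double* cv, double* grad) {
  for (int d = 0; d < g.ncv; ++d) grad[d] = 0.0;
  int ic[2] = {0, 0};
  for (int d = 0; d < g.ncv; ++d) {
    double t = (cv[d] - g.lo[d]) / g.h[d] - 0.5;
    ic[d] = std::max(0, std::min(g.nc[d] - 2, (int)std::floor(t)));
  }
  if (g.ncv == 1) {
    grad[0] = (g.B[ic[0] + 1] - g.B[ic[0]]) / g.h[0];
  } else {
    // bilinear cell corner gradients
    double t1 = (cv[1] - g.lo[1]) / g.h[1] - 0.5 - ic[1];
    t1 = std::max(0.0, std::min(1.0, t1));
    grad[0] = ((1 - t1) * (g.B[g.idx(ic[0]+1, ic[1])] - g.B[g.idx(ic[0], ic[1])]) +
               t1 * (g.B[g.idx(ic[0]+1, ic[1]+1)] - g.B[g.idx(ic[0], ic[1]+1)])) / g.h[0];
    double t0 = (cv[0] - g.lo[0]) / g.h[0] - 0.5 - ic[0];
    t0 = std::max(0.0, std::min(1.0, t0));
    grad[1] = ((1 - t0) * (g.B[g.idx(ic[0], ic[1]+1)] - g.B[g.idx(ic[0], ic[1])]) +
               t0 * (g.B[g.idx(ic[0]+1, ic[1]+1)] - g.B[g.idx(ic[0]+1, ic[1])])) / g.h[1];
  }
}

// ---------------- integrator --------------------------------------------

// mode: 0 = cMD, 1 = GaMD, 2 = ABMD
// gamd: list(E, k); abmd: list(cvs = list(list(kind,T,U,W,X)), lo, hi, ncells,
//   halfwidth_cells, tau, wall_k, dep_stride)
// [[Rcpp::export]]
List cpp_run_dynamics(List pack, NumericMatrix x0, double dt, double gamma_ps,
                      double temperature, int n_steps, int stride, int mode,
                      List modepar) {
  System s = unpack(pack);
  const int n = s.n;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i + k] = x0(i, k);

  RNGScope scope;
  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(KB * temperature * ACC / s.mass[i]);
    for (int k = 0; k < 3; ++k)
      v[3*i + k] = s.frozen[i] ? 0.0 : R::rnorm(0.0, sd);
  }
  double gamma = gamma_ps * 1e-3; // 1/ps -> 1/fs
  double c1 = std::exp(-gamma * dt);
  std::vector<double> c2(n);
  for (int i = 0; i < n; ++i)
    c2[i] = std::sqrt((1.0 - c1 * c1) * KB * temperature * ACC / s.mass[i]);

  // GaMD parameters
  double gE = 0, gk = 0;
  if (mode == 1) { gE = as<double>(modepar["E"]); gk = as<double>(modepar["k"]); }

  // ABMD setup
  BiasGrid grid;
  std::vector<CVDef> cvs;
  double tau = 1, wall_k = 0;
  int dep_stride = 1;
  if (mode == 2) {
    List cvl = modepar["cvs"];
    for (int c = 0; c < cvl.size(); ++c) {
      List cd = cvl[c];
      CVDef cv;
      cv.kind = as<int>(cd["kind"]);
      cv.T = as<std::vector<int>>(cd["T"]); cv.U = as<std::vector<int>>(cd["U"]);
      cv.W = as<std::vector<int>>(cd["W"]); cv.X = as<std::vector<int>>(cd["X"]);
      cvs.push_back(cv);
    }
    grid.ncv = cvs.size();
    NumericVector lo = modepar["lo"], hi = modepar["hi"], hw = modepar["halfwidth"];
    IntegerVector nc = modepar["ncells"];
    int tot = 1;
    for (int d = 0; d < grid.ncv; ++d) {
      grid.lo[d] = lo[d]; grid.hi[d] = hi[d]; grid.nc[d] = nc[d];
      grid.h[d] = (hi[d] - lo[d]) / nc[d];
      grid.halfwidth[d] = hw[d];
      tot *= nc[d];
    }
    grid.B.assign(tot, 0.0);
    tau = as<double>(modepar["tau"]);         // fs
    wall_k = as<double>(modepar["wall_k"]);
    dep_stride = as<int>(modepar["dep_stride"]);
  }

  int n_save = n_steps / stride + 1;
  std::vector<double> wsum;     // window-averaged bias for convergence checks
  long wcount = 0;
  if (mode == 2) wsum.assign(grid.B.size(), 0.0);
  NumericVector Vs(n_save), Bs(n_save);
  NumericMatrix cvtrace(n_save, mode == 2 ? (int)cvs.size() : 1);
  NumericMatrix coords(n_save, 3 * n);
  List snapshots;
  int snap_every = std::max(1, n_steps / 10);

  std::vector<double> cvgrad1(3 * n), cvgrad2(3 * n);
  double cvval[2] = {0, 0};

  // force evaluation incl. bias / boost; returns original potential,
  // sets vboost; fills f
  auto full_force = [&](double& vboost) {
    double V = energy_forces(s, x, f, nullptr);
    if (!std::isfinite(V)) stop("non-finite potential energy during dynamics");
    vboost = 0.0;
    if (mode == 1 && V < gE) {
      double sc = 1.0 - gk * (gE - V);
      for (int q = 0; q < 3 * n; ++q) f[q] *= sc;
      vboost = 0.5 * gk * (gE - V) * (gE - V);
    } else if (mode == 2) {
      for (size_t c = 0; c < cvs.size(); ++c) {
        std::vector<double>& gbuf = (c == 0) ? cvgrad1 : cvgrad2;
        std::fill(gbuf.begin(), gbuf.end(), 0.0);
        cvval[c] = eval_cv_grad(cvs[c], x, s.mass, &gbuf);
      }
      double bg[2];
      bias_grad(grid, cvval, bg);
      for (size_t c = 0; c < cvs.size(); ++c) {
        double dBdc = bg[c];
        // harmonic walls confine the cv to the grid range
        if (wall_k > 0) {
          if (cvval[c] < grid.lo[c]) dBdc += wall_k * (cvval[c] - grid.lo[c]);
          if (cvval[c] > grid.hi[c]) dBdc += wall_k * (cvval[c] - grid.hi[c]);
        }
        if (dBdc != 0.0) {
          const std::vector<double>& gbuf = (c == 0) ? cvgrad1 : cvgrad2;
          for (int q = 0; q < 3 * n; ++q) f[q] -= dBdc * gbuf[q];
        }
      }
    }
    return V;
  };

  double vboost = 0.0;
  double V = full_force(vboost);
  int save_at = 0;
  auto save_frame = [&](int slot) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) coords(slot, 3*i + k) = x[3*i + k];
    Vs[slot] = V; Bs[slot] = vboost;
    if (mode == 2) for (size_t c = 0; c < cvs.size(); ++c) cvtrace(slot, c) = cvval[c];
  };
  if (mode == 2) {
    for (size_t c = 0; c < cvs.size(); ++c)
      cvval[c] = eval_cv_grad(cvs[c], x, s.mass, nullptr);
  }
  save_frame(save_at++);

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      double a = 0.5 * dt * ACC / s.mass[i];
      for (int k = 0; k < 3; ++k) v[3*i + k] += a * f[3*i + k];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int k = 0; k < 3; ++k) x[3*i + k] += 0.5 * dt * v[3*i + k];
    }
    // O: Ornstein-Uhlenbeck
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int k = 0; k < 3; ++k)
        v[3*i + k] = c1 * v[3*i + k] + c2[i] * R::norm_rand();
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      for (int k = 0; k < 3; ++k) x[3*i + k] += 0.5 * dt * v[3*i + k];
    }
    // force refresh + B: half kick
    V = full_force(vboost);
    for (int i = 0; i < n; ++i) {
      if (s.frozen[i]) continue;
      double a = 0.5 * dt * ACC / s.mass[i];
      for (int k = 0; k < 3; ++k) {
        v[3*i + k] += a * f[3*i + k];
        if (!std::isfinite(v[3*i + k]) || !std::isfinite(x[3*i + k]))
          stop("non-finite state at step %d (bead %d)", step, i + 1);
      }
    }
    // ABMD deposition
    if (mode == 2 && step % dep_stride == 0) {
      deposit(grid, cvval, dt * dep_stride / tau);
    }
    if (step % stride == 0) save_frame(save_at++);
    if (mode == 2) {
      for (size_t q = 0; q < grid.B.size(); ++q) wsum[q] += grid.B[q];
      ++wcount;
      if (step % snap_every == 0) {
        NumericVector snap(grid.B.size());
        for (size_t q = 0; q < grid.B.size(); ++q) snap[q] = wsum[q] / wcount;
        snapshots.push_back(snap);
        std::fill(wsum.begin(), wsum.end(), 0.0);
        wcount = 0;
      }
    }
  }

  List out = List::create(_["coords"] = coords, _["V"] = Vs, _["Vboost"] = Bs,
                          _["n_saved"] = save_at);
  if (mode == 2) {
    out["bias"] = NumericVector(grid.B.begin(), grid.B.end());
    out["cv"] = cvtrace;
    out["snapshots"] = snapshots;
  }
  return out;
}
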