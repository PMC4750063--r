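// Core numerics for the meshless rod-membrane model: pair/chain potentials,
// analytic forces and orientation gradients, and the Langevin (BAOAB) loop
// with optional constant-tension Monte Carlo box moves.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Params {
  double sigma, eps_rep, eps_att, rho_star, k_tilt, k_bend;
  double C0, C_side, C_rod, k_bond, k_angle, bond_l;
  double r_cut, r_att, kT, zeta, zeta_r, dt, m, inertia;
};

static Params read_params(const List& p) {
  Params q;
  q.sigma   = as<double>(p["sigma"]);
  q.eps_rep = as<double>(p["eps_rep"]);
  q.eps_att = as<double>(p["eps_att"]);
  q.rho_star= as<double>(p["rho_star"]);
  q.k_tilt  = as<double>(p["k_tilt"]);
  q.k_bend  = as<double>(p["k_bend"]);
  q.C0      = as<double>(p["C_0"]);
  q.C_side  = as<double>(p["C_side"]);
  q.C_rod   = as<double>(p["C_rod"]);
  q.k_bond  = as<double>(p["k_bond"]);
  q.k_angle = as<double>(p["k_angle"]);
  q.bond_l  = as<double>(p["bond_length"]);
  q.r_cut   = as<double>(p["r_cut"]);
  q.r_att   = as<double>(p["r_att"]);
  q.kT      = as<double>(p["kT"]);
  q.zeta    = as<double>(p["zeta"]);
  q.zeta_r  = as<double>(p["zeta_r"]);
  q.dt      = as<double>(p["dt"]);
  q.m       = as<double>(p["m"]);
  q.inertia = as<double>(p["inertia"]);
  return q;
}

// smooth compact weight: 1 for r <= r_att, C1 cosine ramp to 0 at r_cut
static inline double wcv(double r, double ra, double rc) {
  if (r <= ra) return 1.0;
  if (r >= rc) return 0.0;
  return 0.5 * (1.0 + std::cos(M_PI * (r - ra) / (rc - ra)));
}
static inline double dwcv(double r, double ra, double rc) {
  if (r <= ra || r >= rc) return 0.0;
  return -0.5 * M_PI / (rc - ra) * std::sin(M_PI * (r - ra) / (rc - ra));
}

// saturating multibody attraction well; u(0) = 0, u -> -0.25*log(1+e^{4 rho*})
static inline double u_att(double rho, double rs) {
  double x = -4.0 * (rho - rs);
  double lse = (x > 0.0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
  double lse0 = 4.0 * rs + std::log1p(std::exp(-4.0 * rs));
  return 0.25 * (lse - lse0);
}
static inline double du_att(double rho, double rs) {
  return -1.0 / (1.0 + std::exp(4.0 * (rho - rs)));
}

static inline void min_image(double& dx, double& dy, double& dz,
                             double Lx, double Ly, double Lz) {
  dx -= Lx * std::nearbyint(dx / Lx);
  dy -= Ly * std::nearbyint(dy / Ly);
  dz -= Lz * std::nearbyint(dz / Lz);
}

struct Workspace {
  std::vector<int> pi, pj;
  std::vector<double> pdx, pdy, pdz, pr;
  std::vector<double> F, G, rho; // 3n, 3n, n
  std::vector<int> head, nxt, cix, ciy, ciz;
};

static void build_pairs(const double* px, const double* py, const double* pz,
                        int n, const double* box, double r_cut, Workspace& w) {
  double Lx = box[0], Ly = box[1], Lz = box[2];
  w.pi.clear(); w.pj.clear(); w.pdx.clear(); w.pdy.clear(); w.pdz.clear(); w.pr.clear();
  int ncx = std::max(1, (int)std::floor(Lx / r_cut));
  int ncy = std::max(1, (int)std::floor(Ly / r_cut));
  int ncz = std::max(1, (int)std::floor(Lz / r_cut));
  bool brute = (ncx < 3 || ncy < 3 || ncz < 3 || n < 64);
  if (brute) {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double dx = px[b] - px[a], dy = py[b] - py[a], dz = pz[b] - pz[a];
        min_image(dx, dy, dz, Lx, Ly, Lz);
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < r_cut) {
          w.pi.push_back(a); w.pj.push_back(b);
          w.pdx.push_back(dx); w.pdy.push_back(dy); w.pdz.push_back(dz); w.pr.push_back(r);
        }
      }
    return;
  }
  int ncell = ncx * ncy * ncz;
  w.head.assign(ncell, -1);
  w.nxt.assign(n, -1);
  w.cix.resize(n); w.ciy.resize(n); w.ciz.resize(n);
  for (int a = 0; a < n; ++a) {
    double x = px[a] - Lx * std::floor(px[a] / Lx);
    double y = py[a] - Ly * std::floor(py[a] / Ly);
    double z = pz[a] - Lz * std::floor(pz[a] / Lz);
    int ix = std::min(ncx - 1, (int)(x / Lx * ncx));
    int iy = std::min(ncy - 1, (int)(y / Ly * ncy));
    int iz = std::min(ncz - 1, (int)(z / Lz * ncz));
    w.cix[a] = ix; w.ciy[a] = iy; w.ciz[a] = iz;
    int c = (iz * ncy + iy) * ncx + ix;
    w.nxt[a] = w.head[c]; w.head[c] = a;
  }
  for (int a = 0; a < n; ++a) {
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int ix = (w.cix[a] + ox + ncx) % ncx;
          int iy = (w.ciy[a] + oy + ncy) % ncy;
          int iz = (w.ciz[a] + oz + ncz) % ncz;
          int c = (iz * ncy + iy) * ncx + ix;
          for (int b = w.head[c]; b != -1; b = w.nxt[b]) {
            if (b <= a) continue;
            double dx = px[b] - px[a], dy = py[b] - py[a], dz = pz[b] - pz[a];
            min_image(dx, dy, dz, Lx, Ly, Lz);
            double r = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (r < r_cut) {
              w.pi.push_back(a); w.pj.push_back(b);
              w.pdx.push_back(dx); w.pdy.push_back(dy); w.pdz.push_back(dz); w.pr.push_back(r);
            }
          }
        }
  }
}

// pair spontaneous-curvature offset for distinct-rod / rod-membrane /
// membrane-membrane pairs; same-rod pairs are handled by the chain terms
static inline double pair_curv(int ri, int rj, const Params& q) {
  if (ri > 0 && rj > 0) return q.C_side;
  if (ri > 0 || rj > 0) return 0.5 * q.C_side;
  return q.C0;
}

struct Energies {
  double rep, att, tilt, bend, bond, angle;
  double total() const { return rep + att + tilt + bend + bond + angle; }
};

// positions/orientations as column-major n x 3 (R layout)
static Energies evaluate(const double* pos, const double* ori, int n,
                         const int* rodid,
                         const int* bonds, int nb, const int* angles, int na,
                         const double* box, const Params& q,
                         bool want_forces, Workspace& w) {
  const double* px = pos; const double* py = pos + n; const double* pz = pos + 2*n;
  build_pairs(px, py, pz, n, box, q.r_cut, w);
  size_t np = w.pi.size();

  Energies E = {0, 0, 0, 0, 0, 0};
  w.F.assign(3 * (size_t)n, 0.0);
  w.G.assign(3 * (size_t)n, 0.0);
  w.rho.assign(n, 0.0);
  double* Fx = w.F.data(); double* Fy = Fx + n; double* Fz = Fy + n;
  double* Gx = w.G.data(); double* Gy = Gx + n; double* Gz = Gy + n;
  const double* ux_ = ori; const double* uy_ = ori + n; const double* uz_ = ori + 2*n;

  const double rc = q.r_cut, ratt = q.r_att, sg = q.sigma;
  const double rep_shift = std::exp(-20.0 * (rc / sg - 1.0));

  // pass 1: local density (exclude non-bonded same-rod pairs)
  for (size_t k = 0; k < np; ++k) {
    int a = w.pi[k], b = w.pj[k];
    bool same_rod = (rodid[a] > 0 && rodid[a] == rodid[b]);
    bool bonded = same_rod && std::abs(a - b) == 1;
    if (same_rod && !bonded) continue;
    double wk = wcv(w.pr[k], ratt, rc);
    w.rho[a] += wk; w.rho[b] += wk;
  }
  for (int a = 0; a < n; ++a) E.att += q.eps_att * u_att(w.rho[a], q.rho_star);

  // pass 2: pair energies and forces
  for (size_t k = 0; k < np; ++k) {
    int a = w.pi[k], b = w.pj[k];
    int ra_id = rodid[a], rb_id = rodid[b];
    bool same_rod = (ra_id > 0 && ra_id == rb_id);
    bool bonded = same_rod && std::abs(a - b) == 1;
    double r = w.pr[k];
    double ex = w.pdx[k] / r, ey = w.pdy[k] / r, ez = w.pdz[k] / r; // rhat: a -> b
    double fx = 0.0, fy = 0.0, fz = 0.0; // force on b

    if (!bonded) { // repulsion (bond term replaces it for bonded pairs)
      double er = std::exp(-20.0 * (r / sg - 1.0));
      E.rep += q.eps_rep * (er - rep_shift);
      if (want_forces) {
        double fr = q.eps_rep * 20.0 / sg * er;
        fx += fr * ex; fy += fr * ey; fz += fr * ez;
      }
    }

    if (!(same_rod && !bonded) && want_forces) { // attraction via local density
      double dw = dwcv(r, ratt, rc);
      if (dw != 0.0) {
        double pref = q.eps_att * (du_att(w.rho[a], q.rho_star) + du_att(w.rho[b], q.rho_star));
        double fr = -pref * dw;
        fx += fr * ex; fy += fr * ey; fz += fr * ez;
      }
    }

    if (!same_rod) { // tilt + bend with spontaneous-curvature offset
      double wk = wcv(r, ratt, rc);
      if (wk > 0.0) {
        double uax = ux_[a], uay = uy_[a], uaz = uz_[a];
        double ubx = ux_[b], uby = uy_[b], ubz = uz_[b];
        double sa = uax*ex + uay*ey + uaz*ez;
        double sb = ubx*ex + uby*ey + ubz*ez;
        E.tilt += 0.5 * q.k_tilt * (sa*sa + sb*sb) * wk;

        double c = pair_curv(ra_id, rb_id, q);
        double dxv = uax - ubx + c * w.pdx[k];
        double dyv = uay - uby + c * w.pdy[k];
        double dzv = uaz - ubz + c * w.pdz[k];
        double d2 = dxv*dxv + dyv*dyv + dzv*dzv;
        E.bend += 0.5 * q.k_bend * d2 * wk;

        if (want_forces) {
          double dw = dwcv(r, ratt, rc);
          double tb = q.k_tilt * wk;
          double s2 = 0.5 * q.k_tilt * (sa*sa + sb*sb) * dw;
          fx -= tb * (sa * (uax - sa*ex) + sb * (ubx - sb*ex)) / r + s2 * ex;
          fy -= tb * (sa * (uay - sa*ey) + sb * (uby - sb*ey)) / r + s2 * ey;
          fz -= tb * (sa * (uaz - sa*ez) + sb * (ubz - sb*ez)) / r + s2 * ez;
          Gx[a] += tb * sa * ex; Gy[a] += tb * sa * ey; Gz[a] += tb * sa * ez;
          Gx[b] += tb * sb * ex; Gy[b] += tb * sb * ey; Gz[b] += tb * sb * ez;

          double bb = q.k_bend * wk * c;
          double b2 = 0.5 * q.k_bend * d2 * dw;
          fx -= bb * dxv + b2 * ex;
          fy -= bb * dyv + b2 * ey;
          fz -= bb * dzv + b2 * ez;
          double kb = q.k_bend * wk;
          Gx[a] += kb * dxv; Gy[a] += kb * dyv; Gz[a] += kb * dzv;
          Gx[b] -= kb * dxv; Gy[b] -= kb * dyv; Gz[b] -= kb * dzv;
        }
      }
    }

    if (want_forces) {
      Fx[b] += fx; Fy[b] += fy; Fz[b] += fz;
      Fx[a] -= fx; Fy[a] -= fy; Fz[a] -= fz;
    }
  }

  double Lx = box[0], Ly = box[1], Lz = box[2];
  for (int k = 0; k < nb; ++k) { // harmonic bonds
    int a = bonds[k], b = bonds[k + nb];
    double dx = px[b] - px[a], dy = py[b] - py[a], dz = pz[b] - pz[a];
    min_image(dx, dy, dz, Lx, Ly, Lz);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - q.bond_l;
    E.bond += 0.5 * q.k_bond * dr * dr;
    if (want_forces) {
      double fr = -q.k_bond * dr / r;
      Fx[b] += fr * dx; Fy[b] += fr * dy; Fz[b] += fr * dz;
      Fx[a] -= fr * dx; Fy[a] -= fr * dy; Fz[a] -= fr * dz;
    }
  }

  // chain angle term: E = (k_angle/2) |t2 - t1 + C_rod * l * u_b|^2.
  // The preferred turn of C_rod*l per joint is directed against the central
  // particle's orientation, so the rod arcs in its own normal plane.
  double c0 = q.C_rod * q.bond_l;
  for (int k = 0; k < na; ++k) {
    int a = angles[k], b = angles[k + na], c = angles[k + 2*na];
    double v1x = px[b] - px[a], v1y = py[b] - py[a], v1z = pz[b] - pz[a];
    double v2x = px[c] - px[b], v2y = py[c] - py[b], v2z = pz[c] - pz[b];
    min_image(v1x, v1y, v1z, Lx, Ly, Lz);
    min_image(v2x, v2y, v2z, Lx, Ly, Lz);
    double n1 = std::sqrt(v1x*v1x + v1y*v1y + v1z*v1z);
    double n2 = std::sqrt(v2x*v2x + v2y*v2y + v2z*v2z);
    double t1x = v1x/n1, t1y = v1y/n1, t1z = v1z/n1;
    double t2x = v2x/n2, t2y = v2y/n2, t2z = v2z/n2;
    double dx = t2x - t1x + c0*ux_[b], dy = t2y - t1y + c0*uy_[b], dz = t2z - t1z + c0*uz_[b];
    double d2 = dx*dx + dy*dy + dz*dz;
    E.angle += 0.5 * q.k_angle * d2;
    if (want_forces) {
      double dt1 = dx*t1x + dy*t1y + dz*t1z;
      double g1x = -q.k_angle * (dx - dt1*t1x) / n1;
      double g1y = -q.k_angle * (dy - dt1*t1y) / n1;
      double g1z = -q.k_angle * (dz - dt1*t1z) / n1;
      double dt2 = dx*t2x + dy*t2y + dz*t2z;
      double g2x = q.k_angle * (dx - dt2*t2x) / n2;
      double g2y = q.k_angle * (dy - dt2*t2y) / n2;
      double g2z = q.k_angle * (dz - dt2*t2z) / n2;
      Fx[a] += g1x; Fy[a] += g1y; Fz[a] += g1z;
      Fx[b] -= (g1x - g2x); Fy[b] -= (g1y - g2y); Fz[b] -= (g1z - g2z);
      Fx[c] -= g2x; Fy[c] -= g2y; Fz[c] -= g2z;
      Gx[b] += q.k_angle * c0 * dx;
      Gy[b] += q.k_angle * c0 * dy;
      Gz[b] += q.k_angle * c0 * dz;
    }
  }

  return E;
}

// [[Rcpp::export]]
List forces_cpp(NumericMatrix pos, NumericMatrix ori, IntegerVector rodid,
                IntegerMatrix bonds, IntegerMatrix angles,
                NumericVector box, List params, bool want_forces) {
  Params q = read_params(params);
  int n = pos.nrow();
  Workspace w;
  Energies E = evaluate(REAL(pos), REAL(ori), n, INTEGER(rodid),
                        INTEGER(bonds), bonds.nrow(), INTEGER(angles), angles.nrow(),
                        REAL(box), q, want_forces, w);
  NumericMatrix F(n, 3), G(n, 3);
  NumericVector rho(n);
  for (int a = 0; a < n; ++a) {
    F(a,0) = w.F[a]; F(a,1) = w.F[a + n]; F(a,2) = w.F[a + 2*n];
    G(a,0) = w.G[a]; G(a,1) = w.G[a + n]; G(a,2) = w.G[a + 2*n];
    rho[a] = w.rho[a];
  }
  return List::create(
    _["e_rep"] = E.rep, _["e_att"] = E.att, _["e_tilt"] = E.tilt,
    _["e_bend"] = E.bend, _["e_bond"] = E.bond, _["e_angle"] = E.angle,
    _["energy"] = E.total(), _["forces"] = F, _["ugrad"] = G, _["rho"] = rho);
}

// [[Rcpp::export]]
NumericVector local_density_cpp(NumericMatrix pos, IntegerVector rodid,
                                NumericVector box, List params) {
  Params q = read_params(params);
  int n = pos.nrow();
  Workspace w;
  const double* p = REAL(pos);
  build_pairs(p, p + n, p + 2*n, n, REAL(box), q.r_cut, w);
  NumericVector rho(n);
  const int* rid = INTEGER(rodid);
  for (size_t k = 0; k < w.pi.size(); ++k) {
    int a = w.pi[k], b = w.pj[k];
    bool same_rod = (rid[a] > 0 && rid[a] == rid[b]);
    bool bonded = same_rod && std::abs(a - b) == 1;
    if (same_rod && !bonded) continue;
    double wk = wcv(w.pr[k], q.r_att, q.r_cut);
    rho[a] += wk; rho[b] += wk;
  }
  return rho;
}

// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, NumericVector box, double cutoff) {
  int n = pos.nrow();
  Workspace w;
  const double* p = REAL(pos);
  build_pairs(p, p + n, p + 2*n, n, REAL(box), cutoff, w);
  int np = w.pi.size();
  IntegerMatrix out(np, 2);
  for (int k = 0; k < np; ++k) { out(k,0) = w.pi[k] + 1; out(k,1) = w.pj[k] + 1; }
  return out;
}

static inline void rotate_about(double& ux, double& uy, double& uz,
                                double wx, double wy, double wz, double h) {
  double wn = std::sqrt(wx*wx + wy*wy + wz*wz);
  double th = wn * h;
  if (th < 1e-14) return;
  double ax = wx/wn, ay = wy/wn, az = wz/wn;
  double ct = std::cos(th), st = std::sin(th);
  double adot = ax*ux + ay*uy + az*uz;
  double cx = ay*uz - az*uy, cy = az*ux - ax*uz, cz = ax*uy - ay*ux;
  double nx = ux*ct + cx*st + ax*adot*(1-ct);
  double ny = uy*ct + cy*st + ay*adot*(1-ct);
  double nz = uz*ct + cz*st + az*adot*(1-ct);
  ux = nx; uy = ny; uz = nz;
}

// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix pos0, NumericMatrix ori0,
                      NumericMatrix vel0, NumericMatrix angv0,
                      IntegerVector rodid, IntegerMatrix bonds, IntegerMatrix angles,
                      NumericVector box0, List params, int nsteps,
                      double seed, bool tension_on, double gamma,
                      int tension_interval, double tension_amp) {
  Params q = read_params(params);
  NumericMatrix pos = clone(pos0), ori = clone(ori0), vel = clone(vel0), angv = clone(angv0);
  NumericVector box = clone(box0);
  int n = pos.nrow();
  int nb = bonds.nrow(), na = angles.nrow();
  const int* bptr = (nb > 0) ? INTEGER(bonds) : nullptr;
  const int* aptr = (na > 0) ? INTEGER(angles) : nullptr;
  const int* rid = INTEGER(rodid);
  double* P = REAL(pos); double* O = REAL(ori); double* V = REAL(vel); double* W = REAL(angv);
  double* Bx = REAL(box);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double dt = q.dt, m = q.m, I = q.inertia;
  double c1 = (q.zeta > 0.0) ? std::exp(-q.zeta * dt / m) : 1.0;
  double c2 = (q.kT > 0.0 && q.zeta > 0.0) ? std::sqrt(q.kT / m * (1.0 - c1 * c1)) : 0.0;
  double c1r = (q.zeta_r > 0.0) ? std::exp(-q.zeta_r * dt / I) : 1.0;
  double c2r = (q.kT > 0.0 && q.zeta_r > 0.0) ? std::sqrt(q.kT / I * (1.0 - c1r * c1r)) : 0.0;

  Workspace w;
  Energies E = evaluate(P, O, n, rid, bptr, nb, aptr, na, Bx, q, true, w);
  double U = E.total();
  int acc = 0, tries = 0;
  double ke_acc = 0.0;
  int ke_n = 0;
  bool bad = false;

  std::vector<double> trial(3 * (size_t)n);
  Workspace w2;

  for (int s = 0; s < nsteps; ++s) {
    for (int a = 0; a < n; ++a) { // B
      V[a]       += 0.5 * dt * w.F[a] / m;
      V[a + n]   += 0.5 * dt * w.F[a + n] / m;
      V[a + 2*n] += 0.5 * dt * w.F[a + 2*n] / m;
      double ux = O[a], uy = O[a + n], uz = O[a + 2*n];
      double gx = w.G[a], gy = w.G[a + n], gz = w.G[a + 2*n];
      W[a]       += 0.5 * dt * (-(uy*gz - uz*gy)) / I;
      W[a + n]   += 0.5 * dt * (-(uz*gx - ux*gz)) / I;
      W[a + 2*n] += 0.5 * dt * (-(ux*gy - uy*gx)) / I;
    }
    for (int a = 0; a < n; ++a) { // A half
      P[a] += 0.5 * dt * V[a];
      P[a + n] += 0.5 * dt * V[a + n];
      P[a + 2*n] += 0.5 * dt * V[a + 2*n];
      rotate_about(O[a], O[a + n], O[a + 2*n], W[a], W[a + n], W[a + 2*n], 0.5 * dt);
    }
    if (q.zeta > 0.0 || q.zeta_r > 0.0) { // O
      for (int a = 0; a < n; ++a) {
        if (q.zeta > 0.0) {
          V[a] = c1 * V[a] + c2 * norm(rng);
          V[a + n] = c1 * V[a + n] + c2 * norm(rng);
          V[a + 2*n] = c1 * V[a + 2*n] + c2 * norm(rng);
        }
        if (q.zeta_r > 0.0) {
          double wx = c1r * W[a] + c2r * norm(rng);
          double wy = c1r * W[a + n] + c2r * norm(rng);
          double wz = c1r * W[a + 2*n] + c2r * norm(rng);
          double ux = O[a], uy = O[a + n], uz = O[a + 2*n];
          double d = wx*ux + wy*uy + wz*uz;
          W[a] = wx - d*ux; W[a + n] = wy - d*uy; W[a + 2*n] = wz - d*uz;
        }
      }
    }
    for (int a = 0; a < n; ++a) { // A half
      P[a] += 0.5 * dt * V[a];
      P[a + n] += 0.5 * dt * V[a + n];
      P[a + 2*n] += 0.5 * dt * V[a + 2*n];
      rotate_about(O[a], O[a + n], O[a + 2*n], W[a], W[a + n], W[a + 2*n], 0.5 * dt);
      double ux = O[a], uy = O[a + n], uz = O[a + 2*n];
      double un = std::sqrt(ux*ux + uy*uy + uz*uz);
      O[a] = ux/un; O[a + n] = uy/un; O[a + 2*n] = uz/un;
    }
    E = evaluate(P, O, n, rid, bptr, nb, aptr, na, Bx, q, true, w);
    U = E.total();
    if (!std::isfinite(U)) { bad = true; break; }
    for (int a = 0; a < n; ++a) { // B
      V[a]       += 0.5 * dt * w.F[a] / m;
      V[a + n]   += 0.5 * dt * w.F[a + n] / m;
      V[a + 2*n] += 0.5 * dt * w.F[a + 2*n] / m;
      double ux = O[a], uy = O[a + n], uz = O[a + 2*n];
      double gx = w.G[a], gy = w.G[a + n], gz = w.G[a + 2*n];
      W[a]       += 0.5 * dt * (-(uy*gz - uz*gy)) / I;
      W[a + n]   += 0.5 * dt * (-(uz*gx - ux*gz)) / I;
      W[a + 2*n] += 0.5 * dt * (-(ux*gy - uy*gx)) / I;
    }

    // constant-tension MC box move on the projected (x,y) area
    if (tension_on && ((s + 1) % tension_interval == 0)) {
      ++tries;
      double A = Bx[0] * Bx[1];
      double dA = (2.0 * unif(rng) - 1.0) * tension_amp * A;
      double scale = std::sqrt((A + dA) / A);
      if (std::isfinite(scale) && scale > 0.0) {
        for (int a = 0; a < n; ++a) {
          trial[a] = P[a] * scale;
          trial[a + n] = P[a + n] * scale;
          trial[a + 2*n] = P[a + 2*n];
        }
        double tb[3] = {Bx[0] * scale, Bx[1] * scale, Bx[2]};
        Energies E2 = evaluate(trial.data(), O, n, rid, bptr, nb, aptr, na,
                               tb, q, false, w2);
        double U2 = E2.total();
        double arg = -(U2 - U - gamma * dA) / q.kT;
        if (std::isfinite(U2) && (arg >= 0.0 || unif(rng) < std::exp(arg))) {
          std::copy(trial.begin(), trial.end(), P);
          Bx[0] = tb[0]; Bx[1] = tb[1];
          ++acc;
          E = evaluate(P, O, n, rid, bptr, nb, aptr, na, Bx, q, true, w);
          U = E.total();
        }
      }
    }

    double ke = 0.0;
    for (int a = 0; a < n; ++a)
      ke += V[a]*V[a] + V[a + n]*V[a + n] + V[a + 2*n]*V[a + 2*n];
    ke_acc += 0.5 * m * ke;
    ++ke_n;
  }

  return List::create(
    _["pos"] = pos, _["ori"] = ori, _["vel"] = vel, _["angv"] = angv,
    _["box"] = box, _["energy"] = U,
    _["ke_mean"] = (ke_n > 0 ? ke_acc / ke_n : NA_REAL),
    _["tension_acc"] = acc, _["tension_try"] = tries,
    _["nan_abort"] = bad);
}
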