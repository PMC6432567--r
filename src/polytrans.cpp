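// Core numerics: pair forces, smooth Ewald sums, Langevin (GJF) integration.
// Reduced units throughout: sigma (length), m (mass), tau_u = sigma*sqrt(m/kT)
// (time), e (charge); k_B T = 1 unless stated otherwise.

#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>
#include <set>
#include <utility>
#include <cstdint>

using namespace Rcpp;
typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++ with Box-Muller gaussians.
// Deterministic per (seed) on one platform; independent of R's RNG.
// ---------------------------------------------------------------------------
struct RNG {
  uint64_t s[4];
  bool has_spare;
  double spare;
  explicit RNG(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// ---------------------------------------------------------------------------
// Small structs unpacked from R lists
// ---------------------------------------------------------------------------
struct Pars {
  double sbb, ebb, sbw, ebw, kb, r0, lB, zeta, T, mass;
};

struct Geo {
  double Lx, Ly, Lz;   // periodic box
  double zlo, zhi;     // pore interval in z (closed); wall slab spans it
  double prad;         // pore radius
  double cx, cy;       // pore axis (x, y)
};

static Pars as_pars(const List& p) {
  Pars q;
  q.sbb = p["sigma_bb"]; q.ebb = p["eps_bb"];
  q.sbw = p["sigma_bw"]; q.ebw = p["eps_bw"];
  q.kb  = p["k_bond"];   q.r0  = p["r0"];
  q.lB  = p["lambda_B"]; q.zeta = p["zeta"];
  q.T   = p["T"];        q.mass = p["mass"];
  return q;
}

static Geo as_geo(const List& g) {
  Geo q;
  NumericVector box = g["box"];
  q.Lx = box[0]; q.Ly = box[1]; q.Lz = box[2];
  q.zlo = g["z_lo"]; q.zhi = g["z_hi"];
  q.prad = g["pore_radius"];
  q.cx = g["axis_x"]; q.cy = g["axis_y"];
  return q;
}

static inline double mimg(double d, double L) {
  // minimum image for one component
  if (d >  0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// ---------------------------------------------------------------------------
// Ewald reciprocal-space setup
// ---------------------------------------------------------------------------
struct KSetup {
  std::vector<double> kx, ky, kz, Ak; // per included half-space vector
  int mx, my, mz;                     // integer phase-table extents
  double alpha, rcut, rcut2;
  double V;
  double s_k;                         // reciprocal truncation k_max/(2 alpha)
};

static KSetup build_kspace(double alpha, double rcut,
                           double nkx, double nky, double nkz,
                           double Lx, double Ly, double Lz) {
  KSetup ks;
  ks.alpha = alpha; ks.rcut = rcut; ks.rcut2 = rcut * rcut;
  ks.V = Lx * Ly * Lz;
  // the mode ellipsoid approximates a sphere of radius k_max = 2 pi nkx/Lx
  ks.s_k = (nkx > 0) ? M_PI * nkx / (Lx * alpha) : 0.0;
  const double tpi = 6.283185307179586476925286766559;
  ks.mx = (int)std::ceil(nkx); ks.my = (int)std::ceil(nky);
  ks.mz = (int)std::ceil(nkz);
  const double inv4a2 = 1.0 / (4.0 * alpha * alpha);
  for (int nx = 0; nx <= ks.mx; ++nx) {
    int ny0 = (nx == 0) ? 0 : -ks.my;
    for (int ny = ny0; ny <= ks.my; ++ny) {
      int nz0 = (nx == 0 && ny == 0) ? 1 : -ks.mz;
      for (int nz = nz0; nz <= ks.mz; ++nz) {
        double ex = nx / std::max(nkx, 1e-12);
        double ey = ny / std::max(nky, 1e-12);
        double ez = nz / std::max(nkz, 1e-12);
        if (ex * ex + ey * ey + ez * ez > 1.0) continue;
        double kxv = tpi * nx / Lx;
        double kyv = tpi * ny / Ly;
        double kzv = tpi * nz / Lz;
        double k2 = kxv * kxv + kyv * kyv + kzv * kzv;
        if (k2 <= 0) continue;
        double Ak = (4.0 * M_PI / ks.V) * std::exp(-k2 * inv4a2) / k2;
        ks.kx.push_back(kxv); ks.ky.push_back(kyv); ks.kz.push_back(kzv);
        ks.Ak.push_back(Ak);
      }
    }
  }
  return ks;
}

// Reciprocal-space energy + forces for charges q (units of kT, Coulomb
// prefactor C = lambda_B). Per-dimension phase tables built by recursion;
// the half-space k sum is doubled.
static double kspace_ef2(const std::vector<double>& px,
                         const std::vector<double>& py,
                         const std::vector<double>& pz,
                         const std::vector<double>& q,
                         const KSetup& ks,
                         double Lx, double Ly, double Lz, double C,
                         std::vector<double>& fx,
                         std::vector<double>& fy,
                         std::vector<double>& fz,
                         bool want_force) {
  const int n = (int)q.size();
  const int K = (int)ks.Ak.size();
  if (K == 0 || n == 0) return 0.0;
  const double tpi = 6.283185307179586476925286766559;
  const int mx = ks.mx, my = ks.my, mz = ks.mz;
  std::vector<cplx> ex((size_t)n * (mx + 1));
  std::vector<cplx> ey((size_t)n * (my + 1));
  std::vector<cplx> ez((size_t)n * (mz + 1));
  for (int j = 0; j < n; ++j) {
    cplx bx(std::cos(tpi * px[j] / Lx), std::sin(tpi * px[j] / Lx));
    cplx by(std::cos(tpi * py[j] / Ly), std::sin(tpi * py[j] / Ly));
    cplx bz(std::cos(tpi * pz[j] / Lz), std::sin(tpi * pz[j] / Lz));
    cplx ax(1.0, 0.0), ay(1.0, 0.0), az(1.0, 0.0);
    for (int m = 0; m <= mx; ++m) { ex[(size_t)j * (mx + 1) + m] = ax; ax *= bx; }
    for (int m = 0; m <= my; ++m) { ey[(size_t)j * (my + 1) + m] = ay; ay *= by; }
    for (int m = 0; m <= mz; ++m) { ez[(size_t)j * (mz + 1) + m] = az; az *= bz; }
  }
  double U = 0.0;
  std::vector<cplx> tj(n); // per-particle q_j e^{i k r_j} for current k
  for (int kk = 0; kk < K; ++kk) {
    double kxv = ks.kx[kk], kyv = ks.ky[kk], kzv = ks.kz[kk];
    int nx = (int)std::lround(kxv * Lx / tpi);
    int ny = (int)std::lround(kyv * Ly / tpi);
    int nz = (int)std::lround(kzv * Lz / tpi);
    cplx S(0.0, 0.0);
    for (int j = 0; j < n; ++j) {
      cplx pxc = ex[(size_t)j * (mx + 1) + std::abs(nx)];
      if (nx < 0) pxc = std::conj(pxc);
      cplx pyc = ey[(size_t)j * (my + 1) + std::abs(ny)];
      if (ny < 0) pyc = std::conj(pyc);
      cplx pzc = ez[(size_t)j * (mz + 1) + std::abs(nz)];
      if (nz < 0) pzc = std::conj(pzc);
      cplx t = q[j] * pxc * pyc * pzc;
      tj[j] = t;
      S += t;
    }
    double Ak = ks.Ak[kk];
    U += Ak * std::norm(S); // Ak already carries the half-space doubling
    if (want_force) {
      // F_j = 2 C Ak k * Im(conj(S) t_j), summed over the half space
      for (int j = 0; j < n; ++j) {
        double im = S.real() * tj[j].imag() - S.imag() * tj[j].real();
        double g = 2.0 * C * Ak * im;
        fx[j] += g * kxv; fy[j] += g * kyv; fz[j] += g * kzv;
      }
    }
  }
  return C * U;
}

// ---------------------------------------------------------------------------
// Standalone periodic Coulomb (Ewald) energy/forces, for the electrostatics
// module. charges may be any real numbers but must sum to ~0.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".ewald_cpp")]]
List ewald_cpp(NumericMatrix pos, NumericVector charge, NumericVector box,
               double alpha, double r_cut, NumericVector nk,
               double lambda_B, bool dipole_correction) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  double qsum = 0.0, q2 = 0.0;
  for (int i = 0; i < n; ++i) { qsum += charge[i]; q2 += charge[i] * charge[i]; }
  if (std::abs(qsum) > 1e-9)
    stop("Ewald requires a charge-neutral system (net charge = %g)", qsum);
  if (r_cut > 0.5 * std::min(Lx, std::min(Ly, Lz)) + 1e-9)
    stop("Ewald real-space cutoff %g exceeds half the smallest box edge", r_cut);
  KSetup ks = build_kspace(alpha, r_cut, nk[0], nk[1], nk[2], Lx, Ly, Lz);
  std::vector<double> px(n), py(n), pz(n), q(n), fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); q[i] = charge[i];
  }
  const double C = lambda_B;
  // real space (all pairs; module scale is <= ~2000 charges)
  double Ur = 0.0;
  const double rc2 = r_cut * r_cut;
  const double twa = 2.0 * alpha / std::sqrt(M_PI);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double qq = q[i] * q[j];
      if (qq == 0.0) continue;
      double dz = mimg(pz[i] - pz[j], Lz);
      if (dz * dz > rc2) continue;
      double dx = mimg(px[i] - px[j], Lx);
      double dy = mimg(py[i] - py[j], Ly);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rc2 || r2 <= 0.0) continue;
      double r = std::sqrt(r2);
      double erfc_ar = std::erfc(alpha * r);
      Ur += C * qq * erfc_ar / r;
      double fmag = C * qq * (erfc_ar / r + twa * std::exp(-alpha * alpha * r2)) / r2;
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
  }
  double Uk = kspace_ef2(px, py, pz, q, ks, Lx, Ly, Lz, C, fx, fy, fz, true);
  double Uself = -C * alpha / std::sqrt(M_PI) * q2;
  // diffuse tail of the truncated reciprocal sum (random-phase estimate of
  // the modes beyond k_max); configuration-independent, so no force term
  double Utail = C * q2 * alpha / std::sqrt(M_PI) * std::erfc(ks.s_k);
  double Ud = 0.0;
  if (dipole_correction) {
    // vacuum (epsilon' = 1) surface term; positions taken as given (unwrapped)
    double Mx = 0, My = 0, Mz = 0;
    for (int i = 0; i < n; ++i) { Mx += q[i] * px[i]; My += q[i] * py[i]; Mz += q[i] * pz[i]; }
    double V = Lx * Ly * Lz;
    Ud = C * 2.0 * M_PI / (3.0 * V) * (Mx * Mx + My * My + Mz * Mz);
    for (int i = 0; i < n; ++i) {
      double g = -C * 4.0 * M_PI / (3.0 * V) * q[i];
      fx[i] += g * Mx; fy[i] += g * My; fz[i] += g * Mz;
    }
  }
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["energy"] = Ur + Uk + Uself + Utail + Ud,
                      _["forces"] = F,
                      _["e_real"] = Ur, _["e_recip"] = Uk + Utail,
                      _["e_self"] = Uself, _["e_dipole"] = Ud,
                      _["n_kvec"] = (int)ks.Ak.size());
}

// ---------------------------------------------------------------------------
// Static wall grid for bead-wall WCA lookups
// ---------------------------------------------------------------------------
struct WallGrid {
  std::vector<double> wx, wy, wz;
  std::vector<int> head, nxt;
  int nx, ny, nz;
  double cell, z0, z1; // z extent covered (wall z range padded by cutoff)
  double Lx, Ly;
  bool empty;
};

static WallGrid build_wall_grid(const NumericMatrix& wall, double cutoff,
                                double Lx, double Ly) {
  WallGrid g;
  int m = wall.nrow();
  g.Lx = Lx; g.Ly = Ly;
  g.empty = (m == 0);
  if (g.empty) { g.nx = g.ny = g.nz = 0; return g; }
  g.wx.resize(m); g.wy.resize(m); g.wz.resize(m);
  double zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < m; ++i) {
    g.wx[i] = wall(i, 0); g.wy[i] = wall(i, 1); g.wz[i] = wall(i, 2);
    zmin = std::min(zmin, g.wz[i]); zmax = std::max(zmax, g.wz[i]);
  }
  g.cell = std::max(cutoff, 1.0);
  g.z0 = zmin - cutoff - 1e-9; g.z1 = zmax + cutoff + 1e-9;
  g.nx = std::max(1, (int)std::floor(Lx / g.cell));
  g.ny = std::max(1, (int)std::floor(Ly / g.cell));
  g.nz = std::max(1, (int)std::ceil((g.z1 - g.z0) / g.cell));
  g.head.assign((size_t)g.nx * g.ny * g.nz, -1);
  g.nxt.assign(m, -1);
  for (int i = 0; i < m; ++i) {
    int cx = (int)std::floor(g.wx[i] / Lx * g.nx); cx = ((cx % g.nx) + g.nx) % g.nx;
    int cy = (int)std::floor(g.wy[i] / Ly * g.ny); cy = ((cy % g.ny) + g.ny) % g.ny;
    int cz = (int)std::floor((g.wz[i] - g.z0) / g.cell);
    cz = std::max(0, std::min(g.nz - 1, cz));
    int c = (cz * g.ny + cy) * g.nx + cx;
    g.nxt[i] = g.head[c]; g.head[c] = i;
  }
  return g;
}

static inline double wca_fmag_over_r(double r2, double sig, double eps,
                                     double& u) {
  // returns F/r (so F_vec = val * d_vec) and adds energy into u
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  u += 4.0 * eps * (s12 - s6 + 0.25);
  return 24.0 * eps * (2.0 * s12 - s6) / r2;
}

// ---------------------------------------------------------------------------
// Force/energy assembly for the full system
// ---------------------------------------------------------------------------
struct ForceCtx {
  Pars p;
  Geo g;
  KSetup ks;
  WallGrid wg;
  double wca_cut2_bb, wca_cut2_bw, wca_cut_bw;
  int n_monomer;
  double E;              // field strength (kT / (e sigma))
  bool barrier_armed;    // one-way exit barrier on monomer 1 active
  double C;              // Coulomb prefactor lambda_B
  bool do_coulomb;
};

struct EnergyParts {
  double pair, bond, wall, coul, field, barrier;
  double total() const { return pair + bond + wall + coul + field + barrier; }
};

static void assemble_forces(const std::vector<double>& px,
                            const std::vector<double>& py,
                            const std::vector<double>& pz,
                            const std::vector<double>& q,
                            const std::vector<int>& bf,
                            const std::vector<int>& bt,
                            ForceCtx& cx,
                            std::vector<double>& fx,
                            std::vector<double>& fy,
                            std::vector<double>& fz,
                            bool want_energy, EnergyParts& ep) {
  const int n = (int)px.size();
  const Pars& P = cx.p;
  const Geo& G = cx.g;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  ep.pair = ep.bond = ep.wall = ep.coul = ep.field = ep.barrier = 0.0;

  // bonded pairs are excluded from the WCA term (the stiff spring already
  // prevents overlap); electrostatics keeps all pairs
  std::set<std::pair<int, int> > bonded_set;
  for (size_t b = 0; b < bf.size(); ++b)
    bonded_set.insert(std::make_pair(std::min(bf[b], bt[b]),
                                     std::max(bf[b], bt[b])));
  // pair loop: WCA (non-bonded) + Ewald real space
  const double rc2 = cx.do_coulomb ? cx.ks.rcut2 : cx.wca_cut2_bb;
  const double alpha = cx.ks.alpha;
  const double twa = 2.0 * alpha / std::sqrt(M_PI);
  double Ureal = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dz = mimg(pz[i] - pz[j], G.Lz);
      if (dz * dz > rc2) continue;
      double dx = mimg(px[i] - px[j], G.Lx);
      double dy = mimg(py[i] - py[j], G.Ly);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rc2) continue;
      if (r2 < 1e-12)
        stop("singular configuration: beads %d and %d overlap (r^2 = %g)",
             i + 1, j + 1, r2);
      double fr = 0.0;
      if (r2 < cx.wca_cut2_bb &&
          (bonded_set.empty() ||
           bonded_set.count(std::make_pair(i, j)) == 0)) {
        fr += wca_fmag_over_r(r2, P.sbb, P.ebb, ep.pair);
      }
      double qq = q[i] * q[j];
      if (cx.do_coulomb && qq != 0.0) {
        double r = std::sqrt(r2);
        double erfc_ar = std::erfc(alpha * r);
        Ureal += cx.C * qq * erfc_ar / r;
        fr += cx.C * qq *
              (erfc_ar / r + twa * std::exp(-alpha * alpha * r2)) / r2;
      }
      if (fr != 0.0) {
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
  }

  // bonds (harmonic; WCA excluded between bonded neighbours)
  for (size_t b = 0; b < bf.size(); ++b) {
    int i = bf[b], j = bt[b];
    double dx = mimg(px[i] - px[j], G.Lx);
    double dy = mimg(py[i] - py[j], G.Ly);
    double dz = mimg(pz[i] - pz[j], G.Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) stop("singular bond %d-%d (r = %g)", i + 1, j + 1, r);
    ep.bond += 0.5 * P.kb * (r - P.r0) * (r - P.r0);
    double fr = -P.kb * (r - P.r0) / r; // force on i along d
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }

  // bead-wall WCA via static grid
  if (!cx.wg.empty) {
    const WallGrid& W = cx.wg;
    for (int i = 0; i < n; ++i) {
      double zi = pz[i];
      if (zi < W.z0 || zi > W.z1) continue;
      int cxi = (int)std::floor(px[i] / W.Lx * W.nx);
      cxi = ((cxi % W.nx) + W.nx) % W.nx;
      int cyi = (int)std::floor(py[i] / W.Ly * W.ny);
      cyi = ((cyi % W.ny) + W.ny) % W.ny;
      int czi = (int)std::floor((zi - W.z0) / W.cell);
      czi = std::max(0, std::min(W.nz - 1, czi));
      for (int oz = -1; oz <= 1; ++oz) {
        int zc = czi + oz;
        if (zc < 0 || zc >= W.nz) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int yc = (cyi + oy + W.ny) % W.ny;
          for (int ox = -1; ox <= 1; ++ox) {
            int xc = (cxi + ox + W.nx) % W.nx;
            for (int w = W.head[(size_t)(zc * W.ny + yc) * W.nx + xc]; w >= 0;
                 w = W.nxt[w]) {
              double dx = mimg(px[i] - W.wx[w], W.Lx);
              double dy = mimg(py[i] - W.wy[w], W.Ly);
              double dz = pz[i] - W.wz[w];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= cx.wca_cut2_bw) continue;
              if (r2 < 1e-12)
                stop("singular configuration: bead %d overlaps a wall bead", i + 1);
              double fr = wca_fmag_over_r(r2, P.sbw, P.ebw, ep.wall);
              fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
            }
          }
        }
      }
    }
  }

  // reciprocal-space Coulomb + self energy
  if (cx.do_coulomb) {
    double Uk = kspace_ef2(px, py, pz, q, cx.ks, G.Lx, G.Ly, G.Lz, cx.C,
                           fx, fy, fz, true);
    double q2 = 0.0;
    for (int i = 0; i < n; ++i) q2 += q[i] * q[i];
    ep.coul = Ureal + Uk +
      cx.C * alpha / std::sqrt(M_PI) * (std::erfc(cx.ks.s_k) - 1.0) * q2;
  }

  // driving field, uniform inside the cylindrical channel: E_vec = -E zhat,
  // force on valence Z bead = Z e E_vec = -Z E zhat
  if (cx.E != 0.0) {
    for (int i = 0; i < n; ++i) {
      if (q[i] == 0.0) continue;
      double zi = pz[i];
      if (zi < G.zlo || zi > G.zhi) continue;
      double dx = mimg(px[i] - G.cx, G.Lx);
      double dy = mimg(py[i] - G.cy, G.Ly);
      if (dx * dx + dy * dy > G.prad * G.prad) continue;
      fz[i] += -q[i] * cx.E;
      ep.field += q[i] * cx.E * (zi - G.zlo);
    }
  }

  // one-way exit barrier: purely repulsive LJ plane at z = zhi, visible only
  // to monomer 1, active once armed (monomer 1 beyond WCA range on trans side)
  if (cx.barrier_armed) {
    double d = pz[0] - G.zhi; // distance above exit plane
    double cutoff = std::pow(2.0, 1.0 / 6.0) * 1.0;
    if (d > 1e-12 && d < cutoff) {
      double r2 = d * d;
      double fr = wca_fmag_over_r(r2, 1.0, 1.2, ep.barrier);
      fz[0] += fr * d; // pushes +z, away from the pore
    }
  }
}

static void unpack_state(const NumericMatrix& pos, const NumericMatrix& vel,
                         const NumericVector& charge,
                         std::vector<double>& px, std::vector<double>& py,
                         std::vector<double>& pz, std::vector<double>& vx,
                         std::vector<double>& vy, std::vector<double>& vz,
                         std::vector<double>& q) {
  int n = pos.nrow();
  px.resize(n); py.resize(n); pz.resize(n);
  vx.resize(n); vy.resize(n); vz.resize(n); q.resize(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    q[i] = charge[i];
  }
}

static ForceCtx make_ctx(const List& params, const List& geom,
                         const NumericMatrix& wall, const List& ewald,
                         double E, int n_monomer, bool do_coulomb) {
  ForceCtx cx;
  cx.p = as_pars(params);
  cx.g = as_geo(geom);
  double sixth = std::pow(2.0, 1.0 / 6.0);
  cx.wca_cut2_bb = std::pow(sixth * cx.p.sbb, 2);
  cx.wca_cut_bw = sixth * cx.p.sbw;
  cx.wca_cut2_bw = cx.wca_cut_bw * cx.wca_cut_bw;
  cx.n_monomer = n_monomer;
  cx.E = E;
  cx.barrier_armed = false;
  cx.C = cx.p.lB;
  cx.do_coulomb = do_coulomb;
  if (do_coulomb) {
    double alpha = ewald["alpha"];
    double rcut = ewald["r_cut"];
    NumericVector nk = ewald["n_k"];
    cx.ks = build_kspace(alpha, rcut, nk[0], nk[1], nk[2],
                         cx.g.Lx, cx.g.Ly, cx.g.Lz);
  } else {
    cx.ks.alpha = 1.0; cx.ks.rcut = 0.0; cx.ks.rcut2 = 0.0;
    cx.ks.s_k = 1e10;
  }
  cx.wg = build_wall_grid(wall, cx.wca_cut_bw, cx.g.Lx, cx.g.Ly);
  return cx;
}

// [[Rcpp::export(name = ".forces_cpp")]]
List forces_cpp(NumericMatrix pos, NumericVector charge,
                IntegerVector bond_from, IntegerVector bond_to,
                NumericMatrix wall, List geom, List params, List ewald,
                double E, int n_monomer, bool do_coulomb, bool barrier_armed) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), q(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); q[i] = charge[i];
  }
  std::vector<int> bf(bond_from.begin(), bond_from.end());
  std::vector<int> bt(bond_to.begin(), bond_to.end());
  ForceCtx cx = make_ctx(params, geom, wall, ewald, E, n_monomer, do_coulomb);
  cx.barrier_armed = barrier_armed;
  std::vector<double> fx(n), fy(n), fz(n);
  EnergyParts ep;
  assemble_forces(px, py, pz, q, bf, bt, cx, fx, fy, fz, true, ep);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = ep.total(),
                      _["e_pair"] = ep.pair, _["e_bond"] = ep.bond,
                      _["e_wall"] = ep.wall, _["e_coulomb"] = ep.coul,
                      _["e_field"] = ep.field, _["e_barrier"] = ep.barrier);
}

// ---------------------------------------------------------------------------
// Langevin dynamics driver: Gronbech-Jensen/Farago discretization of
//   m r'' = -zeta r' - grad U + Z e E(r) + eta,   <eta_a eta_b> = 2 kT zeta dt
// per cartesian component (i.e. <eta.eta> = 6 kT zeta per unit time).
// Reduces to velocity Verlet at zeta = 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".run_dynamics_cpp")]]
List run_dynamics_cpp(NumericMatrix pos, NumericMatrix vel,
                      NumericVector charge,
                      IntegerVector bond_from, IntegerVector bond_to,
                      NumericMatrix wall, List geom, List params, List ewald,
                      double E, int n_monomer,
                      int n_steps, double dt, double seed,
                      int frame_every, int tether,
                      bool barrier, bool detect_fp,
                      bool do_coulomb, bool record_energy) {
  const int n = pos.nrow();
  std::vector<double> px, py, pz, vx, vy, vz, q;
  unpack_state(pos, vel, charge, px, py, pz, vx, vy, vz, q);
  std::vector<int> bf(bond_from.begin(), bond_from.end());
  std::vector<int> bt(bond_to.begin(), bond_to.end());
  ForceCtx cx = make_ctx(params, geom, wall, ewald, E, n_monomer, do_coulomb);
  const Geo& G = cx.g;
  const Pars& P = cx.p;

  RNG rng((uint64_t)(seed < 0 ? -seed : seed) + 0x51u);
  const double m = P.mass;
  const double b = 1.0 / (1.0 + P.zeta * dt / (2.0 * m));
  const double a = (1.0 - P.zeta * dt / (2.0 * m)) * b;
  const double sd = std::sqrt(2.0 * P.zeta * P.T * dt);

  std::vector<double> fx(n), fy(n), fz(n), bxn(n), byn(n), bzn(n);
  EnergyParts ep;
  // arm the one-way barrier only after monomer 1 has cleared its range, so a
  // start just at the exit plane is not kicked
  const double barrier_range = std::pow(2.0, 1.0 / 6.0);
  if (barrier && pz[0] > G.zhi + barrier_range) cx.barrier_armed = true;
  assemble_forces(px, py, pz, q, bf, bt, cx, fx, fy, fz, false, ep);

  int max_frames = n_steps / std::max(frame_every, 1) + 2;
  NumericVector frame_time(max_frames);
  NumericVector frame_temp(max_frames);
  NumericVector frame_energy(record_energy ? max_frames : 1);
  std::vector<double> frames; // nf * n * 3, filled frame-major
  frames.reserve((size_t)max_frames * n * 3);
  int nf = 0;
  double tau = NA_REAL;
  bool completed = false;
  double min_z_prev = 0.0;
  if (detect_fp) {
    min_z_prev = pz[0];
    for (int i = 1; i < n_monomer; ++i) min_z_prev = std::min(min_z_prev, pz[i]);
  }

  // instantaneous temperature uses the half-step velocity u = dr/(sqrt(b) dt)
  // whose variance is exactly kT/m under the GJF discretization
  double ke_half = NA_REAL;
  int n_free = 0;
  for (int i = 0; i < n; ++i) if (i != tether) ++n_free;
  auto store_frame = [&](int step) {
    frame_time[nf] = step * dt;
    double ke_full = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i == tether) continue;
      ke_full += 0.5 * m * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    double ke_t = (step == 0 || !std::isfinite(ke_half)) ? ke_full : ke_half;
    frame_temp[nf] = n_free > 0 ? 2.0 * ke_t / (3.0 * n_free) : 0.0;
    if (record_energy) {
      EnergyParts e2;
      std::vector<double> tfx(n), tfy(n), tfz(n);
      assemble_forces(px, py, pz, q, bf, bt, cx, tfx, tfy, tfz, true, e2);
      frame_energy[nf] = e2.total() + ke_full;
    }
    for (int i = 0; i < n; ++i) {
      frames.push_back(px[i]); frames.push_back(py[i]); frames.push_back(pz[i]);
    }
    ++nf;
  };
  store_frame(0);

  int steps_done = 0;
  std::vector<double> fx2(n), fy2(n), fz2(n);
  for (int step = 1; step <= n_steps; ++step) {
    // position half of GJF
    double keh = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i == tether) { bxn[i] = byn[i] = bzn[i] = 0.0; continue; }
      double gx = sd * rng.gauss(), gy = sd * rng.gauss(), gz = sd * rng.gauss();
      bxn[i] = gx; byn[i] = gy; bzn[i] = gz;
      double ddx = b * dt * vx[i] + b * dt * dt / (2.0 * m) * fx[i] +
                   b * dt / (2.0 * m) * gx;
      double ddy = b * dt * vy[i] + b * dt * dt / (2.0 * m) * fy[i] +
                   b * dt / (2.0 * m) * gy;
      double ddz = b * dt * vz[i] + b * dt * dt / (2.0 * m) * fz[i] +
                   b * dt / (2.0 * m) * gz;
      px[i] += ddx; py[i] += ddy; pz[i] += ddz;
      keh += 0.5 * m * (ddx * ddx + ddy * ddy + ddz * ddz) / (b * dt * dt);
      // wrap into [0, L)
      px[i] -= G.Lx * std::floor(px[i] / G.Lx);
      py[i] -= G.Ly * std::floor(py[i] / G.Ly);
      pz[i] -= G.Lz * std::floor(pz[i] / G.Lz);
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
        stop("integration blew up at step %d, bead %d (dt = %g)", step, i + 1, dt);
    }
    ke_half = keh;
    if (barrier && !cx.barrier_armed && pz[0] > G.zhi + barrier_range)
      cx.barrier_armed = true;
    // new forces
    assemble_forces(px, py, pz, q, bf, bt, cx, fx2, fy2, fz2, false, ep);
    // velocity half
    for (int i = 0; i < n; ++i) {
      if (i == tether) { vx[i] = vy[i] = vz[i] = 0.0; continue; }
      vx[i] = a * vx[i] + dt / (2.0 * m) * (a * fx[i] + fx2[i]) + b / m * bxn[i];
      vy[i] = a * vy[i] + dt / (2.0 * m) * (a * fy[i] + fy2[i]) + b / m * byn[i];
      vz[i] = a * vz[i] + dt / (2.0 * m) * (a * fz[i] + fz2[i]) + b / m * bzn[i];
    }
    fx.swap(fx2); fy.swap(fy2); fz.swap(fz2);
    steps_done = step;

    if (detect_fp) {
      double mz = pz[0];
      for (int i = 1; i < n_monomer; ++i) mz = std::min(mz, pz[i]);
      if (!completed && mz > G.zhi) {
        double frac = (G.zhi - min_z_prev) / (mz - min_z_prev);
        if (!std::isfinite(frac) || frac < 0.0 || frac > 1.0) frac = 1.0;
        tau = (step - 1 + frac) * dt;
        completed = true;
        store_frame(step);
        break;
      }
      min_z_prev = mz;
    }
    if (step % std::max(frame_every, 1) == 0) store_frame(step);
  }
  if (!completed && nf > 0 && frame_time[nf - 1] < steps_done * dt &&
      steps_done > 0)
    store_frame(steps_done);

  NumericMatrix P2(n, 3), V2(n, 3);
  for (int i = 0; i < n; ++i) {
    P2(i, 0) = px[i]; P2(i, 1) = py[i]; P2(i, 2) = pz[i];
    V2(i, 0) = vx[i]; V2(i, 1) = vy[i]; V2(i, 2) = vz[i];
  }
  NumericVector fr(frames.begin(), frames.end());
  fr.attr("dim") = IntegerVector::create(3, n, nf);
  return List::create(_["pos"] = P2, _["vel"] = V2,
                      _["frames"] = fr,
                      _["frame_time"] = frame_time[Range(0, std::max(nf - 1, 0))],
                      _["frame_temp"] = frame_temp[Range(0, std::max(nf - 1, 0))],
                      _["frame_energy"] =
                          record_energy ? frame_energy[Range(0, std::max(nf - 1, 0))]
                                        : NumericVector(0),
                      _["tau"] = tau, _["completed"] = completed,
                      _["steps_done"] = steps_done);
}

// ---------------------------------------------------------------------------
// Direct lattice-sum oracle for the Ewald tests: real-space sum of the bare
// Coulomb form over all periodic images with |n| <= n_images, accumulated in
// spherical shells; the two outermost shell partial sums are averaged to damp
// the conditional-convergence oscillation. Vacuum (epsilon'=1) boundary.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".direct_sum_cpp")]]
NumericVector direct_sum_cpp(NumericMatrix pos, NumericVector charge,
                             NumericVector box, int n_images, double lambda_B) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  // shell index by |n| rounded image radius
  std::vector<double> shell(n_images + 1, 0.0);
  for (int nx = -n_images; nx <= n_images; ++nx)
    for (int ny = -n_images; ny <= n_images; ++ny)
      for (int nz = -n_images; nz <= n_images; ++nz) {
        int s2 = nx * nx + ny * ny + nz * nz;
        int s = (int)std::floor(std::sqrt((double)s2) + 0.5);
        if (s > n_images) continue;
        double ox = nx * Lx, oy = ny * Ly, oz = nz * Lz;
        double u = 0.0;
        bool home = (nx == 0 && ny == 0 && nz == 0);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j) {
            if (home && i == j) continue;
            if (home && j < i) continue; // count each home pair once
            double qq = charge[i] * charge[j];
            if (qq == 0.0) continue;
            double dx = pos(i, 0) - pos(j, 0) + ox;
            double dy = pos(i, 1) - pos(j, 1) + oy;
            double dz = pos(i, 2) - pos(j, 2) + oz;
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            double w = home ? 1.0 : 0.5; // image pairs double-counted
            u += w * lambda_B * qq / r;
          }
        shell[s] += u;
      }
  // cumulative partial sums per shell
  NumericVector partial(n_images + 1);
  double acc = 0.0;
  for (int s = 0; s <= n_images; ++s) { acc += shell[s]; partial[s] = acc; }
  return partial;
}
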