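// Coarse-grained 2D actomyosin cortex: semiflexible bead-spring filaments
// with polarity, two-headed walking motors, passive crosslinkers, filament
// turnover and (de)polymerisation, fixed walls or deformable membrane chains
// along the vertical boundaries, periodic in y. Overdamped explicit Euler
// with a self-contained xoshiro256++ RNG stream so trajectories are
// bit-reproducible for a given (params, seed) independent of R's RNG.
//
// Units: um, s, pN. 2D stress in pN/um, tensile positive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++, uniform + cached Box-Muller normals
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool haveSpare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  double norm() {  // Marsaglia polar method (no trig calls)
    if (haveSpare) { haveSpare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    haveSpare = true;
    return u * m;
  }
  int intBelow(int n) { return (int)(unif() * n) % n; }
};

// ---------------------------------------------------------------------------
// Model structures
// ---------------------------------------------------------------------------
struct Fil {
  std::vector<double> x, y;   // minus end (bead 0) -> plus end
  bool anchored = false;
  int memSide = -1;           // -1: fixed anchor point; 0/1: left/right membrane
  int memIdx = 0;             // membrane bead index (0-based)
  double ax = 0, ay = 0;      // fixed anchor point (when memSide == -1)
  int nseg() const { return (int)x.size() - 1; }
};

struct Linker {               // motor or crosslinker; head fil == -1: unbound
  int f0 = -1, f1 = -1;
  double s0 = 0, s1 = 0;
};

// virial tallies per region + pair ledger (optional)
struct Tally {
  double cxx = 0, cyy = 0, cxy = 0;    // central region
  double axx = 0, ayy = 0, axy = 0;    // whole domain
  std::vector<double> *ledger = nullptr; // rows: rx, ry, fx, fy, mx, my
};

struct Sim {
  // parameters
  double Lx, Ly, band;                       // domain + central band height
  double margin;                             // x-inset of the central region
  int boundary;                              // 0 fixed walls, 1 deformable
  double segL, kStretch, kBend;
  int minSeg, maxSeg;
  double capR, mOn, mOff, v0, fStall, kLink, linkRest;
  double xOn, xOff, kXl, xlRest, kAlign, anchorAffinity;
  double memSpacing, kMemStretch, kMemBend, kFound, memDrag;
  double polyRate, depolyRate, turnRate;
  double dt, drag, kT, kConf;
  bool noise;

  // state
  double time = 0;
  std::vector<Fil> fils;
  std::vector<Linker> motors, xls;
  std::vector<double> memY, memXL, memXR;    // membrane bead coordinates
  // work arrays
  std::vector<std::vector<double>> ffx, ffy; // filament bead forces
  std::vector<double> fmL, fmR;              // membrane bead forces (x)
  bool diverged = false;

  // binding grid over segments
  int gx_ = 0, gy_ = 0;
  double cell_ = 0.5;
  std::vector<std::vector<int>> grid;        // encoded fil * 64 + seg
  double anchorLoad = 0;                     // net inward pull on the clamps
  // per-grid-row wall cache (membranes move ~nm between grid rebuilds)
  std::vector<double> rowXL, rowXR, rowUL, rowUR;
  std::vector<int> rowJL, rowJR;

  double wrapY(double y) const {
    y -= Ly * std::floor(y / Ly);  // periodic image in [0, Ly)
    if (y >= Ly) y -= Ly;
    if (y < 0) y += Ly;
    return y;
  }
  double minImY(double dy) const {
    if (dy > 0.5 * Ly) dy -= Ly;
    else if (dy < -0.5 * Ly) dy += Ly;
    return dy;
  }
  // central region: middle y-band, inset from the walls in x (the wall
  // strips, where stiff filaments align with the boundary sterically, are
  // peripheral)
  bool inCentral(double x, double y) const {
    double yw = wrapY(y);
    double y0 = 0.5 * (Ly - band), y1 = 0.5 * (Ly + band);
    return yw >= y0 && yw <= y1 && x >= margin && x <= Lx - margin;
  }

  // membrane wall x-position at (wrapped) y, by linear interpolation
  double wallX(int side, double y, int *j0 = nullptr, double *u = nullptr) const {
    if (boundary == 0) { if (j0) *j0 = -1; return side == 0 ? 0.0 : Lx; }
    const std::vector<double> &mx = (side == 0) ? memXL : memXR;
    double yw = wrapY(y);
    double p = yw / memSpacing;
    int j = (int)p;
    if (j >= (int)mx.size() - 1) j = (int)mx.size() - 2;
    double uu = p - j;
    if (j0) { *j0 = j; *u = uu; }
    return mx[j] * (1 - uu) + mx[j + 1] * uu;
  }

  // position/tangent at arc position s (rest-length parametrisation)
  void pointOn(const Fil &f, double s, double &px, double &py,
               double &tx, double &ty, int &iseg, double &u) const {
    int ns = f.nseg();
    double p = s / segL;
    iseg = (int)p;
    if (iseg >= ns) { iseg = ns - 1; p = ns; }
    if (iseg < 0) iseg = 0;
    u = p - iseg;
    if (u < 0) u = 0;
    if (u > 1) u = 1;
    px = f.x[iseg] * (1 - u) + f.x[iseg + 1] * u;
    py = f.y[iseg] * (1 - u) + f.y[iseg + 1] * u;
    double dx = f.x[iseg + 1] - f.x[iseg], dy = f.y[iseg + 1] - f.y[iseg];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) { tx = 1; ty = 0; } else { tx = dx / r; ty = dy / r; }
  }

  // pair contribution: (f2x, f2y) is the force on particle 2; r = r1 - r2
  // (minimum image in y). Tensile springs give positive diagonal stress.
  void addPair(Tally *t, double x1, double y1, double x2, double y2,
               double f2x, double f2y) {
    if (!t) return;
    double rx = x1 - x2, ry = minImY(y1 - y2);
    double mx = 0.5 * (x1 + x2), my = wrapY(y2 + 0.5 * ry);
    double sxx = f2x * rx, syy = f2y * ry;
    double sxy = 0.5 * (f2x * ry + f2y * rx);
    t->axx += sxx; t->ayy += syy; t->axy += sxy;
    if (inCentral(mx, my)) {
      t->cxx += sxx; t->cyy += syy; t->cxy += sxy;
    }
    if (t->ledger) {
      t->ledger->push_back(rx); t->ledger->push_back(ry);
      t->ledger->push_back(f2x); t->ledger->push_back(f2y);
      t->ledger->push_back(mx); t->ledger->push_back(my);
    }
  }

  // -------------------------------------------------------------------------
  // Forces (fills ffx/ffy/fmL/fmR); optional virial tally / ledger
  // -------------------------------------------------------------------------
  void forces(Tally *t) {
    size_t nf = fils.size();
    ffx.resize(nf); ffy.resize(nf);
    for (size_t i = 0; i < nf; ++i) {
      ffx[i].assign(fils[i].x.size(), 0.0);
      ffy[i].assign(fils[i].x.size(), 0.0);
    }
    fmL.assign(memXL.size(), 0.0);
    fmR.assign(memXR.size(), 0.0);

    // per-filament scratch: segment tangents computed once, shared by the
    // stretch and bending terms
    std::vector<double> tx_, ty_, ln_;
    for (size_t fi = 0; fi < nf; ++fi) {
      Fil &f = fils[fi];
      int ns = f.nseg();
      tx_.resize(ns); ty_.resize(ns); ln_.resize(ns);
      for (int i = 0; i < ns; ++i) {
        double dx = f.x[i + 1] - f.x[i], dy = f.y[i + 1] - f.y[i];
        double r = std::sqrt(dx * dx + dy * dy);
        ln_[i] = r;
        if (r < 1e-12) { tx_[i] = 1; ty_[i] = 0; continue; }
        tx_[i] = dx / r; ty_[i] = dy / r;
        double fmag = kStretch * (r - segL);   // > 0 when stretched
        double fx = -fmag * tx_[i], fy = -fmag * ty_[i]; // force on bead i+1
        ffx[fi][i + 1] += fx; ffy[fi][i + 1] += fy;
        ffx[fi][i] -= fx; ffy[fi][i] -= fy;
        addPair(t, f.x[i], f.y[i], f.x[i + 1], f.y[i + 1], fx, fy);
      }
      // bending: E = (kBend/segL) * (1 - t1.t2) per interior bead
      double A = kBend / segL;
      for (int i = 1; i < ns; ++i) {
        double l1 = ln_[i - 1], l2 = ln_[i];
        if (l1 < 1e-12 || l2 < 1e-12) continue;
        double t1x = tx_[i - 1], t1y = ty_[i - 1];
        double t2x = tx_[i], t2y = ty_[i];
        double c = t1x * t2x + t1y * t2y;
        // force on bead i+1 and on bead i-1 (central bead gets the rest)
        double fpx = A * (t1x - c * t2x) / l2, fpy = A * (t1y - c * t2y) / l2;
        double fmx = -A * (t2x - c * t1x) / l1, fmy = -A * (t2y - c * t1y) / l1;
        ffx[fi][i + 1] += fpx; ffy[fi][i + 1] += fpy;
        ffx[fi][i - 1] += fmx; ffy[fi][i - 1] += fmy;
        ffx[fi][i] -= fpx + fmx; ffy[fi][i] -= fpy + fmy;
        addPair(t, f.x[i], f.y[i], f.x[i + 1], f.y[i + 1], fpx, fpy);
        addPair(t, f.x[i], f.y[i], f.x[i - 1], f.y[i - 1], fmx, fmy);
      }
    }

    // motor / crosslinker link springs (both heads bound); crosslinkers
    // additionally carry a nematic aligning stiffness (parallel bundler)
    linkForces(motors, kLink, linkRest, 0.0, t);
    linkForces(xls, kXl, xlRest, kAlign, t);

    // membranes
    if (boundary == 1) {
      memForces(memXL, fmL, 0.0, t);
      memForces(memXR, fmR, Lx, t);
    }

    // anchored-filament clamp: the base segment at the plus end (the last
    // two beads, sarcomere-like plus-end anchorage) is held rigidly, fixing
    // both position and orientation of the anchor root; x-forces on the
    // clamped beads are transferred to the carrying membrane bead (or
    // discarded at a fixed anchor, where they are external).
    anchorLoad = 0;
    for (size_t fi = 0; fi < nf; ++fi) {
      Fil &f = fils[fi];
      if (!f.anchored) continue;
      size_t nb = f.x.size();
      // inward component of the pull on the clamp, along the anchor axis
      double axn = f.x[0] - f.x[nb - 1], ayn = f.y[0] - f.y[nb - 1];
      double an = std::sqrt(axn * axn + ayn * ayn);
      if (an > 1e-12)
        anchorLoad += (ffx[fi][nb - 1] + ffx[fi][nb - 2]) * axn / an +
                      (ffy[fi][nb - 1] + ffy[fi][nb - 2]) * ayn / an;
      if (boundary == 1 && f.memSide >= 0) {
        std::vector<double> &fm = (f.memSide == 0) ? fmL : fmR;
        if (f.memIdx >= 0 && f.memIdx < (int)fm.size())
          fm[f.memIdx] += ffx[fi][nb - 1] + ffx[fi][nb - 2];
      }
      ffx[fi][nb - 1] = 0; ffy[fi][nb - 1] = 0;
      ffx[fi][nb - 2] = 0; ffy[fi][nb - 2] = 0;
    }

    // confinement between the walls (soft springs; reaction on the
    // membrane). Wall positions come from the per-row cache: membranes
    // move nanometres between cache refreshes.
    if (rowXL.empty()) rebuildGrid();
    for (size_t fi = 0; fi < nf; ++fi) {
      Fil &f = fils[fi];
      for (size_t b = 0; b < f.x.size(); ++b) {
        if (f.anchored && b == 0) continue;
        int cy = (int)(wrapY(f.y[b]) / cell_);
        if (cy >= gy_) cy = gy_ - 1;
        double xl = rowXL[cy], xr = rowXR[cy];
        if (f.x[b] >= xl && f.x[b] <= xr) continue;
        if (f.x[b] < xl) {
          double fc = kConf * (xl - f.x[b]);   // push bead in +x
          ffx[fi][b] += fc;
          if (boundary == 1 && rowJL[cy] >= 0) {
            fmL[rowJL[cy]] -= fc * (1 - rowUL[cy]);
            fmL[rowJL[cy] + 1] -= fc * rowUL[cy];
          }
          addPair(t, xl, f.y[b], f.x[b], f.y[b], fc, 0.0);
        } else {
          double fc = kConf * (xr - f.x[b]);   // negative: push in -x
          ffx[fi][b] += fc;
          if (boundary == 1 && rowJR[cy] >= 0) {
            fmR[rowJR[cy]] -= fc * (1 - rowUR[cy]);
            fmR[rowJR[cy] + 1] -= fc * rowUR[cy];
          }
          addPair(t, xr, f.y[b], f.x[b], f.y[b], fc, 0.0);
        }
      }
    }
  }

  void linkForces(std::vector<Linker> &ls, double k, double rest,
                  double kAli, Tally *t) {
    for (Linker &l : ls) {
      if (l.f0 < 0 || l.f1 < 0) continue;
      double p0x, p0y, p1x, p1y, tx, ty, u0, u1;
      int i0, i1;
      pointOn(fils[l.f0], l.s0, p0x, p0y, tx, ty, i0, u0);
      pointOn(fils[l.f1], l.s1, p1x, p1y, tx, ty, i1, u1);
      double dx = p0x - p1x, dy = minImY(p0y - p1y);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < 1e-12) continue;
      double fmag = k * (r - rest);
      double fx = fmag * dx / r, fy = fmag * dy / r;  // force on head 1
      ffx[l.f0][i0] -= fx * (1 - u0); ffy[l.f0][i0] -= fy * (1 - u0);
      ffx[l.f0][i0 + 1] -= fx * u0; ffy[l.f0][i0 + 1] -= fy * u0;
      ffx[l.f1][i1] += fx * (1 - u1); ffy[l.f1][i1] += fy * (1 - u1);
      ffx[l.f1][i1 + 1] += fx * u1; ffy[l.f1][i1 + 1] += fy * u1;
      addPair(t, p0x, p0y, p1x, p1y, fx, fy);
      if (kAli > 0) alignForces(l, i0, i1, kAli, t);
    }
  }

  // nematic aligning interaction of a doubly-bound crosslinker:
  // E = kAli * (1 - (t0.t1)^2) on the two host segments. Forces are
  // equal-and-opposite within each segment, so momentum and total torque
  // are conserved and the pair ledger stays two-body.
  void alignForces(const Linker &l, int i0, int i1, double kAli, Tally *t) {
    Fil &f0 = fils[l.f0], &f1 = fils[l.f1];
    double ax = f0.x[i0], ay = f0.y[i0];
    double bx = f0.x[i0 + 1], by = f0.y[i0 + 1];
    double cx2 = f1.x[i1], cy2 = f1.y[i1];
    double dx2 = f1.x[i1 + 1], dy2 = f1.y[i1 + 1];
    double v0x = bx - ax, v0y = by - ay;
    double v1x = dx2 - cx2, v1y = dy2 - cy2;
    double L0 = std::sqrt(v0x * v0x + v0y * v0y);
    double L1 = std::sqrt(v1x * v1x + v1y * v1y);
    if (L0 < 1e-12 || L1 < 1e-12) return;
    double t0x = v0x / L0, t0y = v0y / L0;
    double t1x = v1x / L1, t1y = v1y / L1;
    double c = t0x * t1x + t0y * t1y;
    // F_b = 2 kAli c (t1 - c t0)/L0, F_a = -F_b (and symmetrically for d,c)
    double fbx = 2 * kAli * c * (t1x - c * t0x) / L0;
    double fby = 2 * kAli * c * (t1y - c * t0y) / L0;
    double fdx = 2 * kAli * c * (t0x - c * t1x) / L1;
    double fdy = 2 * kAli * c * (t0y - c * t1y) / L1;
    ffx[l.f0][i0 + 1] += fbx; ffy[l.f0][i0 + 1] += fby;
    ffx[l.f0][i0] -= fbx; ffy[l.f0][i0] -= fby;
    ffx[l.f1][i1 + 1] += fdx; ffy[l.f1][i1 + 1] += fdy;
    ffx[l.f1][i1] -= fdx; ffy[l.f1][i1] -= fdy;
    addPair(t, ax, ay, bx, by, fbx, fby);
    addPair(t, cx2, cy2, dx2, dy2, fdx, fdy);
  }

  void memForces(std::vector<double> &mx, std::vector<double> &fm,
                 double xRest, Tally *t) {
    int n = (int)mx.size();
    // stretch along the chain (y spacing fixed)
    for (int j = 0; j + 1 < n; ++j) {
      double dx = mx[j] - mx[j + 1];
      double r = std::sqrt(dx * dx + memSpacing * memSpacing);
      double fmag = kMemStretch * (r - memSpacing);
      double fx = fmag * dx / r;                  // x-force on bead j+1
      fm[j + 1] += fx; fm[j] -= fx;
      addPair(t, mx[j], memY[j], mx[j + 1], memY[j + 1], fx,
              fmag * memSpacing / r);
    }
    // bending (fourth-difference from squared second differences)
    double B = kMemBend / (memSpacing * memSpacing * memSpacing);
    for (int j = 1; j + 1 < n; ++j) {
      double u = mx[j - 1] - 2 * mx[j] + mx[j + 1];
      fm[j - 1] -= B * u; fm[j + 1] -= B * u; fm[j] += 2 * B * u;
      addPair(t, mx[j], memY[j], mx[j - 1], memY[j - 1], -B * u, 0.0);
      addPair(t, mx[j], memY[j], mx[j + 1], memY[j + 1], -B * u, 0.0);
    }
    // elastic foundation toward the rest line
    for (int j = 0; j < n; ++j) {
      double fx = -kFound * (mx[j] - xRest);
      fm[j] += fx;
      addPair(t, xRest, memY[j], mx[j], memY[j], fx, 0.0);
    }
  }

  double energy() const {
    double E = 0;
    for (const Fil &f : fils) {
      int ns = f.nseg();
      for (int i = 0; i < ns; ++i) {
        double dx = f.x[i + 1] - f.x[i], dy = f.y[i + 1] - f.y[i];
        double r = std::sqrt(dx * dx + dy * dy);
        E += 0.5 * kStretch * (r - segL) * (r - segL);
      }
      double A = kBend / segL;
      for (int i = 1; i < ns; ++i) {
        double r1x = f.x[i] - f.x[i - 1], r1y = f.y[i] - f.y[i - 1];
        double r2x = f.x[i + 1] - f.x[i], r2y = f.y[i + 1] - f.y[i];
        double l1 = std::sqrt(r1x * r1x + r1y * r1y);
        double l2 = std::sqrt(r2x * r2x + r2y * r2y);
        if (l1 < 1e-12 || l2 < 1e-12) continue;
        E += A * (1 - (r1x * r2x + r1y * r2y) / (l1 * l2));
      }
    }
    E += linkEnergy(motors, kLink, linkRest, 0.0);
    E += linkEnergy(xls, kXl, xlRest, kAlign);
    if (boundary == 1) {
      E += memEnergy(memXL, 0.0);
      E += memEnergy(memXR, Lx);
    }
    // confinement
    for (const Fil &f : fils)
      for (size_t b = 0; b < f.x.size(); ++b) {
        double xl = wallX(0, f.y[b]), xr = wallX(1, f.y[b]);
        if (f.x[b] < xl) E += 0.5 * kConf * (xl - f.x[b]) * (xl - f.x[b]);
        if (f.x[b] > xr) E += 0.5 * kConf * (f.x[b] - xr) * (f.x[b] - xr);
      }
    return E;
  }

  double linkEnergy(const std::vector<Linker> &ls, double k, double rest,
                    double kAli) const {
    double E = 0;
    for (const Linker &l : ls) {
      if (l.f0 < 0 || l.f1 < 0) continue;
      double p0x, p0y, t0x, t0y, p1x, p1y, t1x, t1y, u;
      int i;
      pointOn(fils[l.f0], l.s0, p0x, p0y, t0x, t0y, i, u);
      pointOn(fils[l.f1], l.s1, p1x, p1y, t1x, t1y, i, u);
      double dx = p0x - p1x, dy = minImY(p0y - p1y);
      double r = std::sqrt(dx * dx + dy * dy);
      E += 0.5 * k * (r - rest) * (r - rest);
      if (kAli > 0) {
        double c = t0x * t1x + t0y * t1y;
        E += kAli * (1 - c * c);
      }
    }
    return E;
  }

  double memEnergy(const std::vector<double> &mx, double xRest) const {
    double E = 0;
    int n = (int)mx.size();
    for (int j = 0; j + 1 < n; ++j) {
      double dx = mx[j] - mx[j + 1];
      double r = std::sqrt(dx * dx + memSpacing * memSpacing);
      E += 0.5 * kMemStretch * (r - memSpacing) * (r - memSpacing);
    }
    double B = kMemBend / (memSpacing * memSpacing * memSpacing);
    for (int j = 1; j + 1 < n; ++j) {
      double u = mx[j - 1] - 2 * mx[j] + mx[j + 1];
      E += 0.5 * B * u * u;
    }
    for (int j = 0; j < n; ++j)
      E += 0.5 * kFound * (mx[j] - xRest) * (mx[j] - xRest);
    return E;
  }

  // -------------------------------------------------------------------------
  // Kinetics
  // -------------------------------------------------------------------------
  void rebuildGrid() {
    cell_ = 0.5;
    gx_ = std::max(1, (int)std::ceil(Lx / cell_));
    gy_ = std::max(1, (int)std::ceil(Ly / cell_));
    grid.assign((size_t)gx_ * gy_, {});
    rowXL.assign(gy_, 0.0); rowXR.assign(gy_, Lx);
    rowUL.assign(gy_, 0.0); rowUR.assign(gy_, 0.0);
    rowJL.assign(gy_, -1); rowJR.assign(gy_, -1);
    for (int cy = 0; cy < gy_; ++cy) {
      double y = (cy + 0.5) * cell_;
      int j; double u;
      rowXL[cy] = wallX(0, y, &j, &u); rowJL[cy] = j; rowUL[cy] = u;
      rowXR[cy] = wallX(1, y, &j, &u); rowJR[cy] = j; rowUR[cy] = u;
    }
    for (size_t fi = 0; fi < fils.size(); ++fi) {
      const Fil &f = fils[fi];
      for (int i = 0; i < f.nseg(); ++i) {
        double mx = 0.5 * (f.x[i] + f.x[i + 1]);
        double my = wrapY(0.5 * (f.y[i] + f.y[i + 1]));
        int cx = std::min(gx_ - 1, std::max(0, (int)(mx / cell_)));
        int cy = std::min(gy_ - 1, (int)(my / cell_));
        grid[(size_t)cy * gx_ + cx].push_back((int)fi * 64 + i);
      }
    }
  }

  // closest segment point within capR of (px, py), excluding filament `self`
  bool findBindingSite(double px, double py, int self, Rng &rng,
                       int &filOut, double &sOut) {
    int cx = std::max(0, std::min(gx_ - 1, (int)(px / cell_)));
    int cy = (int)(wrapY(py) / cell_);
    int bestFil = -1; double bestS = 0, bestD = capR;
    for (int dyc = -1; dyc <= 1; ++dyc) {
      int yy = (cy + dyc + gy_) % gy_;
      for (int dxc = -1; dxc <= 1; ++dxc) {
        int xx = cx + dxc;
        if (xx < 0 || xx >= gx_) continue;
        for (int code : grid[(size_t)yy * gx_ + xx]) {
          int fi = code / 64, seg = code % 64;
          if (fi == self) continue;
          const Fil &f = fils[fi];
          if (seg >= f.nseg()) continue;
          double ax = f.x[seg], ay = f.y[seg];
          double bx = f.x[seg + 1], by = f.y[seg + 1];
          double vx = bx - ax, vy = by - ay;
          double dx = px - ax, dy = minImY(py - ay);
          double vv = vx * vx + vy * vy;
          double u = vv > 1e-12 ? (dx * vx + dy * vy) / vv : 0.0;
          if (u < 0) u = 0;
          if (u > 1) u = 1;
          double ex = dx - u * vx, ey = dy - u * vy;
          double d = std::sqrt(ex * ex + ey * ey);
          if (d < bestD) {
            bestD = d; bestFil = fi; bestS = (seg + u) * segL;
          }
        }
      }
    }
    if (bestFil < 0) return false;
    filOut = bestFil; sOut = bestS;
    return true;
  }

  void linkKinetics(std::vector<Linker> &ls, double onRate, double offRate,
                    bool isMotor, Rng &rng, double dtK) {
    double pOn = 1 - std::exp(-onRate * dtK);
    double pOff = 1 - std::exp(-offRate * dtK);
    // well-mixed first-head binding, weighted: anchored filaments bind with
    // higher affinity (junction-anchored bundling scaffolds)
    double totW = 0;
    for (const Fil &f : fils)
      totW += f.nseg() * (f.anchored ? anchorAffinity : 1.0);
    for (Linker &l : ls) {
      // unbinding first (fixed event order)
      if (l.f0 >= 0 && rng.unif() < pOff) l.f0 = -1;
      if (l.f1 >= 0 && rng.unif() < pOff) l.f1 = -1;
      if (l.f0 < 0 && l.f1 >= 0) { l.f0 = l.f1; l.s0 = l.s1; l.f1 = -1; }
      if (l.f0 < 0) {
        // fully unbound: implicit-diffusion reservoir, binds uniformly on
        // the network at the on-rate
        if (rng.unif() < pOn) {
          double pick = rng.unif() * totW;
          for (size_t fi = 0; fi < fils.size(); ++fi) {
            double w = fils[fi].nseg() *
              (fils[fi].anchored ? anchorAffinity : 1.0);
            if (pick < w) {
              l.f0 = (int)fi;
              l.s0 = (pick / w) * fils[fi].nseg() * segL;
              break;
            }
            pick -= w;
          }
        }
      } else if (l.f1 < 0) {
        // second head searches within the capture radius of the bound head
        if (rng.unif() < pOn) {
          double px, py, tx, ty, u;
          int i;
          pointOn(fils[l.f0], l.s0, px, py, tx, ty, i, u);
          int fi; double s;
          if (findBindingSite(px, py, l.f0, rng, fi, s)) {
            l.f1 = fi; l.s1 = s;
          }
        }
      }
      // motor stepping toward the plus end with linear force-velocity
      if (isMotor) {
        for (int h = 0; h < 2; ++h) {
          int fi = (h == 0) ? l.f0 : l.f1;
          if (fi < 0) continue;
          double s = (h == 0) ? l.s0 : l.s1;
          double v = v0;
          int oi = (h == 0) ? l.f1 : l.f0;
          if (oi >= 0) {  // load from the link spring, projected on tangent
            double px, py, tx, ty, ox, oy, otx, oty, u;
            int i;
            pointOn(fils[fi], s, px, py, tx, ty, i, u);
            double so = (h == 0) ? l.s1 : l.s0;
            pointOn(fils[oi], so, ox, oy, otx, oty, i, u);
            double dx = ox - px, dy = minImY(oy - py);
            double r = std::sqrt(dx * dx + dy * dy);
            if (r > 1e-12) {
              double fmag = kLink * (r - linkRest);
              double fpar = fmag * (dx * tx + dy * ty) / r; // + = toward plus
              if (fpar < 0) {
                v = v0 * std::max(0.0, 1.0 + fpar / fStall);
              }
            }
          }
          s += v * dtK;
          double Lf = fils[fi].nseg() * segL;
          if (s >= Lf) {  // detach at the plus end
            if (h == 0) l.f0 = -1; else l.f1 = -1;
          } else {
            if (h == 0) l.s0 = s; else l.s1 = s;
          }
        }
        if (l.f0 < 0 && l.f1 >= 0) { l.f0 = l.f1; l.s0 = l.s1; l.f1 = -1; }
      }
    }
  }

  void detachHeadsOn(int fi) {
    for (std::vector<Linker> *ls : {&motors, &xls})
      for (Linker &l : *ls) {
        if (l.f0 == fi) { l.f0 = -1; }
        if (l.f1 == fi) { l.f1 = -1; }
        if (l.f0 < 0 && l.f1 >= 0) { l.f0 = l.f1; l.s0 = l.s1; l.f1 = -1; }
      }
  }

  void shiftHeadsOn(int fi, double ds) {
    for (std::vector<Linker> *ls : {&motors, &xls})
      for (Linker &l : *ls) {
        if (l.f0 == fi) { l.s0 += ds; if (l.s0 < 0) l.f0 = -1; }
        if (l.f1 == fi) { l.s1 += ds; if (l.s1 < 0) l.f1 = -1; }
        if (l.f0 < 0 && l.f1 >= 0) { l.f0 = l.f1; l.s0 = l.s1; l.f1 = -1; }
      }
  }

  void filamentKinetics(Rng &rng, double dtK) {
    double pPoly = 1 - std::exp(-polyRate * dtK);
    double pDepoly = 1 - std::exp(-depolyRate * dtK);
    double pTurn = 1 - std::exp(-turnRate * dtK);
    for (size_t fi = 0; fi < fils.size(); ++fi) {
      Fil &f = fils[fi];
      if (f.anchored) continue;  // anchored scaffolds are static in length
      // whole-filament turnover: delete + re-insert (atomic, count conserved)
      if (rng.unif() < pTurn) {
        int ns = minSeg + rng.intBelow(maxSeg - minSeg + 1);
        placeRandom(f, ns, rng);
        detachHeadsOn((int)fi);
        continue;
      }
      // plus-end polymerisation
      if (f.nseg() < maxSeg && rng.unif() < pPoly) {
        int n = (int)f.x.size();
        double tx = f.x[n - 1] - f.x[n - 2], ty = f.y[n - 1] - f.y[n - 2];
        double r = std::sqrt(tx * tx + ty * ty);
        if (r > 1e-12) {
          double nx = f.x[n - 1] + segL * tx / r;
          double nyy = f.y[n - 1] + segL * ty / r;
          if (nx > 0.2 && nx < Lx - 0.2) { f.x.push_back(nx); f.y.push_back(nyy); }
        }
      }
      // minus-end depolymerisation
      if (f.nseg() > minSeg && rng.unif() < pDepoly) {
        f.x.erase(f.x.begin());
        f.y.erase(f.y.begin());
        shiftHeadsOn((int)fi, -segL);
      }
    }
  }

  void placeRandom(Fil &f, int ns, Rng &rng) {
    for (int attempt = 0; attempt < 64; ++attempt) {
      double cx = 0.5 + rng.unif() * (Lx - 1.0);
      double cy = rng.unif() * Ly;
      double th = rng.unif() * 2 * M_PI;
      double hx = 0.5 * ns * segL * std::cos(th);
      if (cx - std::fabs(hx) < 0.1 || cx + std::fabs(hx) > Lx - 0.1)
        continue;  // keep inside the walls in x
      f.x.assign(ns + 1, 0.0); f.y.assign(ns + 1, 0.0);
      for (int i = 0; i <= ns; ++i) {
        double s = (i - 0.5 * ns) * segL;
        f.x[i] = cx + s * std::cos(th);
        f.y[i] = cy + s * std::sin(th);
      }
      return;
    }
    // fall back: vertical placement always fits
    double cx = 0.5 + rng.unif() * (Lx - 1.0);
    double cy = rng.unif() * Ly;
    f.x.assign(ns + 1, cx); f.y.assign(ns + 1, 0.0);
    for (int i = 0; i <= ns; ++i) f.y[i] = cy + (i - 0.5 * ns) * segL;
  }

  // -------------------------------------------------------------------------
  // One explicit-Euler step: forces -> motion -> kinetics (fixed order)
  // -------------------------------------------------------------------------
  void step(Rng &rng, Tally *tally, int stepIdx) {
    forces(tally);
    double amp = noise ? std::sqrt(2 * kT * dt / drag) : 0.0;
    double maxDisp = 0;
    for (size_t fi = 0; fi < fils.size(); ++fi) {
      Fil &f = fils[fi];
      // clamped plus-end base segment of anchored filaments does not move
      size_t bEnd = f.anchored ? f.x.size() - 2 : f.x.size();
      for (size_t b = 0; b < bEnd; ++b) {
        double dx = ffx[fi][b] * dt / drag;
        double dy = ffy[fi][b] * dt / drag;
        double d2 = dx * dx + dy * dy;
        // displacement limiter: transient stiff clusters (many links on one
        // bead) are slowed instead of exploding; inactive in normal motion
        double cap = 0.2 * segL;
        if (d2 > cap * cap) {
          double sc = cap / std::sqrt(d2);
          dx *= sc; dy *= sc; d2 = cap * cap;
        }
        if (d2 > maxDisp) maxDisp = d2;
        f.x[b] += dx + amp * rng.norm();
        f.y[b] += dy + amp * rng.norm();
        if (boundary == 0) {  // hard clamp at the fixed walls
          if (f.x[b] < 0) f.x[b] = 0;
          if (f.x[b] > Lx) f.x[b] = Lx;
        }
      }
      if (f.anchored) {  // rigid clamp: plus-end base follows the anchor
        size_t nb = f.x.size();
        if (f.memSide < 0) {
          double ddx = f.ax - f.x[nb - 1], ddy = f.ay - f.y[nb - 1];
          f.x[nb - 1] += ddx; f.y[nb - 1] += ddy;
          f.x[nb - 2] += ddx; f.y[nb - 2] += ddy;
        } else {
          const std::vector<double> &mx = (f.memSide == 0) ? memXL : memXR;
          double ddx = mx[f.memIdx] - f.x[nb - 1];
          f.x[nb - 1] += ddx; f.x[nb - 2] += ddx;
        }
      }
      // re-wrap whole filament by its centroid (keeps internal geometry)
      double cy = 0;
      for (double yy : f.y) cy += yy;
      cy /= f.y.size();
      if (cy < 0) for (double &yy : f.y) yy += Ly;
      else if (cy >= Ly) for (double &yy : f.y) yy -= Ly;
    }
    if (boundary == 1) {
      int n = (int)memXL.size();
      for (int j = 1; j + 1 < n; ++j) {  // endpoints pinned
        memXL[j] += fmL[j] * dt / memDrag;
        memXR[j] += fmR[j] * dt / memDrag;
      }
    }
    if (maxDisp > segL * segL) { diverged = true; return; }
    // stochastic kinetics on a coarser interval (operator splitting): beads
    // move < 2 nm per dt, so evaluating binding/stepping every 8 steps with
    // rates scaled accordingly is an excellent approximation and saves time
    const int KIN = 8;
    if (stepIdx % KIN == 0) {
      double dtK = KIN * dt;
      if (stepIdx % 24 == 0) rebuildGrid();
      linkKinetics(motors, mOn, mOff, true, rng, dtK);
      linkKinetics(xls, xOn, xOff, false, rng, dtK);
      filamentKinetics(rng, dtK);
    }
    time += dt;
  }

  // -------------------------------------------------------------------------
  // Readouts
  // -------------------------------------------------------------------------
  void alignment(double &nx2c, double &sc, double &nx2p, double &sp) const {
    nx2c = sc = nx2p = sp = 0;
    for (const Fil &f : fils)
      for (int i = 0; i < f.nseg(); ++i) {
        double dx = f.x[i + 1] - f.x[i], dy = f.y[i + 1] - f.y[i];
        double r2 = dx * dx + dy * dy;
        if (r2 < 1e-24) continue;
        double nx2 = dx * dx / r2;
        double mx = 0.5 * (f.x[i] + f.x[i + 1]);
        double my = 0.5 * (f.y[i] + f.y[i + 1]);
        if (inCentral(mx, my)) { nx2c += nx2; sc += 1; }
        else { nx2p += nx2; sp += 1; }
      }
  }

  double widthCentral() const {
    if (boundary == 0) return Lx;
    double y0 = 0.5 * (Ly - band), y1 = 0.5 * (Ly + band);
    double acc = 0; int n = 0;
    for (size_t j = 0; j < memY.size(); ++j)
      if (memY[j] >= y0 && memY[j] <= y1) { acc += memXR[j] - memXL[j]; ++n; }
    return n > 0 ? acc / n : Lx;
  }

  double widthAll() const {
    if (boundary == 0) return Lx;
    double acc = 0;
    for (size_t j = 0; j < memY.size(); ++j) acc += memXR[j] - memXL[j];
    return acc / memY.size();
  }
};

// ---------------------------------------------------------------------------
// R <-> C++ conversion
// ---------------------------------------------------------------------------
static Sim fromR(List state, List params) {
  Sim s;
  s.Lx = as<double>(params["Lx"]); s.Ly = as<double>(params["Ly"]);
  s.band = as<double>(params["centralBand"]);
  s.margin = as<double>(params["centralMargin"]);
  s.boundary = as<int>(params["boundary"]);
  s.segL = as<double>(params["segL"]);
  s.kStretch = as<double>(params["kStretch"]);
  s.kBend = as<double>(params["kBend"]);
  s.minSeg = as<int>(params["minSeg"]); s.maxSeg = as<int>(params["maxSeg"]);
  s.capR = as<double>(params["capR"]);
  s.mOn = as<double>(params["mOn"]); s.mOff = as<double>(params["mOff"]);
  s.v0 = as<double>(params["v0"]); s.fStall = as<double>(params["fStall"]);
  s.kLink = as<double>(params["kLink"]);
  s.linkRest = as<double>(params["linkRest"]);
  s.xOn = as<double>(params["xOn"]); s.xOff = as<double>(params["xOff"]);
  s.kXl = as<double>(params["kXl"]); s.xlRest = as<double>(params["xlRest"]);
  s.kAlign = as<double>(params["kAlign"]);
  s.anchorAffinity = as<double>(params["anchorAffinity"]);
  s.memSpacing = as<double>(params["memSpacing"]);
  s.kMemStretch = as<double>(params["kMemStretch"]);
  s.kMemBend = as<double>(params["kMemBend"]);
  s.kFound = as<double>(params["kFound"]);
  s.memDrag = as<double>(params["memDrag"]);
  s.polyRate = as<double>(params["polyRate"]);
  s.depolyRate = as<double>(params["depolyRate"]);
  s.turnRate = as<double>(params["turnRate"]);
  s.dt = as<double>(params["dt"]); s.drag = as<double>(params["drag"]);
  s.kT = as<double>(params["kT"]); s.kConf = as<double>(params["kConf"]);
  s.noise = as<bool>(params["noise"]);

  s.time = as<double>(state["time"]);
  List rf = state["filaments"];
  for (int i = 0; i < rf.size(); ++i) {
    List lf = rf[i];
    NumericMatrix b = lf["beads"];
    Fil f;
    f.x.resize(b.nrow()); f.y.resize(b.nrow());
    for (int j = 0; j < b.nrow(); ++j) { f.x[j] = b(j, 0); f.y[j] = b(j, 1); }
    f.anchored = as<bool>(lf["anchored"]);
    if (f.anchored) {
      f.memSide = as<int>(lf["memSide"]);
      f.memIdx = as<int>(lf["memIdx"]) - 1;  // R is 1-based
      NumericVector a = lf["anchor"];
      f.ax = a[0]; f.ay = a[1];
    }
    s.fils.push_back(std::move(f));
  }
  auto readLinkers = [&](NumericMatrix m) {
    std::vector<Linker> out;
    for (int i = 0; i < m.nrow(); ++i) {
      Linker l;
      l.f0 = (int)m(i, 0) - 1; l.s0 = m(i, 1);
      l.f1 = (int)m(i, 2) - 1; l.s1 = m(i, 3);
      out.push_back(l);
    }
    return out;
  };
  s.motors = readLinkers(as<NumericMatrix>(state["motors"]));
  s.xls = readLinkers(as<NumericMatrix>(state["crosslinkers"]));
  List mem = state["membranes"];
  if (mem.size() > 0) {
    s.memY = as<std::vector<double>>(mem["y"]);
    s.memXL = as<std::vector<double>>(mem["left"]);
    s.memXR = as<std::vector<double>>(mem["right"]);
  }
  s.rebuildGrid();
  return s;
}

static List toR(const Sim &s) {
  List rf(s.fils.size());
  for (size_t i = 0; i < s.fils.size(); ++i) {
    const Fil &f = s.fils[i];
    NumericMatrix b((int)f.x.size(), 2);
    for (size_t j = 0; j < f.x.size(); ++j) { b(j, 0) = f.x[j]; b(j, 1) = f.y[j]; }
    rf[i] = List::create(_["beads"] = b, _["anchored"] = f.anchored,
                         _["memSide"] = f.memSide,
                         _["memIdx"] = f.memIdx + 1,
                         _["anchor"] = NumericVector::create(f.ax, f.ay));
  }
  auto writeLinkers = [](const std::vector<Linker> &ls) {
    NumericMatrix m((int)ls.size(), 4);
    for (size_t i = 0; i < ls.size(); ++i) {
      m(i, 0) = ls[i].f0 + 1; m(i, 1) = ls[i].s0;
      m(i, 2) = ls[i].f1 + 1; m(i, 3) = ls[i].s1;
    }
    colnames(m) = CharacterVector::create("f1", "s1", "f2", "s2");
    return m;
  };
  List mem;
  if (!s.memY.empty())
    mem = List::create(_["y"] = s.memY, _["left"] = s.memXL,
                       _["right"] = s.memXR);
  return List::create(_["time"] = s.time, _["filaments"] = rf,
                      _["motors"] = writeLinkers(s.motors),
                      _["crosslinkers"] = writeLinkers(s.xls),
                      _["membranes"] = mem);
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_cortex(List state, List params, int seed, double duration,
                    double recordEvery) {
  Sim s = fromR(state, params);
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  int nSteps = (int)std::llround(duration / s.dt);
  int recEvery = std::max(1, (int)std::llround(recordEvery / s.dt));
  std::vector<double> times, sxx, syy, sxy, sxxA, syyA, sxyA,
      nx2c, sc, nx2p, sp, width, aload;
  for (int k = 0; k < nSteps && !s.diverged; ++k) {
    bool rec = (k % recEvery) == 0;
    if (rec) {
      Tally t;
      s.step(rng, &t, k);
      if (s.diverged) break;
      double w = s.widthCentral();
      double areaC = ((s.boundary == 1 ? w : s.Lx) - 2 * s.margin) * s.band;
      double areaA = (s.boundary == 1 ? s.widthAll() : s.Lx) * s.Ly;
      times.push_back(s.time);
      sxx.push_back(t.cxx / areaC); syy.push_back(t.cyy / areaC);
      sxy.push_back(t.cxy / areaC);
      sxxA.push_back(t.axx / areaA); syyA.push_back(t.ayy / areaA);
      sxyA.push_back(t.axy / areaA);
      double a, b, c, d;
      s.alignment(a, b, c, d);
      nx2c.push_back(a); sc.push_back(b); nx2p.push_back(c); sp.push_back(d);
      width.push_back(w);
      aload.push_back(s.anchorLoad);
    } else {
      s.step(rng, nullptr, k);
    }
    if ((k & 0x3fff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["times"] = times, _["sxx"] = sxx, _["syy"] = syy, _["sxy"] = sxy,
      _["sxxAll"] = sxxA, _["syyAll"] = syyA, _["sxyAll"] = sxyA,
      _["nx2Central"] = nx2c, _["sCentral"] = sc,
      _["nx2Peripheral"] = nx2p, _["sPeripheral"] = sp,
      _["width"] = width, _["anchorLoad"] = aload,
      _["state"] = toR(s), _["diverged"] = s.diverged);
}

// [[Rcpp::export]]
List cpp_step_cortex(List state, List params, int seed, int nSteps) {
  Sim s = fromR(state, params);
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  for (int k = 0; k < nSteps && !s.diverged; ++k) s.step(rng, nullptr, k);
  return List::create(_["state"] = toR(s), _["diverged"] = s.diverged);
}

// Pair-force ledger of the current configuration: one row per interacting
// pair with separation (min-image in y), force on the second member, and the
// (wrapped) pair midpoint. Input to the R-level virial stress calculation.
// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(List state, List params) {
  Sim s = fromR(state, params);
  Tally t;
  std::vector<double> led;
  t.ledger = &led;
  s.forces(&t);
  int n = (int)led.size() / 6;
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = led[(size_t)i * 6 + j];
  colnames(out) = CharacterVector::create("rx", "ry", "fx", "fy", "mx", "my");
  return out;
}

// Per-bead forces (filaments, then membranes) for conservation tests.
// [[Rcpp::export]]
List cpp_bead_forces(List state, List params) {
  Sim s = fromR(state, params);
  s.forces(nullptr);
  List ff(s.fils.size());
  for (size_t i = 0; i < s.fils.size(); ++i) {
    NumericMatrix m((int)s.ffx[i].size(), 2);
    for (size_t j = 0; j < s.ffx[i].size(); ++j) {
      m(j, 0) = s.ffx[i][j]; m(j, 1) = s.ffy[i][j];
    }
    ff[i] = m;
  }
  return List::create(_["filaments"] = ff, _["membraneLeft"] = s.fmL,
                      _["membraneRight"] = s.fmR);
}

// [[Rcpp::export]]
double cpp_energy(List state, List params) {
  Sim s = fromR(state, params);
  return s.energy();
}

// Instantaneous region readouts used by the R accessors.
// [[Rcpp::export]]
List cpp_readouts(List state, List params) {
  Sim s = fromR(state, params);
  s.forces(nullptr);   // refresh the anchor-load diagnostic
  double a, b, c, d;
  s.alignment(a, b, c, d);
  // link engagement diagnostics
  int mBound = 0, mDouble = 0, mAnchor = 0;
  double tension = 0;
  for (const Linker &l : s.motors) {
    if (l.f0 >= 0) ++mBound;
    if (l.f0 >= 0 && l.f1 >= 0) {
      ++mDouble;
      if (s.fils[l.f0].anchored || s.fils[l.f1].anchored) ++mAnchor;
      double p0x, p0y, p1x, p1y, tx, ty, u;
      int i;
      s.pointOn(s.fils[l.f0], l.s0, p0x, p0y, tx, ty, i, u);
      s.pointOn(s.fils[l.f1], l.s1, p1x, p1y, tx, ty, i, u);
      double dx = p0x - p1x, dy = s.minImY(p0y - p1y);
      double r = std::sqrt(dx * dx + dy * dy);
      tension += s.kLink * (r - s.linkRest);
    }
  }
  return List::create(_["nx2Central"] = a, _["sCentral"] = b,
                      _["nx2Peripheral"] = c, _["sPeripheral"] = d,
                      _["widthCentral"] = s.widthCentral(),
                      _["widthAll"] = s.widthAll(),
                      _["motorsBound"] = mBound,
                      _["motorsDouble"] = mDouble,
                      _["motorsOnAnchors"] = mAnchor,
                      _["meanMotorTension"] = mDouble > 0 ?
                        tension / mDouble : 0.0,
                      _["anchorLoad"] = s.anchorLoad);
}
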