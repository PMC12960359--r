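// DPD engine: soft conservative/dissipative/random pair forces with a
// Groot-Warren modified velocity-Verlet integrator, frozen-particle walls
// with specular reflection, viscoelastic spring-dashpot adhesion bonds and
// Bell-type stochastic bond formation/rupture.
//
// All randomness is counter-based: every variate is a pure hash of
// (seed, stream, step, identifiers), so theta_ij == theta_ji holds by
// construction and a run is reproducible from a single seed regardless of
// traversal order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t sm64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_key(uint64_t seed, uint64_t stream,
                                uint64_t step, uint64_t a, uint64_t b) {
  uint64_t h = sm64(seed ^ 0xD1B54A32D192ED03ULL);
  h = sm64(h ^ stream);
  h = sm64(h ^ step);
  h = sm64(h ^ a);
  h = sm64(h ^ b);
  return h;
}

// uniform in [0, 1)
static inline double u01(uint64_t h) {
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

// standard normal via Box-Muller from one 64-bit hash
static inline double gauss(uint64_t h) {
  double u1 = ((double)(uint32_t)(h >> 32) + 1.0) * (1.0 / 4294967296.0); // (0,1]
  double u2 = (double)(uint32_t)h * (1.0 / 4294967296.0);                 // [0,1)
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// ------------------------------------------------------------- engine ----

// particle kinds
enum Kind { PLASMA = 0, WALL = 1, COATED = 2, PLATELET = 3 };
// bond pair classes
enum Cls { PP = 0, PS = 1 }; // platelet-platelet, platelet-coated-surface
// RNG streams
enum Stream { S_PAIR = 0, S_BOND = 1, S_INJECT = 2 };
// bond event types
enum Ev { EV_FORM = 1, EV_BREAK = 2, EV_PROMOTE = 3, EV_RANGE = 4, EV_EVAP = 5 };

struct Bond {
  int a, b;        // particle indices, a < b
  int cls;         // PP or PS
  int stage;       // 1 reversible, 2 irreversible
  double t_form;   // DPD time of formation
};

struct Engine {
  // state
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<double> fx, fy, fz;          // total force
  std::vector<double> nbx, nby, nbz;       // non-bond force (platelets)
  std::vector<int> kind;
  std::vector<char> alive;
  int n;                                   // occupied slots
  int cap;

  // geometry
  double Lx, Ly, Lz, wall_pad, rc, rc2;

  // interaction tables (4x4, row-major)
  double A[16], G[16], SIG[16];
  double kBT, body_force, dt;

  // adhesion parameters
  bool adhesion_on;
  double a0[2], gp[2], k0[2], F0[2];
  double a1, ra, t_stage2;
  double p_dis_override;    // < 0 -> disabled
  bool bond_additive;       // add bond force on top of DPD C+D (default: replace)
  bool f_projection;        // use |projection on bond| instead of |net force|

  // injection / evaporation
  double inject_rate, inlet_len, outlet_len, diameter;
  double inject_margin;

  // rng
  uint64_t seed;

  // bonds
  std::vector<Bond> bonds;
  std::unordered_map<uint64_t, int> bond_of; // key(min,max) -> index in bonds
  std::vector<int> nbond;                    // active bonds per particle
  std::vector<int> nbond2;                   // stage-2 bonds per particle
  std::vector<char> anchored;                // connected to the coated surface
                                             // through the bond graph

  // cell list (counting sort into contiguous per-cell ranges)
  int ncx, ncy, ncz;
  double ylo, yhi;
  std::vector<int> cell_start, perm;
  std::vector<double> sx, sy, sz, svx, svy, svz, sfx, sfy, sfz, snx, sny, snz;
  std::vector<int> skind;

  // candidate bondable pairs collected during the force pass
  struct Cand { int a, b, cls; };
  std::vector<Cand> cands;

  // diagnostics
  long n_coincident;
  double mean_plasma_vx;
  int n_plasma;

  // events
  std::vector<double> events; // rows of 7: step, type, a, b, F, Pdis, Pr
  long n_events_total;
  long max_events;

  static inline uint64_t pair_key(int a, int b) {
    if (a > b) std::swap(a, b);
    return ((uint64_t)a << 32) | (uint64_t)b;
  }

  bool mobile(int i) const { return kind[i] == PLASMA || kind[i] == PLATELET; }

  void build_cells() {
    ylo = -wall_pad; yhi = Ly + wall_pad;
    ncx = std::max(1, (int)std::floor(Lx / rc));
    ncy = std::max(1, (int)std::floor((yhi - ylo) / rc));
    ncz = std::max(1, (int)std::floor(Lz / rc));
    size_t ncell = (size_t)ncx * ncy * ncz;
    static thread_local std::vector<int> cell_of;
    cell_of.assign(n, -1);
    cell_start.assign(ncell + 1, 0);
    int na = 0;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      int cx = (int)std::floor(x[i] / Lx * ncx); cx = ((cx % ncx) + ncx) % ncx;
      int cy = (int)std::floor((y[i] - ylo) / (yhi - ylo) * ncy);
      cy = std::min(std::max(cy, 0), ncy - 1);
      int cz = (int)std::floor(z[i] / Lz * ncz); cz = ((cz % ncz) + ncz) % ncz;
      int c = (cz * ncy + cy) * ncx + cx;
      cell_of[i] = c;
      ++cell_start[c + 1];
      ++na;
    }
    for (size_t c = 0; c < ncell; ++c) cell_start[c + 1] += cell_start[c];
    perm.resize(na);
    sx.resize(na); sy.resize(na); sz.resize(na);
    svx.resize(na); svy.resize(na); svz.resize(na);
    sfx.assign(na, 0.0); sfy.assign(na, 0.0); sfz.assign(na, 0.0);
    snx.assign(na, 0.0); sny.assign(na, 0.0); snz.assign(na, 0.0);
    skind.resize(na);
    static thread_local std::vector<int> fill;
    fill.assign(ncell, 0);
    for (int i = 0; i < n; ++i) {
      if (cell_of[i] < 0) continue;
      int c = cell_of[i];
      int pos = cell_start[c] + fill[c]++;
      perm[pos] = i;
      sx[pos] = x[i]; sy[pos] = y[i]; sz[pos] = z[i];
      svx[pos] = vx[i]; svy[pos] = vy[i]; svz[pos] = vz[i];
      skind[pos] = kind[i];
    }
  }

  // minimum-image displacement (periodic x, z; open y)
  inline void min_image(double& dx, double& dz) const {
    if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
    if (dz > 0.5 * Lz) dz -= Lz; else if (dz < -0.5 * Lz) dz += Lz;
  }

  inline int bond_index(int i, int j) const {
    auto it = bond_of.find(pair_key(i, j));
    return it == bond_of.end() ? -1 : it->second;
  }

  // pair interaction between sorted slots ii, jj (not both immobile)
  inline void pair_force_sorted(int ii, int jj, uint64_t step, double inv_sqrt_dt) {
    double dx = sx[ii] - sx[jj], dy = sy[ii] - sy[jj], dz = sz[ii] - sz[jj];
    min_image(dx, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    int i = perm[ii], j = perm[jj];
    double r = std::sqrt(r2);
    double ex, ey, ez;
    if (r < 1e-12) {
      ex = 1.0; ey = 0.0; ez = 0.0; r = 0.0;
      ++n_coincident;
    } else {
      ex = dx / r; ey = dy / r; ez = dz / r;
    }
    double w = 1.0 - r / rc;                 // omega_R
    double dvx = svx[ii] - svx[jj], dvy = svy[ii] - svy[jj], dvz = svz[ii] - svz[jj];
    double edv = ex * dvx + ey * dvy + ez * dvz;

    int ki = skind[ii], kj = skind[jj];

    // bondable pair bookkeeping
    int bidx = -1;
    if (adhesion_on && (ki == PLATELET || kj == PLATELET)) {
      int cls = -1;
      if (ki == PLATELET && kj == PLATELET) cls = PP;
      else if (ki == COATED || kj == COATED) cls = PS;
      if (cls >= 0) {
        cands.push_back({std::min(i, j), std::max(i, j), cls});
        bidx = bond_index(i, j);
      }
    }

    uint64_t h = hash_key(seed, S_PAIR, step,
                          (uint64_t)std::min(i, j), (uint64_t)std::max(i, j));
    int t = ki * 4 + kj;
    double frand = SIG[t] == 0.0 ? 0.0 : SIG[t] * w * gauss(h) * inv_sqrt_dt;

    double fmag_nb; // non-bond magnitude along e (drives detachment kinetics)
    double fmag;
    if (bidx >= 0 && !bond_additive) {
      // bonded pair: viscoelastic spring-dashpot replaces DPD C + D
      double ap = (r <= ra) ? a1 : -a0[bonds[bidx].cls];
      fmag = ap * w - gp[bonds[bidx].cls] * w * w * edv + frand;
      fmag_nb = frand;
    } else {
      double fcons = A[t] * w;
      double fdiss = -G[t] * w * w * edv;
      fmag_nb = fcons + fdiss + frand;
      fmag = fmag_nb;
      if (bidx >= 0) { // additive mode: bond force on top
        double ap = (r <= ra) ? a1 : -a0[bonds[bidx].cls];
        fmag += ap * w - gp[bonds[bidx].cls] * w * w * edv;
      }
    }

    double fxp = fmag * ex, fyp = fmag * ey, fzp = fmag * ez;
    sfx[ii] += fxp; sfy[ii] += fyp; sfz[ii] += fzp;
    sfx[jj] -= fxp; sfy[jj] -= fyp; sfz[jj] -= fzp;
    if (ki == PLATELET) {
      snx[ii] += fmag_nb * ex; sny[ii] += fmag_nb * ey; snz[ii] += fmag_nb * ez;
    }
    if (kj == PLATELET) {
      snx[jj] -= fmag_nb * ex; sny[jj] -= fmag_nb * ey; snz[jj] -= fmag_nb * ez;
    }
  }

  static inline bool kind_mobile(int k) { return k == PLASMA || k == PLATELET; }

  void compute_forces(uint64_t step) {
    cands.clear();
    build_cells();
    double inv_sqrt_dt = 1.0 / std::sqrt(dt);

    // half stencil: 13 neighbours + same cell
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
    };
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          int i0 = cell_start[c], i1 = cell_start[c + 1];
          if (i0 == i1) continue;
          // same cell
          for (int ii = i0; ii < i1; ++ii)
            for (int jj = ii + 1; jj < i1; ++jj) {
              if (!kind_mobile(skind[ii]) && !kind_mobile(skind[jj])) continue;
              pair_force_sorted(ii, jj, step, inv_sqrt_dt);
            }
          // neighbour cells
          for (int s = 0; s < 13; ++s) {
            int ox = cx + off[s][0], oy = cy + off[s][1], oz = cz + off[s][2];
            if (oy < 0 || oy >= ncy) continue;
            ox = (ox + ncx) % ncx;
            oz = (oz + ncz) % ncz;
            int c2 = (oz * ncy + oy) * ncx + ox;
            int j0 = cell_start[c2], j1 = cell_start[c2 + 1];
            for (int ii = i0; ii < i1; ++ii) {
              bool imm = !kind_mobile(skind[ii]);
              for (int jj = j0; jj < j1; ++jj) {
                if (imm && !kind_mobile(skind[jj])) continue;
                pair_force_sorted(ii, jj, step, inv_sqrt_dt);
              }
            }
          }
        }

    // scatter sorted forces back to particle order
    std::fill(fx.begin(), fx.begin() + n, 0.0);
    std::fill(fy.begin(), fy.begin() + n, 0.0);
    std::fill(fz.begin(), fz.begin() + n, 0.0);
    std::fill(nbx.begin(), nbx.begin() + n, 0.0);
    std::fill(nby.begin(), nby.begin() + n, 0.0);
    std::fill(nbz.begin(), nbz.begin() + n, 0.0);
    for (int s = 0; s < (int)perm.size(); ++s) {
      int i = perm[s];
      fx[i] = sfx[s]; fy[i] = sfy[s]; fz[i] = sfz[s];
      nbx[i] = snx[s]; nby[i] = sny[s]; nbz[i] = snz[s];
    }

    // body force on mobile particles along x
    if (body_force != 0.0) {
      for (int i = 0; i < n; ++i) {
        if (!alive[i] || !mobile(i)) continue;
        fx[i] += body_force;
        if (kind[i] == PLATELET) nbx[i] += body_force;
      }
    }
  }

  // brute-force all-pairs (used when the box is too small for a cell list)
  void compute_forces_naive(uint64_t step) {
    cands.clear();
    double inv_sqrt_dt = 1.0 / std::sqrt(dt);
    int na = 0;
    for (int i = 0; i < n; ++i) if (alive[i]) ++na;
    perm.resize(na);
    sx.resize(na); sy.resize(na); sz.resize(na);
    svx.resize(na); svy.resize(na); svz.resize(na);
    sfx.assign(na, 0.0); sfy.assign(na, 0.0); sfz.assign(na, 0.0);
    snx.assign(na, 0.0); sny.assign(na, 0.0); snz.assign(na, 0.0);
    skind.resize(na);
    int s = 0;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      perm[s] = i;
      sx[s] = x[i]; sy[s] = y[i]; sz[s] = z[i];
      svx[s] = vx[i]; svy[s] = vy[i]; svz[s] = vz[i];
      skind[s] = kind[i];
      ++s;
    }
    for (int ii = 0; ii < na; ++ii)
      for (int jj = ii + 1; jj < na; ++jj) {
        if (!kind_mobile(skind[ii]) && !kind_mobile(skind[jj])) continue;
        pair_force_sorted(ii, jj, step, inv_sqrt_dt);
      }
    std::fill(fx.begin(), fx.begin() + n, 0.0);
    std::fill(fy.begin(), fy.begin() + n, 0.0);
    std::fill(fz.begin(), fz.begin() + n, 0.0);
    std::fill(nbx.begin(), nbx.begin() + n, 0.0);
    std::fill(nby.begin(), nby.begin() + n, 0.0);
    std::fill(nbz.begin(), nbz.begin() + n, 0.0);
    for (int t = 0; t < na; ++t) {
      int i = perm[t];
      fx[i] = sfx[t]; fy[i] = sfy[t]; fz[i] = sfz[t];
      nbx[i] = snx[t]; nby[i] = sny[t]; nbz[i] = snz[t];
    }
    if (body_force != 0.0) {
      for (int i = 0; i < n; ++i) {
        if (!alive[i] || !mobile(i)) continue;
        fx[i] += body_force;
        if (kind[i] == PLATELET) nbx[i] += body_force;
      }
    }
  }

  void forces(uint64_t step) {
    if (Lx >= 3.0 * rc && Lz >= 3.0 * rc) compute_forces(step);
    else compute_forces_naive(step);
    // running mean plasma vx (used to seed injected platelet velocity)
    double s = 0.0; int m = 0;
    for (int i = 0; i < n; ++i)
      if (alive[i] && kind[i] == PLASMA) { s += vx[i]; ++m; }
    n_plasma = m;
    mean_plasma_vx = m > 0 ? s / m : 0.0;
  }

  void log_event(uint64_t step, int type, int a, int b,
                 double F, double pdis, double pr) {
    ++n_events_total;
    if ((long)(events.size() / 7) < max_events) {
      events.push_back((double)step); events.push_back((double)type);
      events.push_back((double)a); events.push_back((double)b);
      events.push_back(F); events.push_back(pdis); events.push_back(pr);
    }
  }

  void add_bond(int a, int b, int cls, double t, uint64_t step,
                double F, double pdis, double pr) {
    Bond bd; bd.a = a; bd.b = b; bd.cls = cls; bd.stage = 1; bd.t_form = t;
    bond_of[pair_key(a, b)] = (int)bonds.size();
    bonds.push_back(bd);
    ++nbond[a]; ++nbond[b];
    log_event(step, EV_FORM, a, b, F, pdis, pr);
  }

  void remove_bond(int idx, uint64_t step, int type,
                   double F, double pdis, double pr) {
    Bond bd = bonds[idx];
    --nbond[bd.a]; --nbond[bd.b];
    if (bd.stage == 2) { --nbond2[bd.a]; --nbond2[bd.b]; }
    log_event(step, type, bd.a, bd.b, F, pdis, pr);
    int last = (int)bonds.size() - 1;
    if (idx != last) {
      bonds[idx] = bonds[last];
      bond_of[pair_key(bonds[idx].a, bonds[idx].b)] = idx;
    }
    bonds.pop_back();
    bond_of.erase(pair_key(bd.a, bd.b));
  }

  double nb_force_mag(int i) const {
    return std::sqrt(nbx[i] * nbx[i] + nby[i] * nby[i] + nbz[i] * nbz[i]);
  }

  // detachment force for a pair: the net non-bond force on the platelet
  // member; for platelet-platelet pairs, the larger of the two loads
  double pair_load(int a, int b, int cls) const {
    if (f_projection) {
      double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
      double dxx = dx, dzz = dz; min_image(dxx, dzz);
      double r = std::sqrt(dxx * dxx + dy * dy + dz * dz);
      if (r < 1e-12) return nb_force_mag(kind[a] == PLATELET ? a : b);
      double ex = dxx / r, ey = dy / r, ez = dzz / r;
      double pa = kind[a] == PLATELET ?
        std::fabs(nbx[a] * ex + nby[a] * ey + nbz[a] * ez) : 0.0;
      double pb = kind[b] == PLATELET ?
        std::fabs(nbx[b] * ex + nby[b] * ey + nbz[b] * ez) : 0.0;
      return std::max(pa, pb);
    }
    if (cls == PS) return nb_force_mag(kind[a] == PLATELET ? a : b);
    return std::max(nb_force_mag(a), nb_force_mag(b));
  }

  double p_dis(double F, int cls) const {
    if (p_dis_override >= 0.0) return p_dis_override;
    double ratio = F / F0[cls];
    double k = (ratio < 1e-3) ? k0[cls]
                              : k0[cls] * std::exp(std::min(ratio, 700.0));
    double p = 1.0 - std::exp(-k * dt);
    return p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
  }

  // one stochastic attach/detach sweep over candidate pairs collected in
  // the force pass; adhered status frozen at sweep start
  void bond_sweep(uint64_t step, double time) {
    if (!adhesion_on) return;
    // deterministic order independent of cell traversal
    std::sort(cands.begin(), cands.end(), [](const Cand& p, const Cand& q) {
      return p.a != q.a ? p.a < q.a : p.b < q.b;
    });
    cands.erase(std::unique(cands.begin(), cands.end(),
      [](const Cand& p, const Cand& q) { return p.a == q.a && p.b == q.b; }),
      cands.end());
    // snapshot of recruiter status: anchored state from the previous step,
    // so a platelet bonded this sweep starts recruiting next step
    const std::vector<char>& adhered = anchored;

    for (const Cand& cd : cands) {
      int idx = bond_index(cd.a, cd.b);
      if (idx >= 0 && bonds[idx].stage == 2) continue; // permanent
      if (idx < 0) {
        // formation requires a recruiter: coated surface, or adhered platelet
        bool ok;
        if (cd.cls == PS) ok = true;
        else ok = adhered[cd.a] || adhered[cd.b];
        if (!ok) continue;
      }
      double F = pair_load(cd.a, cd.b, cd.cls);
      double pdis = p_dis(F, cd.cls);
      double pr = u01(hash_key(seed, S_BOND, step, (uint64_t)cd.a, (uint64_t)cd.b));
      if (idx < 0) {
        if (pr >= pdis) add_bond(cd.a, cd.b, cd.cls, time, step, F, pdis, pr);
      } else {
        if (pr < pdis) remove_bond(idx, step, EV_BREAK, F, pdis, pr);
      }
    }

    // prune stage-1 bonds stretched beyond the cutoff
    for (int i = (int)bonds.size() - 1; i >= 0; --i) {
      if (bonds[i].stage == 2) continue;
      double dx = x[bonds[i].a] - x[bonds[i].b];
      double dy = y[bonds[i].a] - y[bonds[i].b];
      double dz = z[bonds[i].a] - z[bonds[i].b];
      min_image(dx, dz);
      if (dx * dx + dy * dy + dz * dz > rc2)
        remove_bond(i, step, EV_RANGE, NA_REAL, NA_REAL, NA_REAL);
    }
  }

  // a platelet is adhered (recruiting, non-evaporating) iff it reaches the
  // coated surface through the bond graph; a pair bonded only to each
  // other is drifting cargo, not part of a clot
  void update_anchored() {
    std::fill(anchored.begin(), anchored.end(), 0);
    for (const Bond& b : bonds) {
      if (b.cls == PS) {
        int p = kind[b.a] == PLATELET ? b.a : b.b;
        anchored[p] = 1;
      }
    }
    bool changed = true;
    while (changed) {
      changed = false;
      for (const Bond& b : bonds) {
        if (b.cls != PP) continue;
        if (anchored[b.a] != anchored[b.b]) {
          anchored[b.a] = anchored[b.b] = 1;
          changed = true;
        }
      }
    }
  }

  void mature_bonds(uint64_t step, double time) {
    if (!adhesion_on || t_stage2 <= 0) return;
    for (Bond& bd : bonds) {
      if (bd.stage == 1 && time - bd.t_form >= t_stage2) {
        bd.stage = 2;
        ++nbond2[bd.a]; ++nbond2[bd.b];
        log_event(step, EV_PROMOTE, bd.a, bd.b, NA_REAL, NA_REAL, NA_REAL);
      }
    }
  }

  void evaporate(uint64_t step) {
    if (outlet_len < 0) return;
    double plane = Lx - outlet_len;
    for (int i = 0; i < n; ++i) {
      if (!alive[i] || kind[i] != PLATELET) continue;
      if (!anchored[i] && x[i] > plane) {
        // drop any remaining bonds (free-drifting platelet-platelet pairs)
        for (int b = (int)bonds.size() - 1; b >= 0; --b)
          if (bonds[b].a == i || bonds[b].b == i)
            remove_bond(b, step, EV_RANGE, NA_REAL, NA_REAL, NA_REAL);
        alive[i] = 0;
        log_event(step, EV_EVAP, i, -1, NA_REAL, NA_REAL, NA_REAL);
      }
    }
  }

  void inject(uint64_t step) {
    if (inject_rate <= 0) return;
    double expect = inject_rate * dt;
    int k = (int)std::floor(expect);
    double frac = expect - k;
    uint64_t ctr = 0;
    if (frac > 0 &&
        u01(hash_key(seed, S_INJECT, step, ctr++, 0)) < frac) ++k;
    for (int m = 0; m < k; ++m) {
      if (n >= cap) return; // capacity exhausted; skip quietly
      bool placed = false;
      for (int attempt = 0; attempt < 30 && !placed; ++attempt) {
        double px = inlet_len * u01(hash_key(seed, S_INJECT, step, ctr++, 1));
        double py = inject_margin + (Ly - 2 * inject_margin) *
          u01(hash_key(seed, S_INJECT, step, ctr++, 2));
        double pz = Lz * u01(hash_key(seed, S_INJECT, step, ctr++, 3));
        bool clash = false;
        for (int i = 0; i < n && !clash; ++i) {
          if (!alive[i] || kind[i] != PLATELET) continue;
          double dx = x[i] - px, dy = y[i] - py, dz = z[i] - pz;
          min_image(dx, dz);
          if (dx * dx + dy * dy + dz * dz < diameter * diameter) clash = true;
        }
        if (clash) continue;
        int i = n++;
        x[i] = px; y[i] = py; z[i] = pz;
        vx[i] = mean_plasma_vx; vy[i] = 0.0; vz[i] = 0.0;
        fx[i] = body_force; fy[i] = 0.0; fz[i] = 0.0;
        nbx[i] = 0; nby[i] = 0; nbz[i] = 0;
        kind[i] = PLATELET; alive[i] = 1;
        placed = true;
      }
    }
  }
};

static void fill_table(double* dst, NumericMatrix m) {
  if (m.nrow() != 4 || m.ncol() != 4)
    stop("interaction coefficient tables must be 4 x 4");
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      if (std::fabs(m(i, j) - m(j, i)) > 1e-12)
        stop("interaction coefficient tables must be symmetric");
      dst[i * 4 + j] = m(i, j);
    }
}

static Engine make_engine(NumericMatrix pos, NumericMatrix vel,
                          IntegerVector kind, List par) {
  Engine e;
  int n0 = pos.nrow();
  if (vel.nrow() != n0 || (int)kind.size() != n0)
    stop("positions, velocities and kinds must have matching length");
  int extra = as<int>(par["max_new_platelets"]);
  e.cap = n0 + std::max(extra, 0);
  e.n = n0;
  e.x.resize(e.cap); e.y.resize(e.cap); e.z.resize(e.cap);
  e.vx.resize(e.cap); e.vy.resize(e.cap); e.vz.resize(e.cap);
  e.fx.assign(e.cap, 0.0); e.fy.assign(e.cap, 0.0); e.fz.assign(e.cap, 0.0);
  e.nbx.assign(e.cap, 0.0); e.nby.assign(e.cap, 0.0); e.nbz.assign(e.cap, 0.0);
  e.kind.assign(e.cap, 0); e.alive.assign(e.cap, 0);
  e.nbond.assign(e.cap, 0); e.nbond2.assign(e.cap, 0);
  e.anchored.assign(e.cap, 0);
  for (int i = 0; i < n0; ++i) {
    e.x[i] = pos(i, 0); e.y[i] = pos(i, 1); e.z[i] = pos(i, 2);
    e.vx[i] = vel(i, 0); e.vy[i] = vel(i, 1); e.vz[i] = vel(i, 2);
    e.kind[i] = kind[i]; e.alive[i] = 1;
    if (e.kind[i] < 0 || e.kind[i] > 3) stop("particle kinds must be 0..3");
  }
  NumericVector box = par["box"];
  e.Lx = box[0]; e.Ly = box[1]; e.Lz = box[2];
  e.wall_pad = as<double>(par["wall_pad"]);
  e.rc = as<double>(par["r_c"]);
  e.rc2 = e.rc * e.rc;
  fill_table(e.A, as<NumericMatrix>(par["a"]));
  fill_table(e.G, as<NumericMatrix>(par["gamma"]));
  e.kBT = as<double>(par["kBT"]);
  for (int t = 0; t < 16; ++t) e.SIG[t] = std::sqrt(2.0 * e.G[t] * e.kBT);
  e.body_force = as<double>(par["body_force"]);
  e.dt = as<double>(par["dt"]);
  if (e.dt <= 0) stop("dt must be positive");

  e.adhesion_on = as<bool>(par["adhesion_on"]);
  NumericVector a0 = par["a0"], gp = par["gamma_p"], k0 = par["k0"], F0 = par["F0"];
  for (int c = 0; c < 2; ++c) {
    e.a0[c] = a0[c]; e.gp[c] = gp[c]; e.k0[c] = k0[c]; e.F0[c] = F0[c];
  }
  e.a1 = as<double>(par["a1"]);
  e.ra = as<double>(par["r_a"]);
  e.t_stage2 = as<double>(par["t_stage2"]);
  e.p_dis_override = as<double>(par["p_dis_override"]);
  e.bond_additive = as<bool>(par["bond_additive"]);
  e.f_projection = as<bool>(par["f_projection"]);

  e.inject_rate = as<double>(par["inject_rate"]);
  e.inlet_len = as<double>(par["inlet_len"]);
  e.outlet_len = as<double>(par["outlet_len"]);
  e.diameter = as<double>(par["platelet_diameter"]);
  e.inject_margin = as<double>(par["inject_margin"]);

  e.seed = (uint64_t)as<double>(par["seed"]);
  e.n_coincident = 0;
  e.mean_plasma_vx = 0.0;
  e.n_events_total = 0;
  e.max_events = (long)as<double>(par["max_events"]);

  // pre-existing bonds, matrix (a, b, cls, stage, t_form) with 1-based ids
  if (par.containsElementNamed("bonds0") && !Rf_isNull(par["bonds0"])) {
    NumericMatrix b0 = par["bonds0"];
    for (int r = 0; r < b0.nrow(); ++r) {
      int a = (int)b0(r, 0) - 1, b = (int)b0(r, 1) - 1;
      if (a > b) std::swap(a, b);
      Bond bd; bd.a = a; bd.b = b; bd.cls = (int)b0(r, 2);
      bd.stage = (int)b0(r, 3); bd.t_form = b0(r, 4);
      if (a < 0 || b >= e.n || !e.alive[a] || !e.alive[b])
        stop("bond references a particle outside the system");
      e.bond_of[Engine::pair_key(a, b)] = (int)e.bonds.size();
      e.bonds.push_back(bd);
      ++e.nbond[a]; ++e.nbond[b];
      if (bd.stage == 2) { ++e.nbond2[a]; ++e.nbond2[b]; }
    }
  }
  e.update_anchored();
  return e;
}

// [[Rcpp::export]]
List dpd_forces_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
                    List par, double step) {
  Engine e = make_engine(pos, vel, kind, par);
  e.forces((uint64_t)step);
  int n = e.n;
  NumericMatrix f(n, 3), nb(n, 3);
  for (int i = 0; i < n; ++i) {
    f(i, 0) = e.fx[i]; f(i, 1) = e.fy[i]; f(i, 2) = e.fz[i];
    nb(i, 0) = e.nbx[i]; nb(i, 1) = e.nby[i]; nb(i, 2) = e.nbz[i];
  }
  return List::create(_["force"] = f, _["nonbond_force"] = nb,
                      _["n_coincident"] = (double)e.n_coincident);
}

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
                 List par, List control) {
  Engine e = make_engine(pos, vel, kind, par);
  long n_steps = (long)as<double>(control["n_steps"]);
  long step0 = (long)as<double>(control["step0"]);
  int metrics_every = as<int>(control["metrics_every"]);
  int snapshot_every = as<int>(control["snapshot_every"]);
  int profile_bins = as<int>(control["profile_bins"]);
  long profile_start = (long)as<double>(control["profile_start_step"]);
  int profile_every = as<int>(control["profile_every"]);
  double t0 = as<double>(control["t0"]);
  double dt = e.dt;

  // profile accumulators (plasma x-velocity vs y)
  std::vector<double> prof_sum(profile_bins, 0.0), prof_sum2(profile_bins, 0.0);
  std::vector<double> prof_n(profile_bins, 0.0);

  // metric records
  std::vector<double> m_step, m_time, m_nplt, m_nadh, m_nbonds, m_temp, m_pvx;
  List adhered_snaps, snapshots;
  std::vector<double> snap_steps, adh_steps;

  auto record_metrics = [&](long gstep, double time) {
    int nplt = 0, nadh = 0;
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i] || e.kind[i] != PLATELET) continue;
      ++nplt;
      if (e.anchored[i]) ++nadh;
    }
    double ke = 0.0; int nm = 0;
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i] || !e.mobile(i)) continue;
      ke += e.vx[i] * e.vx[i] + e.vy[i] * e.vy[i] + e.vz[i] * e.vz[i];
      ++nm;
    }
    m_step.push_back((double)gstep);
    m_time.push_back(time);
    m_nplt.push_back(nplt);
    m_nadh.push_back(nadh);
    m_nbonds.push_back((double)e.bonds.size());
    m_temp.push_back(nm > 0 ? ke / (3.0 * nm) : NA_REAL);
    m_pvx.push_back(e.mean_plasma_vx);
    NumericMatrix adh(nadh, 6); // id, x, y, z, nbond, stage
    int r = 0;
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i] || e.kind[i] != PLATELET || !e.anchored[i]) continue;
      adh(r, 0) = i + 1; adh(r, 1) = e.x[i]; adh(r, 2) = e.y[i];
      adh(r, 3) = e.z[i]; adh(r, 4) = e.nbond[i];
      adh(r, 5) = e.nbond2[i] > 0 ? 2 : 1;
      ++r;
    }
    adh_steps.push_back((double)gstep);
    adhered_snaps.push_back(adh);
  };

  auto record_snapshot = [&](long gstep) {
    int na = 0;
    for (int i = 0; i < e.n; ++i) if (e.alive[i]) ++na;
    NumericMatrix s(na, 8); // id, kind, x, y, z, vx, vy, vz
    int r = 0;
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i]) continue;
      s(r, 0) = i + 1; s(r, 1) = e.kind[i];
      s(r, 2) = e.x[i]; s(r, 3) = e.y[i]; s(r, 4) = e.z[i];
      s(r, 5) = e.vx[i]; s(r, 6) = e.vy[i]; s(r, 7) = e.vz[i];
      ++r;
    }
    snap_steps.push_back((double)gstep);
    snapshots.push_back(s);
  };

  // initial force evaluation
  e.forces((uint64_t)step0);
  if (metrics_every > 0) record_metrics(step0, t0);
  if (snapshot_every > 0) record_snapshot(step0);

  for (long s = 0; s < n_steps; ++s) {
    long gstep = step0 + s;
    double time = t0 + (s + 1) * dt;

    // Groot-Warren modified velocity-Verlet, lambda = 1/2:
    // half kick + drift, dissipative force evaluated at the half-step
    // velocity, then the second half kick
    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i] || !e.mobile(i)) continue;
      e.vx[i] += 0.5 * dt * e.fx[i];
      e.vy[i] += 0.5 * dt * e.fy[i];
      e.vz[i] += 0.5 * dt * e.fz[i];
      e.x[i] += dt * e.vx[i];
      e.y[i] += dt * e.vy[i];
      e.z[i] += dt * e.vz[i];
      // periodic wrap in x and z
      if (e.x[i] >= e.Lx) e.x[i] -= e.Lx; else if (e.x[i] < 0) e.x[i] += e.Lx;
      if (e.z[i] >= e.Lz) e.z[i] -= e.Lz; else if (e.z[i] < 0) e.z[i] += e.Lz;
      if (!std::isfinite(e.x[i]) || !std::isfinite(e.y[i]) ||
          !std::isfinite(e.z[i]) || e.y[i] < -e.rc || e.y[i] > e.Ly + e.rc) {
        stop("numeric instability: particle %d left the domain at step %ld",
             i + 1, gstep + 1);
      }
      // specular reflection at the y walls
      if (e.y[i] < 0) { e.y[i] = -e.y[i]; e.vy[i] = -e.vy[i]; }
      else if (e.y[i] > e.Ly) { e.y[i] = 2.0 * e.Ly - e.y[i]; e.vy[i] = -e.vy[i]; }
    }

    e.forces((uint64_t)(gstep + 1));

    for (int i = 0; i < e.n; ++i) {
      if (!e.alive[i] || !e.mobile(i)) continue;
      e.vx[i] += 0.5 * dt * e.fx[i];
      e.vy[i] += 0.5 * dt * e.fy[i];
      e.vz[i] += 0.5 * dt * e.fz[i];
    }

    e.bond_sweep((uint64_t)(gstep + 1), time);
    e.mature_bonds((uint64_t)(gstep + 1), time);
    e.update_anchored();
    e.evaporate((uint64_t)(gstep + 1));
    e.inject((uint64_t)(gstep + 1));

    if (profile_bins > 0 && gstep + 1 >= profile_start &&
        profile_every > 0 && (gstep + 1) % profile_every == 0) {
      for (int i = 0; i < e.n; ++i) {
        if (!e.alive[i] || e.kind[i] != PLASMA) continue;
        int b = (int)std::floor(e.y[i] / e.Ly * profile_bins);
        b = std::min(std::max(b, 0), profile_bins - 1);
        prof_sum[b] += e.vx[i];
        prof_sum2[b] += e.vx[i] * e.vx[i];
        prof_n[b] += 1.0;
      }
    }
    if (metrics_every > 0 && (s + 1) % metrics_every == 0)
      record_metrics(gstep + 1, time);
    if (snapshot_every > 0 && (s + 1) % snapshot_every == 0)
      record_snapshot(gstep + 1);
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // final state
  int na = 0;
  for (int i = 0; i < e.n; ++i) if (e.alive[i]) ++na;
  NumericMatrix X(na, 3), V(na, 3);
  IntegerVector K(na), ID(na), ACT(na), NB(na);
  int r = 0;
  std::vector<int> newidx(e.n, -1);
  for (int i = 0; i < e.n; ++i) {
    if (!e.alive[i]) continue;
    newidx[i] = r;
    X(r, 0) = e.x[i]; X(r, 1) = e.y[i]; X(r, 2) = e.z[i];
    V(r, 0) = e.vx[i]; V(r, 1) = e.vy[i]; V(r, 2) = e.vz[i];
    K[r] = e.kind[i]; ID[r] = i + 1;
    NB[r] = e.nbond[i];
    ACT[r] = e.kind[i] == PLATELET && e.anchored[i] ?
      (e.nbond2[i] > 0 ? 2 : 1) : 0;
    ++r;
  }
  NumericMatrix B((int)e.bonds.size(), 5);
  for (int i = 0; i < (int)e.bonds.size(); ++i) {
    B(i, 0) = e.bonds[i].a + 1; B(i, 1) = e.bonds[i].b + 1;
    B(i, 2) = e.bonds[i].cls; B(i, 3) = e.bonds[i].stage;
    B(i, 4) = e.bonds[i].t_form;
  }
  colnames(B) = CharacterVector::create("a", "b", "class", "stage", "t_form");

  int ner = (int)(e.events.size() / 7);
  NumericMatrix EV(ner, 7);
  for (int i = 0; i < ner; ++i)
    for (int j = 0; j < 7; ++j) EV(i, j) = e.events[i * 7 + j];
  colnames(EV) = CharacterVector::create("step", "type", "a", "b",
                                         "F", "p_dis", "p_r");

  return List::create(
    _["x"] = X, _["v"] = V, _["kind"] = K, _["id"] = ID,
    _["activation"] = ACT, _["n_bonds_per_particle"] = NB,
    _["bonds"] = B,
    _["metrics"] = List::create(
      _["step"] = wrap(m_step), _["time"] = wrap(m_time),
      _["n_platelets"] = wrap(m_nplt), _["n_adhered"] = wrap(m_nadh),
      _["n_bonds"] = wrap(m_nbonds), _["temperature"] = wrap(m_temp),
      _["mean_plasma_vx"] = wrap(m_pvx)),
    _["adhered_snapshots"] = adhered_snaps,
    _["adhered_snapshot_steps"] = wrap(adh_steps),
    _["snapshots"] = snapshots,
    _["snapshot_steps"] = wrap(snap_steps),
    _["profile"] = List::create(
      _["n"] = wrap(prof_n), _["vx_sum"] = wrap(prof_sum),
      _["vx_sum2"] = wrap(prof_sum2)),
    _["events"] = EV,
    _["n_events_total"] = (double)e.n_events_total,
    _["n_coincident"] = (double)e.n_coincident,
    _["final_step"] = (double)(step0 + n_steps),
    _["final_time"] = t0 + n_steps * dt);
}
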