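// Coarse-grained Metropolis Monte Carlo engine for bead-chain peptides
// aggregating via saturating inter-chain "hydrogen bonds" in a periodic box
// holding fixed spherical nanoparticles with a square-well adsorption shell.
//
// Units: lengths in sigma (bead diameter = 1 by convention), energies in kT.
// A step is one attempted move of one randomly chosen chain.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>
#include <functional>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// deterministic RNG (engine state independent of R's RNG)
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  // uniform in [0, 1)
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in {0, ..., n-1}
  int unif_int(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  // Marsaglia point on the unit sphere
  void unit_vec(double v[3]) {
    double u1, u2, s;
    do {
      u1 = 2.0 * unif() - 1.0;
      u2 = 2.0 * unif() - 1.0;
      s = u1 * u1 + u2 * u2;
    } while (s >= 1.0 || s == 0.0);
    double f = 2.0 * std::sqrt(1.0 - s);
    v[0] = u1 * f;
    v[1] = u2 * f;
    v[2] = 1.0 - 2.0 * s;
  }
};

inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard against floor rounding
  return x;
}

// nearest-image displacement component
inline double mind1(double d, double L) { return d - L * std::round(d / L); }

struct Vec3 {
  double x, y, z;
};

// Rodrigues rotation of d about unit axis u by angle a
inline Vec3 rotate_vec(const Vec3& d, const double u[3], double a) {
  double c = std::cos(a), s = std::sin(a);
  double dot = d.x * u[0] + d.y * u[1] + d.z * u[2];
  Vec3 cr{u[1] * d.z - u[2] * d.y, u[2] * d.x - u[0] * d.z,
          u[0] * d.y - u[1] * d.x};
  return Vec3{d.x * c + cr.x * s + u[0] * dot * (1 - c),
              d.y * c + cr.y * s + u[1] * dot * (1 - c),
              d.z * c + cr.z * s + u[2] * dot * (1 - c)};
}

// ---------------------------------------------------------------------------
struct Params {
  double L;             // box length
  int n_chains;
  int chain_len;
  double bead_d;
  double bond_len;
  double eps_hb;        // H-bond well depth (kT, >0 attractive)
  double hb_cutoff;
  int max_bonds;        // per bead
  double w[4];          // pivot, crankshaft, kink-jump, translation
  bool ads_block;       // adsorbed beads barred from forming new bonds
  double crank_max;     // crankshaft max |angle|
};

Params params_from_list(const List& cfg) {
  Params p;
  p.L = as<double>(cfg["box_length"]);
  p.n_chains = as<int>(cfg["n_chains"]);
  p.chain_len = as<int>(cfg["chain_length"]);
  p.bead_d = as<double>(cfg["bead_diameter"]);
  p.bond_len = as<double>(cfg["bond_length"]);
  p.eps_hb = as<double>(cfg["eps_hb"]);
  p.hb_cutoff = as<double>(cfg["hb_cutoff"]);
  p.max_bonds = as<int>(cfg["max_bonds_per_bead"]);
  NumericVector w = cfg["move_weights"];
  for (int i = 0; i < 4; ++i) p.w[i] = w[i];
  p.ads_block = as<bool>(cfg["adsorbed_bond_block"]);
  p.crank_max = cfg.containsElementNamed("crankshaft_max_angle")
                    ? as<double>(cfg["crankshaft_max_angle"])
                    : M_PI / 2.0;
  return p;
}

// ---------------------------------------------------------------------------
struct System {
  Params p;
  int n_beads;
  std::vector<double> x, y, z;      // bead coordinates in [0, L)
  // nanoparticles
  int n_np;
  std::vector<double> npx, npy, npz, npr, npeps, npshell;
  // bond registry: partner slots per bead (-1 = empty)
  std::vector<int> partner;         // n_beads * max_bonds
  std::vector<int> nbond;
  double energy;
  // cell list
  bool use_cells;
  int nc;                            // cells per side
  double cw;
  std::vector<int> head, nxt, prv, cell_of;

  int chain_of(int b) const { return b / p.chain_len; }
  int local_of(int b) const { return b % p.chain_len; }

  double mdist2(double ax, double ay, double az, double bx, double by,
                double bz) const {
    double dx = mind1(ax - bx, p.L), dy = mind1(ay - by, p.L),
           dz = mind1(az - bz, p.L);
    return dx * dx + dy * dy + dz * dz;
  }

  void init_cells() {
    double rmax = std::max(p.bead_d, p.hb_cutoff);
    nc = static_cast<int>(std::floor(p.L / rmax));
    use_cells = nc >= 4;
    if (!use_cells) return;
    if (nc > 64) nc = 64;  // cap memory; cells stay >= cutoff wide
    cw = p.L / nc;
    head.assign(static_cast<size_t>(nc) * nc * nc, -1);
    nxt.assign(n_beads, -1);
    prv.assign(n_beads, -1);
    cell_of.assign(n_beads, -1);
  }
  int cell_index(double cx, double cy, double cz) const {
    int ix = static_cast<int>(cx / cw); if (ix >= nc) ix = nc - 1;
    int iy = static_cast<int>(cy / cw); if (iy >= nc) iy = nc - 1;
    int iz = static_cast<int>(cz / cw); if (iz >= nc) iz = nc - 1;
    return (ix * nc + iy) * nc + iz;
  }
  void cell_insert(int b) {
    if (!use_cells) return;
    int c = cell_index(x[b], y[b], z[b]);
    cell_of[b] = c;
    nxt[b] = head[c];
    prv[b] = -1;
    if (head[c] >= 0) prv[head[c]] = b;
    head[c] = b;
  }
  void cell_remove(int b) {
    if (!use_cells) return;
    int c = cell_of[b];
    if (prv[b] >= 0) nxt[prv[b]] = nxt[b]; else head[c] = nxt[b];
    if (nxt[b] >= 0) prv[nxt[b]] = prv[b];
    cell_of[b] = -1;
  }

  // visit candidate neighbours of a position (caller filters)
  template <typename F>
  void neighbours(double cx, double cy, double cz, F f) const {
    if (!use_cells) {
      for (int j = 0; j < n_beads; ++j) f(j);
      return;
    }
    int ix = static_cast<int>(cx / cw); if (ix >= nc) ix = nc - 1;
    int iy = static_cast<int>(cy / cw); if (iy >= nc) iy = nc - 1;
    int iz = static_cast<int>(cz / cw); if (iz >= nc) iz = nc - 1;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int jx = (ix + dx + nc) % nc, jy = (iy + dy + nc) % nc,
              jz = (iz + dz + nc) % nc;
          for (int j = head[(jx * nc + jy) * nc + jz]; j >= 0; j = nxt[j]) f(j);
        }
  }

  bool inside_np(double cx, double cy, double cz) const {
    for (int k = 0; k < n_np; ++k) {
      double r2 = mdist2(cx, cy, cz, npx[k], npy[k], npz[k]);
      if (r2 < npr[k] * npr[k]) return true;
    }
    return false;
  }
  bool in_shell(double cx, double cy, double cz) const {
    for (int k = 0; k < n_np; ++k) {
      double r2 = mdist2(cx, cy, cz, npx[k], npy[k], npz[k]);
      double ro = npr[k] + npshell[k];
      if (r2 >= npr[k] * npr[k] && r2 < ro * ro) return true;
    }
    return false;
  }
  double ads_energy_at(double cx, double cy, double cz) const {
    double e = 0.0;
    for (int k = 0; k < n_np; ++k) {
      double r2 = mdist2(cx, cy, cz, npx[k], npy[k], npz[k]);
      double ro = npr[k] + npshell[k];
      if (r2 >= npr[k] * npr[k] && r2 < ro * ro) e -= npeps[k];
    }
    return e;
  }

  bool bonded(int a, int b) const {
    for (int s = 0; s < p.max_bonds; ++s)
      if (partner[a * p.max_bonds + s] == b) return true;
    return false;
  }
  void add_bond(int a, int b) {
    for (int s = 0; s < p.max_bonds; ++s)
      if (partner[a * p.max_bonds + s] < 0) {
        partner[a * p.max_bonds + s] = b;
        break;
      }
    for (int s = 0; s < p.max_bonds; ++s)
      if (partner[b * p.max_bonds + s] < 0) {
        partner[b * p.max_bonds + s] = a;
        break;
      }
    ++nbond[a];
    ++nbond[b];
  }
  void drop_bond(int a, int b) {
    for (int s = 0; s < p.max_bonds; ++s)
      if (partner[a * p.max_bonds + s] == b) {
        partner[a * p.max_bonds + s] = -1;
        break;
      }
    for (int s = 0; s < p.max_bonds; ++s)
      if (partner[b * p.max_bonds + s] == a) {
        partner[b * p.max_bonds + s] = -1;
        break;
      }
    --nbond[a];
    --nbond[b];
  }
  int total_bonds() const {
    int t = 0;
    for (int b = 0; b < n_beads; ++b) t += nbond[b];
    return t / 2;
  }
  double full_energy() const {
    double e = -p.eps_hb * total_bonds();
    for (int b = 0; b < n_beads; ++b) e += ads_energy_at(x[b], y[b], z[b]);
    return e;
  }
};

System system_from_r(const List& cfg, const NumericMatrix& coords,
                     const NumericMatrix& np, const IntegerMatrix& bonds) {
  System S;
  S.p = params_from_list(cfg);
  S.n_beads = coords.nrow();
  S.x.resize(S.n_beads);
  S.y.resize(S.n_beads);
  S.z.resize(S.n_beads);
  for (int b = 0; b < S.n_beads; ++b) {
    S.x[b] = wrap1(coords(b, 0), S.p.L);
    S.y[b] = wrap1(coords(b, 1), S.p.L);
    S.z[b] = wrap1(coords(b, 2), S.p.L);
  }
  S.n_np = np.nrow();
  for (int k = 0; k < S.n_np; ++k) {
    S.npx.push_back(np(k, 0));
    S.npy.push_back(np(k, 1));
    S.npz.push_back(np(k, 2));
    S.npr.push_back(np(k, 3) / 2.0);  // column 4 is the diameter
    S.npeps.push_back(np(k, 4));
    S.npshell.push_back(np(k, 5));
  }
  S.partner.assign(static_cast<size_t>(S.n_beads) * S.p.max_bonds, -1);
  S.nbond.assign(S.n_beads, 0);
  for (int i = 0; i < bonds.nrow(); ++i) {
    int a = bonds(i, 0) - 1, b = bonds(i, 1) - 1;  // 1-based from R
    S.add_bond(a, b);
  }
  S.init_cells();
  if (S.use_cells)
    for (int b = 0; b < S.n_beads; ++b) S.cell_insert(b);
  S.energy = S.full_energy();
  return S;
}

IntegerMatrix bonds_to_r(const System& S) {
  std::vector<std::pair<int, int>> pr;
  for (int a = 0; a < S.n_beads; ++a)
    for (int s = 0; s < S.p.max_bonds; ++s) {
      int b = S.partner[a * S.p.max_bonds + s];
      if (b > a) pr.emplace_back(a + 1, b + 1);
    }
  std::sort(pr.begin(), pr.end());
  IntegerMatrix out(pr.size(), 2);
  for (size_t i = 0; i < pr.size(); ++i) {
    out(i, 0) = pr[i].first;
    out(i, 1) = pr[i].second;
  }
  return out;
}

NumericMatrix coords_to_r(const System& S) {
  NumericMatrix out(S.n_beads, 3);
  for (int b = 0; b < S.n_beads; ++b) {
    out(b, 0) = S.x[b];
    out(b, 1) = S.y[b];
    out(b, 2) = S.z[b];
  }
  return out;
}

// ---------------------------------------------------------------------------
struct Proposal {
  int type;                  // 0 pivot, 1 crankshaft, 2 kink-jump, 3 translation
  int chain;
  std::vector<int> beads;    // global indices
  std::vector<Vec3> newpos;  // wrapped
};

Proposal propose(const System& S, Rng& rng) {
  const Params& p = S.p;
  Proposal pr;
  pr.chain = rng.unif_int(p.n_chains);
  double u = rng.unif(), acc = 0.0;
  pr.type = 3;
  for (int t = 0; t < 4; ++t) {
    acc += p.w[t];
    if (u < acc) {
      pr.type = t;
      break;
    }
  }
  int base = pr.chain * p.chain_len;
  int L = p.chain_len;
  double Lbox = p.L;

  if (pr.type == 0) {  // pivot: rigid rotation of one tail about a pivot bead
    bool right = rng.unif() < 0.5;
    int piv = right ? rng.unif_int(L - 1) : 1 + rng.unif_int(L - 1);
    double axis[3];
    rng.unit_vec(axis);
    double ang = (2.0 * rng.unif() - 1.0) * M_PI;
    int gp = base + piv;
    double ox = S.x[gp], oy = S.y[gp], oz = S.z[gp];
    int lo = right ? piv + 1 : 0, hi = right ? L - 1 : piv - 1;
    for (int i = lo; i <= hi; ++i) {
      int g = base + i;
      Vec3 d{mind1(S.x[g] - ox, Lbox), mind1(S.y[g] - oy, Lbox),
             mind1(S.z[g] - oz, Lbox)};
      Vec3 r = rotate_vec(d, axis, ang);
      pr.beads.push_back(g);
      pr.newpos.push_back(Vec3{wrap1(ox + r.x, Lbox), wrap1(oy + r.y, Lbox),
                               wrap1(oz + r.z, Lbox)});
    }
  } else if (pr.type == 1) {  // crankshaft about the neighbour-neighbour axis
    int i = 1 + rng.unif_int(L - 2);
    int g = base + i, ga = base + i - 1, gc = base + i + 1;
    double ox = S.x[ga], oy = S.y[ga], oz = S.z[ga];
    double ax = mind1(S.x[gc] - ox, Lbox), ay = mind1(S.y[gc] - oy, Lbox),
           az = mind1(S.z[gc] - oz, Lbox);
    double n = std::sqrt(ax * ax + ay * ay + az * az);
    if (n < 1e-12) {  // degenerate axis: null move
      pr.beads.push_back(g);
      pr.newpos.push_back(Vec3{S.x[g], S.y[g], S.z[g]});
      return pr;
    }
    double axis[3] = {ax / n, ay / n, az / n};
    double ang = (2.0 * rng.unif() - 1.0) * p.crank_max;
    Vec3 d{mind1(S.x[g] - ox, Lbox), mind1(S.y[g] - oy, Lbox),
           mind1(S.z[g] - oz, Lbox)};
    Vec3 r = rotate_vec(d, axis, ang);
    pr.beads.push_back(g);
    pr.newpos.push_back(Vec3{wrap1(ox + r.x, Lbox), wrap1(oy + r.y, Lbox),
                             wrap1(oz + r.z, Lbox)});
  } else if (pr.type == 2) {  // kink-jump: resample interior bead on its circle
    int i = 1 + rng.unif_int(L - 2);
    int g = base + i, ga = base + i - 1, gc = base + i + 1;
    double ox = S.x[ga], oy = S.y[ga], oz = S.z[ga];
    // local frame anchored at bead i-1
    Vec3 w{mind1(S.x[gc] - ox, Lbox), mind1(S.y[gc] - oy, Lbox),
           mind1(S.z[gc] - oz, Lbox)};
    Vec3 v{mind1(S.x[g] - ox, Lbox), mind1(S.y[g] - oy, Lbox),
           mind1(S.z[g] - oz, Lbox)};
    double d = std::sqrt(w.x * w.x + w.y * w.y + w.z * w.z);
    double b1 = std::sqrt(v.x * v.x + v.y * v.y + v.z * v.z);
    double dxc = v.x - w.x, dyc = v.y - w.y, dzc = v.z - w.z;
    double b2 = std::sqrt(dxc * dxc + dyc * dyc + dzc * dzc);
    if (d < 1e-12) {  // degenerate: null move
      pr.beads.push_back(g);
      pr.newpos.push_back(Vec3{S.x[g], S.y[g], S.z[g]});
      return pr;
    }
    double t = (d * d + b1 * b1 - b2 * b2) / (2.0 * d);
    double r2 = b1 * b1 - t * t;
    if (r2 <= 1e-14) {  // collinear: circle degenerates to a point
      pr.beads.push_back(g);
      pr.newpos.push_back(Vec3{S.x[g], S.y[g], S.z[g]});
      return pr;
    }
    double r = std::sqrt(r2);
    double wn[3] = {w.x / d, w.y / d, w.z / d};
    // orthonormal basis perpendicular to wn
    double ref[3] = {1.0, 0.0, 0.0};
    if (std::fabs(wn[0]) > 0.9) { ref[0] = 0.0; ref[1] = 1.0; }
    double e1[3] = {wn[1] * ref[2] - wn[2] * ref[1],
                    wn[2] * ref[0] - wn[0] * ref[2],
                    wn[0] * ref[1] - wn[1] * ref[0]};
    double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int k = 0; k < 3; ++k) e1[k] /= n1;
    double e2[3] = {wn[1] * e1[2] - wn[2] * e1[1],
                    wn[2] * e1[0] - wn[0] * e1[2],
                    wn[0] * e1[1] - wn[1] * e1[0]};
    double phi = rng.unif() * 2.0 * M_PI;
    double cx = ox + t * wn[0] + r * (std::cos(phi) * e1[0] + std::sin(phi) * e2[0]);
    double cy = oy + t * wn[1] + r * (std::cos(phi) * e1[1] + std::sin(phi) * e2[1]);
    double cz = oz + t * wn[2] + r * (std::cos(phi) * e1[2] + std::sin(phi) * e2[2]);
    pr.beads.push_back(g);
    pr.newpos.push_back(Vec3{wrap1(cx, Lbox), wrap1(cy, Lbox), wrap1(cz, Lbox)});
  } else {  // whole-chain translation
    double dx = (2.0 * rng.unif() - 1.0) * p.bead_d;
    double dy = (2.0 * rng.unif() - 1.0) * p.bead_d;
    double dz = (2.0 * rng.unif() - 1.0) * p.bead_d;
    for (int i = 0; i < L; ++i) {
      int g = base + i;
      pr.beads.push_back(g);
      pr.newpos.push_back(Vec3{wrap1(S.x[g] + dx, Lbox),
                               wrap1(S.y[g] + dy, Lbox),
                               wrap1(S.z[g] + dz, Lbox)});
    }
  }
  return pr;
}

struct EvalResult {
  bool feasible;
  double dE;
  std::vector<std::pair<int, int>> broken, formed;  // global 0-based pairs
};

struct Cand {
  double d;
  int c1, i1, c2, i2;  // normalized (chain, bead) pair for tie-breaking
  int a, b;            // global indices
};

// Bond judgment and energy difference for a proposal. All moved beads belong
// to one chain, so bonds (inter-chain only) always pair a moved bead with an
// unmoved one.
EvalResult evaluate(const System& S, const Proposal& pr,
                    std::vector<char>& movedflag) {
  const Params& p = S.p;
  EvalResult R;
  R.feasible = true;
  R.dE = 0.0;
  int m = pr.beads.size();
  for (int i = 0; i < m; ++i) movedflag[pr.beads[i]] = 1;

  double ev2 = p.bead_d * p.bead_d;
  double hb2 = p.hb_cutoff * p.hb_cutoff;

  // hard constraints at the proposed positions
  for (int i = 0; i < m && R.feasible; ++i) {
    const Vec3& q = pr.newpos[i];
    int b = pr.beads[i];
    if (S.inside_np(q.x, q.y, q.z)) {
      R.feasible = false;
      break;
    }
    int bc = S.chain_of(b), bl = S.local_of(b);
    bool clash = false;
    S.neighbours(q.x, q.y, q.z, [&](int j) {
      if (clash || j == b || movedflag[j]) return;
      if (S.chain_of(j) == bc && std::abs(S.local_of(j) - bl) == 1) return;
      if (S.mdist2(q.x, q.y, q.z, S.x[j], S.y[j], S.z[j]) < ev2) clash = true;
    });
    if (clash) R.feasible = false;
  }

  if (R.feasible) {
    // broken bonds: registered partners stretched beyond the cutoff
    std::vector<int> extra_free(m, 0);  // freed valence on moved beads
    for (int i = 0; i < m; ++i) {
      int b = pr.beads[i];
      const Vec3& q = pr.newpos[i];
      for (int s = 0; s < p.max_bonds; ++s) {
        int j = S.partner[b * p.max_bonds + s];
        if (j < 0) continue;
        if (S.mdist2(q.x, q.y, q.z, S.x[j], S.y[j], S.z[j]) > hb2) {
          R.broken.emplace_back(b, j);
        }
      }
    }
    // new bonds: nearest-first under saturation; a bead inside an adsorption
    // shell cannot be the newly bonding end when the block is active
    if (p.eps_hb > 0) {
      std::vector<Cand> cands;
      for (int i = 0; i < m; ++i) {
        int b = pr.beads[i];
        const Vec3& q = pr.newpos[i];
        if (p.ads_block && S.in_shell(q.x, q.y, q.z)) continue;
        int bc = S.chain_of(b);
        S.neighbours(q.x, q.y, q.z, [&](int j) {
          if (movedflag[j]) return;
          if (S.chain_of(j) == bc) return;
          if (S.bonded(b, j)) return;
          if (p.ads_block && S.in_shell(S.x[j], S.y[j], S.z[j])) return;
          double d2 = S.mdist2(q.x, q.y, q.z, S.x[j], S.y[j], S.z[j]);
          if (d2 > hb2) return;
          Cand c;
          c.d = std::sqrt(d2);
          c.a = b;
          c.b = j;
          int ca = S.chain_of(b), ia = S.local_of(b);
          int cb = S.chain_of(j), ib = S.local_of(j);
          if (ca < cb || (ca == cb && ia < ib)) {
            c.c1 = ca; c.i1 = ia; c.c2 = cb; c.i2 = ib;
          } else {
            c.c1 = cb; c.i1 = ib; c.c2 = ca; c.i2 = ia;
          }
          cands.push_back(c);
        });
      }
      std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
        if (a.d != b.d) return a.d < b.d;
        if (a.c1 != b.c1) return a.c1 < b.c1;
        if (a.i1 != b.i1) return a.i1 < b.i1;
        if (a.c2 != b.c2) return a.c2 < b.c2;
        return a.i2 < b.i2;
      });
      // free valence after subtracting current bonds and adding breaks
      std::vector<std::pair<int, int>> freev;  // (bead, free slots), sparse
      freev.reserve(2 * cands.size() + 4);     // references must stay valid
      auto free_of = [&](int bead) -> int& {
        for (auto& pr2 : freev)
          if (pr2.first == bead) return pr2.second;
        int f = p.max_bonds - S.nbond[bead];
        for (auto& br : R.broken)
          if (br.first == bead || br.second == bead) ++f;
        freev.emplace_back(bead, f);
        return freev.back().second;
      };
      for (const Cand& c : cands) {
        int& fa = free_of(c.a);
        int& fb = free_of(c.b);
        if (fa > 0 && fb > 0) {
          R.formed.emplace_back(c.a, c.b);
          --fa;
          --fb;
        }
      }
    }
    // adsorption energy change for moved beads
    double dads = 0.0;
    for (int i = 0; i < m; ++i) {
      int b = pr.beads[i];
      const Vec3& q = pr.newpos[i];
      dads += S.ads_energy_at(q.x, q.y, q.z) -
              S.ads_energy_at(S.x[b], S.y[b], S.z[b]);
    }
    R.dE = -p.eps_hb * (static_cast<double>(R.formed.size()) -
                        static_cast<double>(R.broken.size())) +
           dads;
  }
  for (int i = 0; i < m; ++i) movedflag[pr.beads[i]] = 0;
  return R;
}

void commit(System& S, const Proposal& pr, const EvalResult& R) {
  for (auto& b : R.broken) S.drop_bond(b.first, b.second);
  for (auto& f : R.formed) S.add_bond(f.first, f.second);
  for (size_t i = 0; i < pr.beads.size(); ++i) {
    int b = pr.beads[i];
    S.cell_remove(b);
    S.x[b] = pr.newpos[i].x;
    S.y[b] = pr.newpos[i].y;
    S.z[b] = pr.newpos[i].z;
    S.cell_insert(b);
  }
  S.energy += R.dE;
}

// union-find over chains
std::vector<int> cluster_sizes_sys(const System& S, bool np_merge) {
  int n = S.p.n_chains;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int a = 0; a < S.n_beads; ++a)
    for (int s = 0; s < S.p.max_bonds; ++s) {
      int b = S.partner[a * S.p.max_bonds + s];
      if (b > a) unite(S.chain_of(a), S.chain_of(b));
    }
  if (np_merge && S.n_np > 0) {
    std::vector<int> np_anchor(S.n_np, -1);
    for (int b = 0; b < S.n_beads; ++b) {
      for (int k = 0; k < S.n_np; ++k) {
        double r2 = S.mdist2(S.x[b], S.y[b], S.z[b], S.npx[k], S.npy[k], S.npz[k]);
        double ro = S.npr[k] + S.npshell[k];
        if (r2 >= S.npr[k] * S.npr[k] && r2 < ro * ro) {
          int c = S.chain_of(b);
          if (np_anchor[k] < 0) np_anchor[k] = c; else unite(np_anchor[k], c);
        }
      }
    }
  }
  std::vector<int> count(n, 0);
  for (int i = 0; i < n; ++i) ++count[find(i)];
  std::vector<int> sizes;
  for (int i = 0; i < n; ++i)
    if (count[i] > 0) sizes.push_back(count[i]);
  std::sort(sizes.rbegin(), sizes.rend());
  return sizes;
}

// initial inter-chain bond scan (nearest-first, saturating)
void initial_bonds(System& S) {
  const Params& p = S.p;
  if (p.eps_hb <= 0) return;
  double hb2 = p.hb_cutoff * p.hb_cutoff;
  std::vector<Cand> cands;
  for (int b = 0; b < S.n_beads; ++b) {
    if (p.ads_block && S.in_shell(S.x[b], S.y[b], S.z[b])) continue;
    int bc = S.chain_of(b);
    S.neighbours(S.x[b], S.y[b], S.z[b], [&](int j) {
      if (j <= b) return;
      if (S.chain_of(j) == bc) return;
      if (p.ads_block && S.in_shell(S.x[j], S.y[j], S.z[j])) return;
      double d2 = S.mdist2(S.x[b], S.y[b], S.z[b], S.x[j], S.y[j], S.z[j]);
      if (d2 > hb2) return;
      Cand c;
      c.d = std::sqrt(d2);
      c.a = b;
      c.b = j;
      c.c1 = S.chain_of(b); c.i1 = S.local_of(b);
      c.c2 = S.chain_of(j); c.i2 = S.local_of(j);
      cands.push_back(c);
    });
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.c1 != b.c1) return a.c1 < b.c1;
    if (a.i1 != b.i1) return a.i1 < b.i1;
    if (a.c2 != b.c2) return a.c2 < b.c2;
    return a.i2 < b.i2;
  });
  for (const Cand& c : cands)
    if (S.nbond[c.a] < p.max_bonds && S.nbond[c.b] < p.max_bonds)
      S.add_bond(c.a, c.b);
}

}  // namespace

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
List cpp_init_system(List cfg, NumericMatrix np_spec, int seed) {
  Params p = params_from_list(cfg);
  Rng rng(static_cast<uint64_t>(seed));
  int n_np = np_spec.nrow();

  System S;
  S.p = p;
  S.n_beads = p.n_chains * p.chain_len;
  S.x.assign(S.n_beads, 0.0);
  S.y.assign(S.n_beads, 0.0);
  S.z.assign(S.n_beads, 0.0);
  S.n_np = n_np;

  // nanoparticles: uniform placement without NP-NP overlap, larger first
  std::vector<int> order(n_np);
  for (int k = 0; k < n_np; ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return np_spec(a, 0) > np_spec(b, 0);
  });
  bool placed_all = n_np == 0;
  for (int attempt = 0; attempt < 200 && !placed_all; ++attempt) {
    S.npx.clear(); S.npy.clear(); S.npz.clear();
    S.npr.clear(); S.npeps.clear(); S.npshell.clear();
    placed_all = true;
    for (int oi = 0; oi < n_np && placed_all; ++oi) {
      int k = order[oi];
      double rk = np_spec(k, 0) / 2.0;
      bool ok = false;
      for (int t = 0; t < 2000 && !ok; ++t) {
        double cx = rng.unif() * p.L, cy = rng.unif() * p.L,
               cz = rng.unif() * p.L;
        ok = true;
        for (size_t j = 0; j < S.npx.size(); ++j) {
          double dmin = rk + S.npr[j];
          double dx = mind1(cx - S.npx[j], p.L), dy = mind1(cy - S.npy[j], p.L),
                 dz = mind1(cz - S.npz[j], p.L);
          if (dx * dx + dy * dy + dz * dz < dmin * dmin) {
            ok = false;
            break;
          }
        }
        if (ok) {
          S.npx.push_back(cx); S.npy.push_back(cy); S.npz.push_back(cz);
          S.npr.push_back(rk);
          S.npeps.push_back(np_spec(k, 1));
          S.npshell.push_back(np_spec(k, 2));
        }
      }
      if (!ok) placed_all = false;
    }
  }
  if (!placed_all)
    stop("density too high: could not place nanoparticles without overlap");

  S.partner.assign(static_cast<size_t>(S.n_beads) * p.max_bonds, -1);
  S.nbond.assign(S.n_beads, 0);
  S.init_cells();

  // chains as self-avoiding random walks
  double ev2 = p.bead_d * p.bead_d;
  int placed_chains = 0;
  for (int c = 0; c < p.n_chains; ++c) {
    int base = c * p.chain_len;
    bool chain_ok = false;
    for (int attempt = 0; attempt < 500 && !chain_ok; ++attempt) {
      int placed = 0;
      for (int i = 0; i < p.chain_len; ++i) {
        int g = base + i;
        bool ok = false;
        int tries = i == 0 ? 200 : 60;
        for (int t = 0; t < tries && !ok; ++t) {
          double cx, cy, cz;
          if (i == 0) {
            cx = rng.unif() * p.L;
            cy = rng.unif() * p.L;
            cz = rng.unif() * p.L;
          } else {
            double u[3];
            rng.unit_vec(u);
            cx = wrap1(S.x[g - 1] + p.bond_len * u[0], p.L);
            cy = wrap1(S.y[g - 1] + p.bond_len * u[1], p.L);
            cz = wrap1(S.z[g - 1] + p.bond_len * u[2], p.L);
          }
          if (S.inside_np(cx, cy, cz)) continue;
          bool clash = false;
          S.neighbours(cx, cy, cz, [&](int j) {
            if (clash) return;
            if (j >= base + placed) return;  // not placed yet (incl. self)
            if (j == g - 1) return;          // bonded neighbour
            if (S.mdist2(cx, cy, cz, S.x[j], S.y[j], S.z[j]) < ev2) clash = true;
          });
          if (clash) continue;
          S.x[g] = cx;
          S.y[g] = cy;
          S.z[g] = cz;
          S.cell_insert(g);
          ++placed;
          ok = true;
        }
        if (!ok) break;
      }
      if (placed == p.chain_len) {
        chain_ok = true;
      } else {
        for (int i = 0; i < placed; ++i) S.cell_remove(base + i);
      }
    }
    if (!chain_ok) {
      double frac = static_cast<double>(placed_chains) * p.chain_len *
                    (M_PI / 6.0) * p.bead_d * p.bead_d * p.bead_d /
                    (p.L * p.L * p.L);
      stop("density too high: placed %d of %d chains (bead volume fraction %.3f)",
           placed_chains, p.n_chains, frac);
    }
    ++placed_chains;
  }

  initial_bonds(S);
  S.energy = S.full_energy();

  NumericMatrix np_out(S.n_np, 6);
  for (int k = 0; k < S.n_np; ++k) {
    np_out(k, 0) = S.npx[k];
    np_out(k, 1) = S.npy[k];
    np_out(k, 2) = S.npz[k];
    np_out(k, 3) = 2.0 * S.npr[k];
    np_out(k, 4) = S.npeps[k];
    np_out(k, 5) = S.npshell[k];
  }
  colnames(np_out) = CharacterVector::create("x", "y", "z", "diameter",
                                             "adsorption_energy",
                                             "shell_thickness");
  return List::create(_["coords"] = coords_to_r(S), _["np"] = np_out,
                      _["bonds"] = bonds_to_r(S), _["energy"] = S.energy);
}

// [[Rcpp::export]]
List cpp_propose(List cfg, NumericMatrix coords, NumericMatrix np,
                 IntegerMatrix bonds, int seed) {
  System S = system_from_r(cfg, coords, np, bonds);
  Rng rng(static_cast<uint64_t>(seed));
  Proposal pr = propose(S, rng);
  int m = pr.beads.size();
  IntegerVector beads(m);
  NumericMatrix np_new(m, 3);
  for (int i = 0; i < m; ++i) {
    beads[i] = pr.beads[i] + 1;
    np_new(i, 0) = pr.newpos[i].x;
    np_new(i, 1) = pr.newpos[i].y;
    np_new(i, 2) = pr.newpos[i].z;
  }
  const char* names[4] = {"pivot", "crankshaft", "kink_jump", "translation"};
  return List::create(_["type"] = std::string(names[pr.type]),
                      _["chain"] = pr.chain + 1, _["beads"] = beads,
                      _["new_coords"] = np_new);
}

// [[Rcpp::export]]
List cpp_evaluate(List cfg, NumericMatrix coords, NumericMatrix np,
                  IntegerMatrix bonds, IntegerVector beads,
                  NumericMatrix new_coords) {
  System S = system_from_r(cfg, coords, np, bonds);
  Proposal pr;
  pr.type = 3;
  pr.chain = S.chain_of(beads[0] - 1);
  for (int i = 0; i < beads.size(); ++i) {
    pr.beads.push_back(beads[i] - 1);
    pr.newpos.push_back(
        Vec3{wrap1(new_coords(i, 0), S.p.L), wrap1(new_coords(i, 1), S.p.L),
             wrap1(new_coords(i, 2), S.p.L)});
  }
  std::vector<char> moved(S.n_beads, 0);
  EvalResult R = evaluate(S, pr, moved);
  auto pairs_to_r = [](const std::vector<std::pair<int, int>>& v) {
    IntegerMatrix m(v.size(), 2);
    for (size_t i = 0; i < v.size(); ++i) {
      m(i, 0) = std::min(v[i].first, v[i].second) + 1;
      m(i, 1) = std::max(v[i].first, v[i].second) + 1;
    }
    return m;
  };
  return List::create(
      _["feasible"] = R.feasible,
      _["delta_energy"] = R.feasible ? R.dE : R_PosInf,
      _["bonds_broken"] = pairs_to_r(R.broken),
      _["bonds_formed"] = pairs_to_r(R.formed));
}

// [[Rcpp::export]]
List cpp_run(List cfg, NumericMatrix coords, NumericMatrix np,
             IntegerMatrix bonds, int n_steps, int analysis_start,
             int snapshot_stride, int seed, bool debug_energy,
             bool cluster_np_contact) {
  System S = system_from_r(cfg, coords, np, bonds);
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<char> moved(S.n_beads, 0);
  std::vector<std::vector<int>> snaps;
  std::vector<int> snap_steps;
  long accepted = 0, proposed = 0;

  for (int s = 1; s <= n_steps; ++s) {
    Proposal pr = propose(S, rng);
    EvalResult R = evaluate(S, pr, moved);
    ++proposed;
    bool acc = false;
    if (R.feasible) {
      if (R.dE <= 0.0 || rng.unif() < std::exp(-R.dE)) acc = true;
    }
    if (acc) {
      commit(S, pr, R);
      ++accepted;
    }
    if (debug_energy && s % 1000 == 0) {
      double ef = S.full_energy();
      if (std::fabs(ef - S.energy) > 1e-8)
        stop("energy bookkeeping drift at step %d: incremental %.12f vs full %.12f",
             s, S.energy, ef);
    }
    if (s > analysis_start && (s - analysis_start) % snapshot_stride == 0) {
      snaps.push_back(cluster_sizes_sys(S, cluster_np_contact));
      snap_steps.push_back(s);
    }
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i)
    snap_list[i] = IntegerVector(snaps[i].begin(), snaps[i].end());
  return List::create(
      _["coords"] = coords_to_r(S), _["bonds"] = bonds_to_r(S),
      _["energy"] = S.energy, _["snapshots"] = snap_list,
      _["snapshot_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
      _["accepted"] = static_cast<double>(accepted),
      _["proposed"] = static_cast<double>(proposed));
}

// [[Rcpp::export]]
double cpp_full_energy(List cfg, NumericMatrix coords, NumericMatrix np,
                       IntegerMatrix bonds) {
  System S = system_from_r(cfg, coords, np, bonds);
  return S.full_energy();
}

// Cluster over an explicit bond list (no registry), so arbitrary bond
// graphs — including ones exceeding the per-bead valence — cluster exactly.
// [[Rcpp::export]]
IntegerVector cpp_cluster_sizes(List cfg, NumericMatrix coords,
                                NumericMatrix np, IntegerMatrix bonds,
                                bool np_contact) {
  Params p = params_from_list(cfg);
  int n = p.n_chains;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int i = 0; i < bonds.nrow(); ++i) {
    unite((bonds(i, 0) - 1) / p.chain_len, (bonds(i, 1) - 1) / p.chain_len);
  }
  if (np_contact && np.nrow() > 0) {
    std::vector<int> anchor(np.nrow(), -1);
    for (int b = 0; b < coords.nrow(); ++b) {
      for (int k = 0; k < np.nrow(); ++k) {
        double dx = mind1(coords(b, 0) - np(k, 0), p.L),
               dy = mind1(coords(b, 1) - np(k, 1), p.L),
               dz = mind1(coords(b, 2) - np(k, 2), p.L);
        double r2 = dx * dx + dy * dy + dz * dz;
        double R = np(k, 3) / 2.0, ro = R + np(k, 5);
        if (r2 >= R * R && r2 < ro * ro) {
          int c = b / p.chain_len;
          if (anchor[k] < 0) anchor[k] = c; else unite(anchor[k], c);
        }
      }
    }
  }
  std::vector<int> count(n, 0);
  for (int i = 0; i < n; ++i) ++count[find(i)];
  std::vector<int> sizes;
  for (int i = 0; i < n; ++i)
    if (count[i] > 0) sizes.push_back(count[i]);
  std::sort(sizes.rbegin(), sizes.rend());
  return IntegerVector(sizes.begin(), sizes.end());
}

// [[Rcpp::export]]
List cpp_check_state(List cfg, NumericMatrix coords, NumericMatrix np,
                     IntegerMatrix bonds) {
  System S = system_from_r(cfg, coords, np, bonds);
  const Params& p = S.p;
  std::vector<std::string> problems;
  double ev2 = p.bead_d * p.bead_d * (1.0 - 1e-9);
  double hb2 = p.hb_cutoff * p.hb_cutoff * (1.0 + 1e-9);

  for (int b = 0; b < S.n_beads; ++b) {
    if (S.inside_np(S.x[b], S.y[b], S.z[b])) {
      problems.push_back("bead centre inside a nanoparticle");
      break;
    }
  }
  bool ev_ok = true;
  for (int b = 0; b < S.n_beads && ev_ok; ++b) {
    int bc = S.chain_of(b), bl = S.local_of(b);
    S.neighbours(S.x[b], S.y[b], S.z[b], [&](int j) {
      if (!ev_ok || j <= b) return;
      if (S.chain_of(j) == bc && std::abs(S.local_of(j) - bl) == 1) return;
      if (S.mdist2(S.x[b], S.y[b], S.z[b], S.x[j], S.y[j], S.z[j]) < ev2)
        ev_ok = false;
    });
  }
  if (!ev_ok) problems.push_back("excluded-volume overlap between beads");

  for (int c = 0; c < p.n_chains; ++c)
    for (int i = 1; i < p.chain_len; ++i) {
      int g = c * p.chain_len + i;
      double d = std::sqrt(
          S.mdist2(S.x[g], S.y[g], S.z[g], S.x[g - 1], S.y[g - 1], S.z[g - 1]));
      if (std::fabs(d - p.bond_len) > 1e-6) {
        problems.push_back("backbone bond length drift");
        c = p.n_chains;
        break;
      }
    }

  for (int a = 0; a < S.n_beads; ++a) {
    int cnt = 0;
    for (int s = 0; s < p.max_bonds; ++s) {
      int b = S.partner[a * p.max_bonds + s];
      if (b < 0) continue;
      ++cnt;
      if (S.chain_of(a) == S.chain_of(b)) {
        problems.push_back("intra-chain bond in registry");
      }
      if (!S.bonded(b, a)) problems.push_back("asymmetric bond registry");
      if (S.mdist2(S.x[a], S.y[a], S.z[a], S.x[b], S.y[b], S.z[b]) > hb2)
        problems.push_back("registered bond beyond cutoff");
    }
    if (cnt > p.max_bonds) problems.push_back("bond saturation exceeded");
    if (!problems.empty() && problems.size() > 8) break;
  }

  double ef = S.full_energy();
  return List::create(_["ok"] = problems.empty(),
                      _["problems"] = wrap(problems),
                      _["energy_recomputed"] = ef);
}
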