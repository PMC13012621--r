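// Rigid-body Brownian dynamics stepper for clathrin / AP-2 self-assembly.
//
// One step = (1) dissociation tests over all bonds, (2) association tests
// (implicit AP-2 layer first, then clathrin-clathrin candidates in
// RNG-shuffled order), (3) diffusion of clusters with no frozen member,
// (4) per-axis reflection at the domain walls, (5) excluded-volume
// resampling of conflicting moves. Molecules taking part in a reaction are
// frozen for the rest of the step. Bound AP-2 is a rigid zero-volume
// appendage directly beneath the host clathrin's AP-2 site; unbound AP-2 is
// an implicit well-mixed membrane pool.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const double kTol = 1e-9;

// ---------------------------------------------------------------- RNG ----
struct Xoshiro {
  uint64_t s[4];
  bool have_spare;
  double spare;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) : have_spare(false), spare(0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  double norm() {  // Marsaglia polar method with cached spare
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
  int randint(int n) {  // 0..n-1
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  template <typename T>
  void shuffle(std::vector<T> &v) {
    for (int i = (int)v.size() - 1; i > 0; i--) {
      int j = randint(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

// --------------------------------------------------------- quaternions ----
struct Quat {
  double w, x, y, z;
};

inline Quat qmul(const Quat &a, const Quat &b) {
  Quat q;
  q.w = a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z;
  q.x = a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y;
  q.y = a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x;
  q.z = a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w;
  return q;
}
inline void qnormalize(Quat &q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= n;
  q.x /= n;
  q.y /= n;
  q.z /= n;
}
inline void qtomat(const Quat &q, double R[3][3]) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R[0][0] = 1 - 2 * (y * y + z * z);
  R[0][1] = 2 * (x * y - w * z);
  R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z);
  R[1][1] = 1 - 2 * (x * x + z * z);
  R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y);
  R[2][1] = 2 * (y * z + w * x);
  R[2][2] = 1 - 2 * (x * x + y * y);
}
inline Quat qfrommat(const double R[3][3]) {
  Quat q;
  double tr = R[0][0] + R[1][1] + R[2][2];
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2;
    q.w = 0.25 * s;
    q.x = (R[2][1] - R[1][2]) / s;
    q.y = (R[0][2] - R[2][0]) / s;
    q.z = (R[1][0] - R[0][1]) / s;
  } else if (R[0][0] > R[1][1] && R[0][0] > R[2][2]) {
    double s = std::sqrt(1.0 + R[0][0] - R[1][1] - R[2][2]) * 2;
    q.w = (R[2][1] - R[1][2]) / s;
    q.x = 0.25 * s;
    q.y = (R[0][1] + R[1][0]) / s;
    q.z = (R[0][2] + R[2][0]) / s;
  } else if (R[1][1] > R[2][2]) {
    double s = std::sqrt(1.0 + R[1][1] - R[0][0] - R[2][2]) * 2;
    q.w = (R[0][2] - R[2][0]) / s;
    q.x = (R[0][1] + R[1][0]) / s;
    q.y = 0.25 * s;
    q.z = (R[1][2] + R[2][1]) / s;
  } else {
    double s = std::sqrt(1.0 + R[2][2] - R[0][0] - R[1][1]) * 2;
    q.w = (R[1][0] - R[0][1]) / s;
    q.x = (R[0][2] + R[2][0]) / s;
    q.y = (R[1][2] + R[2][1]) / s;
    q.z = 0.25 * s;
  }
  qnormalize(q);
  return q;
}
inline Quat qaxis(int axis, double angle) {
  Quat q;
  double c = std::cos(angle / 2), s = std::sin(angle / 2);
  q.w = c;
  q.x = axis == 0 ? s : 0;
  q.y = axis == 1 ? s : 0;
  q.z = axis == 2 ? s : 0;
  return q;
}

struct Vec3 {
  double x, y, z;
};
inline Vec3 rotate(const double R[3][3], const Vec3 &v) {
  Vec3 o;
  o.x = R[0][0] * v.x + R[0][1] * v.y + R[0][2] * v.z;
  o.y = R[1][0] * v.x + R[1][1] * v.y + R[1][2] * v.z;
  o.z = R[2][0] * v.x + R[2][1] * v.y + R[2][2] * v.z;
  return o;
}

// ------------------------------------------------------------- segment ----
struct Segment {
  int start_step;
  double p_cc3_gated, p_cc2_gated, p_cc3_free, p_cc2_free;
  double p_off_cc, p_off_ap2;
  double k_ap2_2d;  // nm^2/us, for the implicit pool
  double d_clat_t[3], d_clat_r[3];
  double inv_clat_t[3], cr_clat_r[3];  // 1/D and D_R^(-1/3), precomputed
  int n_ap2_target;
};

// -------------------------------------------------------------- engine ----
struct Engine {
  int n;         // clathrins
  double L, dt, sigma, capture_h, excl, excl2;
  double leg_off[3][3];  // body-frame leg sites (row per leg)
  double ap2_drop;       // AP-2 site depth below center
  double leg_radius, bond_gap;
  double d_ap2_t[3], d_ap2_r[3];
  double inv_ap2_t[3], cr_ap2_r[3];
  int max_retries;
  bool pair_mode, record_events;
  int validate_every;

  std::vector<Vec3> pos;
  std::vector<Quat> quat;
  std::vector<int> legp;   // n*3, partner molecule (-1 free)
  std::vector<int> legs;   // n*3, partner site (0..2)
  std::vector<char> hasap2;
  int ap2_free, ap2_total, ap2_pending;
  double time_us;

  std::vector<Segment> segs;
  int cur_seg;

  // scratch (allocated once)
  std::vector<int> parent, csize;
  std::vector<char> cmembrane, frozen;
  std::vector<Vec3> sites;  // n*4 world sites (legs 1-3, ap2)
  std::vector<Vec3> ppos;   // proposals
  std::vector<Quat> pquat;
  std::vector<int> roots, rindex, cstart, cmem, molcluster;
  std::vector<char> movable, conflict;
  std::vector<double> cDT, cDR;

  Xoshiro rng;
  long ev_counts[4];  // bind_cc, unbind_cc, bind_ap2, unbind_ap2
  std::vector<int> ev_log;  // step, kind, a, sa, b, sb (0-based mol ids)

  Engine(uint64_t seed) : rng(seed) {
    ev_counts[0] = ev_counts[1] = ev_counts[2] = ev_counts[3] = 0;
  }

  // ---- union-find ----
  int findroot(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    a = findroot(a);
    b = findroot(b);
    if (a != b) parent[b] = a;
  }
  void build_clusters() {
    for (int i = 0; i < n; i++) parent[i] = i;
    for (int i = 0; i < n; i++)
      for (int l = 0; l < 3; l++)
        if (legp[i * 3 + l] >= 0) unite(i, legp[i * 3 + l]);
    for (int i = 0; i < n; i++) {
      csize[i] = 0;
      cmembrane[i] = 0;
    }
    for (int i = 0; i < n; i++) {
      int r = findroot(i);
      csize[r]++;
      if (hasap2[i]) cmembrane[r] = 1;
    }
  }

  void site_coords(int i) {
    double R[3][3];
    qtomat(quat[i], R);
    for (int l = 0; l < 3; l++) {
      Vec3 b = {leg_off[l][0], leg_off[l][1], leg_off[l][2]};
      Vec3 w = rotate(R, b);
      sites[i * 4 + l].x = pos[i].x + w.x;
      sites[i * 4 + l].y = pos[i].y + w.y;
      sites[i * 4 + l].z = pos[i].z + w.z;
    }
    Vec3 b = {0, 0, -ap2_drop};
    Vec3 w = rotate(R, b);
    sites[i * 4 + 3].x = pos[i].x + w.x;
    sites[i * 4 + 3].y = pos[i].y + w.y;
    sites[i * 4 + 3].z = pos[i].z + w.z;
  }
  void all_site_coords() {
    for (int i = 0; i < n; i++) site_coords(i);
  }

  bool in_box(double v) { return v >= -kTol && v <= L + kTol; }
  bool mol_pose_in_box(const Vec3 &p, const Quat &q) {
    if (!in_box(p.x) || !in_box(p.y) || !in_box(p.z)) return false;
    double R[3][3];
    qtomat(q, R);
    for (int l = 0; l < 4; l++) {
      Vec3 b;
      if (l < 3) {
        b.x = leg_off[l][0];
        b.y = leg_off[l][1];
        b.z = leg_off[l][2];
      } else {
        b.x = 0;
        b.y = 0;
        b.z = -ap2_drop;
      }
      Vec3 w = rotate(R, b);
      if (!in_box(p.x + w.x) || !in_box(p.y + w.y) || !in_box(p.z + w.z))
        return false;
    }
    return true;
  }

  void log_event(int step, int kind, int a, int sa, int b, int sb) {
    ev_counts[kind - 1]++;
    if (record_events) {
      ev_log.push_back(step);
      ev_log.push_back(kind);
      ev_log.push_back(a);
      ev_log.push_back(sa);
      ev_log.push_back(b);
      ev_log.push_back(sb);
    }
  }

  // flatten molecule i onto the membrane preserving its in-plane heading
  void flat_pose(int i, Vec3 &p, Quat &q) {
    double R[3][3];
    qtomat(quat[i], R);
    double bx = R[0][0], by = R[1][0];  // world image of body x-axis
    double nrm = std::sqrt(bx * bx + by * by);
    double xh[3];
    if (nrm < 1e-9) {
      xh[0] = 1;
      xh[1] = 0;
    } else {
      xh[0] = bx / nrm;
      xh[1] = by / nrm;
    }
    xh[2] = 0;
    double Rn[3][3];
    Rn[0][0] = xh[0];
    Rn[1][0] = xh[1];
    Rn[2][0] = 0;
    Rn[0][1] = -xh[1];
    Rn[1][1] = xh[0];
    Rn[2][1] = 0;
    Rn[0][2] = 0;
    Rn[1][2] = 0;
    Rn[2][2] = 1;
    q = qfrommat(Rn);
    p.x = pos[i].x;
    p.y = pos[i].y;
    p.z = ap2_drop;
  }

  // bound pose of molecule b (via its leg lb) head-to-head at site la of a
  void bound_pose(int a, int la, int lb, Vec3 &pb, Quat &qb) {
    double Ra[3][3];
    qtomat(quat[a], Ra);
    const Vec3 &sa = sites[a * 4 + la];
    double ux = sa.x - pos[a].x, uy = sa.y - pos[a].y, uz = sa.z - pos[a].z;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un;
    uy /= un;
    uz /= un;
    double nx = Ra[0][2], ny = Ra[1][2], nz = Ra[2][2];
    double d = 2 * leg_radius + bond_gap;
    pb.x = pos[a].x + d * ux;
    pb.y = pos[a].y + d * uy;
    pb.z = pos[a].z + d * uz;
    // base frame: body x -> -u, body z -> n
    double xb[3] = {-ux, -uy, -uz};
    double zb[3] = {nx, ny, nz};
    double yb[3] = {zb[1] * xb[2] - zb[2] * xb[1],
                    zb[2] * xb[0] - zb[0] * xb[2],
                    zb[0] * xb[1] - zb[1] * xb[0]};
    // rotate base frame so that leg lb (at angle th in body plane) is the
    // one pointing along -u
    double th = lb * 2.0 * M_PI / 3.0;
    double c = std::cos(th), s = std::sin(th);
    double Rb[3][3];  // base * Rz(-th): leg lb maps onto -u
    for (int r = 0; r < 3; r++) {
      Rb[r][0] = xb[r] * c - yb[r] * s;
      Rb[r][1] = xb[r] * s + yb[r] * c;
      Rb[r][2] = zb[r];
    }
    // Rb * (cos th, sin th, 0) = -u as required
    qb = qfrommat(Rb);
  }

  const Segment &seg() { return segs[cur_seg]; }

  void enter_segment(int s) {
    cur_seg = s;
    int target = segs[s].n_ap2_target;
    if (target >= 0 && target != ap2_total) {
      int delta = target - ap2_total;
      if (delta > 0) {
        ap2_free += delta;
        ap2_total += delta;
      } else {
        int take = std::min(ap2_free, -delta);
        ap2_free -= take;
        ap2_total -= take;
        ap2_pending += (-delta - take);  // removed on future unbinding
      }
    }
  }

  // -------------------------------------------------------------- step ----
  void step(int step_idx) {
    if (cur_seg + 1 < (int)segs.size() &&
        step_idx >= segs[cur_seg + 1].start_step)
      enter_segment(cur_seg + 1);
    const Segment &sg = seg();

    for (int i = 0; i < n; i++) frozen[i] = 0;

    // ---- 1. dissociations ----
    for (int i = 0; i < n; i++) {
      for (int l = 0; l < 3; l++) {
        int j = legp[i * 3 + l];
        if (j > i && !frozen[i] && !frozen[j]) {
          if (rng.unif() < sg.p_off_cc) {
            int sl = legs[i * 3 + l];
            legp[i * 3 + l] = -1;
            legp[j * 3 + sl] = -1;
            frozen[i] = 1;
            frozen[j] = 1;
            log_event(step_idx, 2, i, l, j, sl);
          }
        }
      }
    }
    for (int i = 0; i < n; i++) {
      if (hasap2[i] && !frozen[i]) {
        if (rng.unif() < sg.p_off_ap2) {
          hasap2[i] = 0;
          if (ap2_pending > 0) {
            ap2_pending--;
            ap2_total--;
          } else {
            ap2_free++;
          }
          frozen[i] = 1;
          log_event(step_idx, 4, i, 3, -1, -1);
        }
      }
    }

    // ---- 2. associations ----
    build_clusters();
    all_site_coords();

    // 2a. implicit AP-2 layer
    if (!pair_mode && ap2_free > 0 && sg.k_ap2_2d > 0) {
      std::vector<int> cand;
      for (int i = 0; i < n; i++) {
        if (frozen[i] || hasap2[i]) continue;
        int r = findroot(i);
        if (csize[r] > 1 && !cmembrane[r]) continue;  // free multimer
        double h = sites[i * 4 + 3].z;
        if (h >= -kTol && h <= capture_h + kTol) cand.push_back(i);
      }
      rng.shuffle(cand);
      for (size_t c = 0; c < cand.size(); c++) {
        if (ap2_free <= 0) break;
        int i = cand[c];
        if (frozen[i]) continue;
        double rho = (double)ap2_free / (L * L);
        double p = 1.0 - std::exp(-sg.k_ap2_2d * rho * dt);
        if (rng.unif() >= p) continue;
        int r = findroot(i);
        if (cmembrane[r]) {
          // already flat on the membrane; AP-2 appears beneath the site
          hasap2[i] = 1;
          ap2_free--;
          frozen[i] = 1;
          log_event(step_idx, 3, i, 3, -1, -1);
        } else {
          // free monomer: flatten onto the membrane
          Vec3 p2;
          Quat q2;
          flat_pose(i, p2, q2);
          if (!mol_pose_in_box(p2, q2)) continue;
          bool ok = true;
          for (int m = 0; m < n && ok; m++) {
            if (m == i) continue;
            double dx = p2.x - pos[m].x, dy = p2.y - pos[m].y,
                   dz = p2.z - pos[m].z;
            if (dx * dx + dy * dy + dz * dz < excl2 * (1 - 1e-12)) ok = false;
          }
          if (!ok) continue;
          pos[i] = p2;
          quat[i] = q2;
          site_coords(i);
          hasap2[i] = 1;
          cmembrane[r] = 1;
          ap2_free--;
          frozen[i] = 1;
          log_event(step_idx, 3, i, 3, -1, -1);
        }
      }
    }

    // 2b. clathrin-clathrin
    bool any_cc = sg.p_cc3_gated > 0 || sg.p_cc3_free > 0;
    if (any_cc) {
      double cutoff = 2 * leg_radius + sigma + 1.0;
      double cutoff2 = cutoff * cutoff;
      std::vector<int> cand;  // packed i, la, j, lb
      for (int i = 0; i < n; i++) {
        for (int j = i + 1; j < n; j++) {
          double dx = pos[i].x - pos[j].x, dy = pos[i].y - pos[j].y,
                 dz = pos[i].z - pos[j].z;
          if (dx * dx + dy * dy + dz * dz > cutoff2) continue;
          int ri = findroot(i), rj = findroot(j);
          if (ri == rj) continue;
          if (!pair_mode && sg.p_cc3_free <= 0 && !cmembrane[ri] &&
              !cmembrane[rj])
            continue;  // gated to zero at candidate-scan time
          for (int la = 0; la < 3; la++) {
            if (legp[i * 3 + la] >= 0) continue;
            const Vec3 &sa = sites[i * 4 + la];
            for (int lb = 0; lb < 3; lb++) {
              if (legp[j * 3 + lb] >= 0) continue;
              const Vec3 &sb = sites[j * 4 + lb];
              double ex = sa.x - sb.x, ey = sa.y - sb.y, ez = sa.z - sb.z;
              if (ex * ex + ey * ey + ez * ez <= sigma * sigma) {
                cand.push_back(i);
                cand.push_back(la);
                cand.push_back(j);
                cand.push_back(lb);
              }
            }
          }
        }
      }
      int ncand = (int)cand.size() / 4;
      if (ncand > 0) {
        std::vector<int> order(ncand);
        for (int k = 0; k < ncand; k++) order[k] = k;
        rng.shuffle(order);
        for (int k = 0; k < ncand; k++) {
          int i = cand[order[k] * 4], la = cand[order[k] * 4 + 1];
          int j = cand[order[k] * 4 + 2], lb = cand[order[k] * 4 + 3];
          if (frozen[i] || frozen[j]) continue;
          if (legp[i * 3 + la] >= 0 || legp[j * 3 + lb] >= 0) continue;
          int ri = findroot(i), rj = findroot(j);
          if (ri == rj) continue;  // no intra-cluster ring closure
          if (pair_mode && (csize[ri] > 1 || csize[rj] > 1)) continue;
          bool mi = cmembrane[ri], mj = cmembrane[rj];
          double p;
          if (pair_mode) {
            p = sg.p_cc3_gated;
          } else if (mi || mj) {
            p = (mi && mj) ? sg.p_cc2_gated : sg.p_cc3_gated;
          } else {
            p = sg.p_cc3_free;
          }
          if (p <= 0) continue;
          if (rng.unif() >= p) continue;
          if (attempt_cc_bind(i, la, j, lb, ri, rj, mi, mj)) {
            log_event(step_idx, 1, i, la, j, lb);
          }
        }
      }
    }

    // ---- 3-5. diffusion with reflection + excluded-volume resampling ----
    diffuse();

    time_us += dt;
  }

  // move cluster of b so that site lb of b binds head-to-head to site la of
  // a; returns false (state untouched) if the pose is invalid
  bool attempt_cc_bind(int i, int la, int j, int lb, int ri, int rj,
                       bool mi, bool mj) {
    // choose the mobile side: never move a membrane cluster to meet a free
    // one; otherwise move the smaller cluster
    int anchor = i, sa = la, mob = j, sb = lb, rmob = rj;
    bool swap = false;
    if (mi != mj) {
      swap = mj;  // j's side is membrane-bound -> move i's side
    } else {
      swap = csize[ri] < csize[rj];
    }
    if (swap) {
      anchor = j;
      sa = lb;
      mob = i;
      sb = la;
      rmob = ri;
    }

    Vec3 pb;
    Quat qb;
    bound_pose(anchor, sa, sb, pb, qb);

    // rigid transform of the mobile cluster: rotation about mob's center
    double Rold[3][3], Rnew[3][3];
    qtomat(quat[mob], Rold);
    qtomat(qb, Rnew);
    double Rd[3][3];  // Rnew * Rold^T
    for (int r = 0; r < 3; r++)
      for (int c = 0; c < 3; c++)
        Rd[r][c] = Rnew[r][0] * Rold[c][0] + Rnew[r][1] * Rold[c][1] +
                   Rnew[r][2] * Rold[c][2];
    Quat qd = qfrommat(Rd);

    std::vector<int> mem;
    for (int m = 0; m < n; m++)
      if (findroot(m) == rmob) mem.push_back(m);

    std::vector<Vec3> np(mem.size());
    std::vector<Quat> nq(mem.size());
    for (size_t k = 0; k < mem.size(); k++) {
      int m = mem[k];
      if (m == mob) {
        np[k] = pb;
        nq[k] = qb;
        continue;
      }
      Vec3 rel = {pos[m].x - pos[mob].x, pos[m].y - pos[mob].y,
                  pos[m].z - pos[mob].z};
      Vec3 rr = rotate(Rd, rel);
      np[k].x = pb.x + rr.x;
      np[k].y = pb.y + rr.y;
      np[k].z = pb.z + rr.z;
      nq[k] = qmul(qd, quat[m]);
      qnormalize(nq[k]);
    }

    // validity: inside the closed domain, no excluded-volume overlap
    for (size_t k = 0; k < mem.size(); k++)
      if (!mol_pose_in_box(np[k], nq[k])) return false;
    std::vector<char> inmob(n, 0);
    for (size_t k = 0; k < mem.size(); k++) inmob[mem[k]] = 1;
    for (size_t k = 0; k < mem.size(); k++) {
      for (int m = 0; m < n; m++) {
        if (inmob[m]) continue;
        double dx = np[k].x - pos[m].x, dy = np[k].y - pos[m].y,
               dz = np[k].z - pos[m].z;
        if (dx * dx + dy * dy + dz * dz < excl2 * (1 - 1e-12)) return false;
      }
    }

    // commit
    for (size_t k = 0; k < mem.size(); k++) {
      pos[mem[k]] = np[k];
      quat[mem[k]] = nq[k];
      site_coords(mem[k]);
    }
    legp[i * 3 + la] = j;
    legs[i * 3 + la] = lb;
    legp[j * 3 + lb] = i;
    legs[j * 3 + lb] = la;
    unite(i, j);
    int r = findroot(i);
    cmembrane[r] = cmembrane[ri] || cmembrane[rj];
    csize[r] = csize[ri] + csize[rj];
    frozen[i] = 1;
    frozen[j] = 1;
    return true;
  }

  // compose the cluster diffusion spec from its members
  void cluster_diffusion(const int *mem, int nc, const Segment &sg,
                         double dT[3], double dR[3]) {
    int na = 0;
    for (int k = 0; k < nc; k++) na += hasap2[mem[k]] ? 1 : 0;
    if (nc == 1 && na == 0) {  // free monomer fast path
      for (int a = 0; a < 3; a++) {
        dT[a] = sg.d_clat_t[a];
        dR[a] = sg.d_clat_r[a];
      }
      return;
    }
    for (int a = 0; a < 3; a++) {
      bool zt = sg.d_clat_t[a] <= 0 || (na > 0 && d_ap2_t[a] <= 0);
      bool zr = sg.d_clat_r[a] <= 0 || (na > 0 && d_ap2_r[a] <= 0);
      if (zt) {
        dT[a] = 0;
      } else {
        double it = nc * sg.inv_clat_t[a] + na * inv_ap2_t[a];
        dT[a] = 1.0 / it;
      }
      if (zr) {
        dR[a] = 0;
      } else {
        double ir = nc * sg.cr_clat_r[a] + na * cr_ap2_r[a];
        dR[a] = 1.0 / (ir * ir * ir);
      }
    }
  }

  // draw a proposed rigid move for one cluster and reflect it into the box
  void propose_cluster(const int *mem, int nm, const double dT[3],
                       const double dR[3]) {
    double cx = 0, cy = 0, cz = 0;
    for (int k = 0; k < nm; k++) {
      cx += pos[mem[k]].x;
      cy += pos[mem[k]].y;
      cz += pos[mem[k]].z;
    }
    cx /= nm;
    cy /= nm;
    cz /= nm;

    double disp[3];
    for (int a = 0; a < 3; a++)
      disp[a] = dT[a] > 0 ? std::sqrt(2 * dT[a] * dt) * rng.norm() : 0.0;
    double ang[3];
    for (int a = 0; a < 3; a++)
      ang[a] = dR[a] > 0 ? std::sqrt(2 * dR[a] * dt) * rng.norm() : 0.0;

    // rotation about centroid: Rz * Ry * Rx (identity factors skipped)
    Quat qd = {1, 0, 0, 0};
    bool rot = false;
    if (ang[0] != 0) {
      qd = qaxis(0, ang[0]);
      rot = true;
    }
    if (ang[1] != 0) {
      qd = rot ? qmul(qaxis(1, ang[1]), qd) : qaxis(1, ang[1]);
      rot = true;
    }
    if (ang[2] != 0) {
      qd = rot ? qmul(qaxis(2, ang[2]), qd) : qaxis(2, ang[2]);
      rot = true;
    }
    double Rd[3][3];
    if (rot) qtomat(qd, Rd);

    for (int k = 0; k < nm; k++) {
      int m = mem[k];
      Vec3 p = pos[m];
      if (rot) {
        Vec3 rel = {p.x - cx, p.y - cy, p.z - cz};
        Vec3 rr = rotate(Rd, rel);
        p.x = cx + rr.x;
        p.y = cy + rr.y;
        p.z = cz + rr.z;
        pquat[m] = qmul(qd, quat[m]);
        qnormalize(pquat[m]);
      } else {
        pquat[m] = quat[m];
      }
      p.x += disp[0];
      p.y += disp[1];
      p.z += disp[2];
      ppos[m] = p;
    }

    // reflect: per axis, translate the whole cluster by the mirror
    // displacement of the offending extreme (monomer: 2L - pos / -pos)
    double shift[3] = {0, 0, 0};
    for (int a = 0; a < 3; a++) {
      double lo = 1e300, hi = -1e300;
      for (int k = 0; k < nm; k++) {
        double v = a == 0 ? ppos[mem[k]].x : (a == 1 ? ppos[mem[k]].y
                                                     : ppos[mem[k]].z);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      double t = 0;
      bool ok = true;
      for (int it = 0; it < 64; it++) {
        if (lo + t < -kTol) {
          t = -2 * lo - t;
        } else if (hi + t > L + kTol) {
          t = 2 * L - 2 * hi - t;
        } else {
          ok = true;
          break;
        }
        ok = false;
      }
      if (!ok) t = 0;  // cluster wider than the box: keep and let overlap
                       // resolution / next step handle it (cannot occur at
                       // the shipped geometry and domain sizes)
      shift[a] = t;
    }
    if (shift[0] != 0 || shift[1] != 0 || shift[2] != 0) {
      for (int k = 0; k < nm; k++) {
        ppos[mem[k]].x += shift[0];
        ppos[mem[k]].y += shift[1];
        ppos[mem[k]].z += shift[2];
      }
    }
  }

  void diffuse() {
    build_clusters();
    const Segment &sg = seg();

    // flat member lists, counting-sorted by cluster root
    roots.clear();
    for (int i = 0; i < n; i++) {
      rindex[i] = -1;
      if (findroot(i) == i) {
        rindex[i] = (int)roots.size();
        roots.push_back(i);
      }
    }
    int nc = (int)roots.size();
    for (int c = 0; c <= nc; c++) cstart[c] = 0;
    for (int i = 0; i < n; i++) {
      molcluster[i] = rindex[findroot(i)];
      cstart[molcluster[i] + 1]++;
    }
    for (int c = 0; c < nc; c++) cstart[c + 1] += cstart[c];
    {
      std::vector<int> &fill = rindex;  // reuse as fill cursor
      for (int c = 0; c < nc; c++) fill[c] = cstart[c];
      for (int i = 0; i < n; i++) cmem[fill[molcluster[i]]++] = i;
    }

    for (int c = 0; c < nc; c++) movable[c] = 1;
    for (int i = 0; i < n; i++)
      if (frozen[i]) movable[molcluster[i]] = 0;

    for (int i = 0; i < n; i++) {
      ppos[i] = pos[i];
      pquat[i] = quat[i];
    }
    for (int c = 0; c < nc; c++) {
      if (!movable[c]) continue;
      const int *mem = &cmem[cstart[c]];
      int nm = cstart[c + 1] - cstart[c];
      cluster_diffusion(mem, nm, sg, &cDT[c * 3], &cDR[c * 3]);
      propose_cluster(mem, nm, &cDT[c * 3], &cDR[c * 3]);
    }

    // excluded-volume resampling
    double thr = excl2 * (1 - 1e-12);
    int retry = 0;
    while (true) {
      bool any = false;
      for (int c = 0; c < nc; c++) conflict[c] = 0;
      for (int i = 0; i < n; i++) {
        for (int j = i + 1; j < n; j++) {
          if (molcluster[i] == molcluster[j]) continue;
          double dx = ppos[i].x - ppos[j].x, dy = ppos[i].y - ppos[j].y,
                 dz = ppos[i].z - ppos[j].z;
          if (dx * dx + dy * dy + dz * dz < thr) {
            any = true;
            if (movable[molcluster[i]]) conflict[molcluster[i]] = 1;
            if (movable[molcluster[j]]) conflict[molcluster[j]] = 1;
          }
        }
      }
      if (!any) break;
      if (retry < max_retries) {
        retry++;
        for (int c = 0; c < nc; c++)
          if (conflict[c])
            propose_cluster(&cmem[cstart[c]], cstart[c + 1] - cstart[c],
                            &cDT[c * 3], &cDR[c * 3]);
      } else {
        // zero-move fallback for every cluster still in conflict; repeat
        // until clean (terminates: the pre-move state is overlap-free)
        bool reverted = false;
        for (int c = 0; c < nc; c++) {
          if (conflict[c]) {
            for (int k = cstart[c]; k < cstart[c + 1]; k++) {
              int m = cmem[k];
              ppos[m] = pos[m];
              pquat[m] = quat[m];
            }
            movable[c] = 0;
            reverted = true;
          }
        }
        if (!reverted) break;
      }
    }

    for (int i = 0; i < n; i++) {
      pos[i] = ppos[i];
      quat[i] = pquat[i];
    }
  }

  void validate(int step_idx) {
    for (int i = 0; i < n; i++) {
      if (!in_box(pos[i].x) || !in_box(pos[i].y) || !in_box(pos[i].z))
        stop("invariant violation at step %d: molecule %d outside the domain",
             step_idx, i + 1);
    }
    double thr = excl2 * (1 - 1e-9);
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double dx = pos[i].x - pos[j].x, dy = pos[i].y - pos[j].y,
               dz = pos[i].z - pos[j].z;
        if (dx * dx + dy * dy + dz * dz < thr)
          stop("invariant violation at step %d: clathrins %d and %d overlap",
               step_idx, i + 1, j + 1);
      }
    for (int i = 0; i < n; i++)
      for (int l = 0; l < 3; l++) {
        int j = legp[i * 3 + l];
        if (j >= 0) {
          int sl = legs[i * 3 + l];
          if (legp[j * 3 + sl] != i || legs[j * 3 + sl] != l)
            stop("invariant violation at step %d: asymmetric bond graph",
                 step_idx);
        }
      }
    int bound = 0;
    for (int i = 0; i < n; i++) bound += hasap2[i] ? 1 : 0;
    if (ap2_free < 0 || bound + ap2_free != ap2_total)
      stop("invariant violation at step %d: AP-2 pool accounting", step_idx);
  }
};

}  // namespace

// [[Rcpp::export]]
List engine_run_cpp(NumericMatrix pos0, NumericMatrix quat0,
                    IntegerMatrix leg_partner, IntegerMatrix leg_partner_site,
                    IntegerVector ap2_bound, int ap2_free, int ap2_total,
                    int ap2_pending, double time0, List cfg) {
  Engine E((uint64_t)(double)cfg["seed"]);
  E.n = pos0.nrow();
  E.L = cfg["L"];
  E.dt = cfg["dt"];
  E.sigma = cfg["sigma"];
  E.capture_h = cfg["capture_height"];
  E.excl = cfg["excl"];
  E.excl2 = E.excl * E.excl;
  NumericMatrix lo = cfg["leg_off"];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 3; c++) E.leg_off[r][c] = lo(r, c);
  E.ap2_drop = cfg["ap2_drop"];
  E.leg_radius = cfg["leg_radius"];
  E.bond_gap = cfg["bond_gap"];
  NumericVector at = cfg["d_ap2_trans"], ar = cfg["d_ap2_rot"];
  for (int a = 0; a < 3; a++) {
    E.d_ap2_t[a] = at[a];
    E.d_ap2_r[a] = ar[a];
    E.inv_ap2_t[a] = at[a] > 0 ? 1.0 / at[a] : 0.0;
    E.cr_ap2_r[a] = ar[a] > 0 ? std::pow(ar[a], -1.0 / 3.0) : 0.0;
  }
  E.max_retries = cfg["max_retries"];
  E.pair_mode = as<bool>(cfg["pair_mode"]);
  E.record_events = as<bool>(cfg["record_events"]);
  E.validate_every = cfg["validate_every"];

  // segments: start_step, k_cc_gated3, k_cc_free3, k_ap2_3d, koff_cc_us,
  // koff_ap2_us, d_clat_t (3), d_clat_r (3)  [rates in nm^3/us, us^-1]
  NumericMatrix sm = cfg["segments"];
  IntegerVector ap2_targets = cfg["segment_n_ap2"];
  double v3 = (4.0 / 3.0) * M_PI * E.sigma * E.sigma * E.sigma;
  double a2 = M_PI * E.sigma * E.sigma;
  for (int s = 0; s < sm.nrow(); s++) {
    Segment sg;
    sg.start_step = (int)sm(s, 0);
    double kg = sm(s, 1), kf = sm(s, 2), ka = sm(s, 3);
    sg.p_cc3_gated = kg > 0 ? 1 - std::exp(-(kg / v3) * E.dt) : 0.0;
    sg.p_cc2_gated =
        kg > 0 ? 1 - std::exp(-((kg / E.capture_h) / a2) * E.dt) : 0.0;
    sg.p_cc3_free = kf > 0 ? 1 - std::exp(-(kf / v3) * E.dt) : 0.0;
    sg.p_cc2_free =
        kf > 0 ? 1 - std::exp(-((kf / E.capture_h) / a2) * E.dt) : 0.0;
    sg.k_ap2_2d = ka / E.capture_h;
    sg.p_off_cc = 1 - std::exp(-sm(s, 4) * E.dt);
    sg.p_off_ap2 = 1 - std::exp(-sm(s, 5) * E.dt);
    for (int a = 0; a < 3; a++) {
      sg.d_clat_t[a] = sm(s, 6 + a);
      sg.d_clat_r[a] = sm(s, 9 + a);
      sg.inv_clat_t[a] = sg.d_clat_t[a] > 0 ? 1.0 / sg.d_clat_t[a] : 0.0;
      sg.cr_clat_r[a] =
          sg.d_clat_r[a] > 0 ? std::pow(sg.d_clat_r[a], -1.0 / 3.0) : 0.0;
    }
    sg.n_ap2_target = ap2_targets[s];
    E.segs.push_back(sg);
  }

  int n = E.n;
  E.pos.resize(n);
  E.quat.resize(n);
  E.legp.assign(n * 3, -1);
  E.legs.assign(n * 3, 0);
  E.hasap2.assign(n, 0);
  for (int i = 0; i < n; i++) {
    E.pos[i].x = pos0(i, 0);
    E.pos[i].y = pos0(i, 1);
    E.pos[i].z = pos0(i, 2);
    E.quat[i].w = quat0(i, 0);
    E.quat[i].x = quat0(i, 1);
    E.quat[i].y = quat0(i, 2);
    E.quat[i].z = quat0(i, 3);
    for (int l = 0; l < 3; l++) {
      E.legp[i * 3 + l] = leg_partner(i, l) - 1;  // 0 = free -> -1
      E.legs[i * 3 + l] = leg_partner_site(i, l) - 1;
    }
    E.hasap2[i] = ap2_bound[i] != 0;
  }
  E.ap2_free = ap2_free;
  E.ap2_total = ap2_total;
  E.ap2_pending = ap2_pending;
  E.time_us = time0;
  E.parent.resize(n);
  E.csize.resize(n);
  E.cmembrane.resize(n);
  E.frozen.assign(n, 0);
  E.sites.resize(n * 4);
  E.ppos.resize(n);
  E.pquat.resize(n);
  E.rindex.resize(n);
  E.cstart.resize(n + 1);
  E.cmem.resize(n);
  E.molcluster.resize(n);
  E.movable.resize(n);
  E.conflict.resize(n);
  E.cDT.resize(3 * n);
  E.cDR.resize(3 * n);
  E.cur_seg = -1;
  E.enter_segment(0);

  int n_steps = cfg["n_steps"];
  int frame_every = cfg["frame_every"];
  int n_frames = frame_every > 0 ? n_steps / frame_every : 0;

  NumericMatrix fpos(n_frames * n, 3), fquat(n_frames * n, 4);
  IntegerMatrix fap2(n_frames, n);
  IntegerVector ffree(n_frames);
  NumericVector ftime(n_frames);
  std::vector<int> fbonds;  // frame, a, sa, b, sb (1-based)

  int fi = 0;
  for (int s = 0; s < n_steps; s++) {
    E.step(s);
    if (E.validate_every > 0 && (s + 1) % E.validate_every == 0)
      E.validate(s + 1);
    if (frame_every > 0 && (s + 1) % frame_every == 0 && fi < n_frames) {
      for (int i = 0; i < n; i++) {
        fpos(fi * n + i, 0) = E.pos[i].x;
        fpos(fi * n + i, 1) = E.pos[i].y;
        fpos(fi * n + i, 2) = E.pos[i].z;
        fquat(fi * n + i, 0) = E.quat[i].w;
        fquat(fi * n + i, 1) = E.quat[i].x;
        fquat(fi * n + i, 2) = E.quat[i].y;
        fquat(fi * n + i, 3) = E.quat[i].z;
        fap2(fi, i) = E.hasap2[i] ? 1 : 0;
        for (int l = 0; l < 3; l++) {
          int j = E.legp[i * 3 + l];
          if (j > i) {
            fbonds.push_back(fi + 1);
            fbonds.push_back(i + 1);
            fbonds.push_back(l + 1);
            fbonds.push_back(j + 1);
            fbonds.push_back(E.legs[i * 3 + l] + 1);
          }
        }
      }
      ffree[fi] = E.ap2_free;
      ftime[fi] = E.time_us;
      fi++;
    }
  }

  // final state
  NumericMatrix spos(n, 3), squat(n, 4);
  IntegerMatrix slp(n, 3), sls(n, 3);
  IntegerVector sap2(n);
  for (int i = 0; i < n; i++) {
    spos(i, 0) = E.pos[i].x;
    spos(i, 1) = E.pos[i].y;
    spos(i, 2) = E.pos[i].z;
    squat(i, 0) = E.quat[i].w;
    squat(i, 1) = E.quat[i].x;
    squat(i, 2) = E.quat[i].y;
    squat(i, 3) = E.quat[i].z;
    for (int l = 0; l < 3; l++) {
      slp(i, l) = E.legp[i * 3 + l] + 1;
      sls(i, l) = E.legs[i * 3 + l] + 1;
    }
    sap2[i] = E.hasap2[i] ? 1 : 0;
  }

  IntegerMatrix bm((int)fbonds.size() / 5, 5);
  for (int r = 0; r < bm.nrow(); r++)
    for (int c = 0; c < 5; c++) bm(r, c) = fbonds[r * 5 + c];

  IntegerMatrix em((int)E.ev_log.size() / 6, 6);
  for (int r = 0; r < em.nrow(); r++)
    for (int c = 0; c < 6; c++) em(r, c) = E.ev_log[r * 6 + c];

  IntegerVector froz;
  for (int i = 0; i < n; i++)
    if (E.frozen[i]) froz.push_back(i + 1);

  NumericVector counts = NumericVector::create(
      _["bind_cc"] = (double)E.ev_counts[0],
      _["unbind_cc"] = (double)E.ev_counts[1],
      _["bind_ap2"] = (double)E.ev_counts[2],
      _["unbind_ap2"] = (double)E.ev_counts[3]);

  return List::create(
      _["pos_frames"] = fpos, _["quat_frames"] = fquat,
      _["ap2_frames"] = fap2, _["free_frames"] = ffree,
      _["time_frames"] = ftime, _["bond_frames"] = bm, _["events"] = em,
      _["frozen_last_step"] = froz, _["event_counts"] = counts,
      _["state"] = List::create(
          _["pos"] = spos, _["quat"] = squat, _["leg_partner"] = slp,
          _["leg_partner_site"] = sls, _["ap2_bound"] = sap2,
          _["ap2_free"] = E.ap2_free, _["ap2_total"] = E.ap2_total,
          _["ap2_pending"] = E.ap2_pending, _["time_us"] = E.time_us));
}
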