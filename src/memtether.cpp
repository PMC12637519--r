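// Geometry kernels for backbone construction, clash detection, hierarchical
// chain growth and stochastic cyclic coordinate descent.  All randomness
// comes from the R RNG (unif_rand/norm_rand) so set.seed() controls every
// sampler.  Distances are in Angstrom, angles in degrees.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <array>
#include <algorithm>
#include <vector>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Ideal backbone geometry (Engh-Huber-like constants, centralized here and
// mirrored in R/geometry.R for documentation).
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329;
static const double B_C_O = 1.231, B_CA_CB = 1.521;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
static const double A_CA_C_O = 120.8, A_C_CA_CB = 110.1;
static const double T_N_C_CA_CB = -122.55; // improper fixing L-chirality
static const double DEG = M_PI / 180.0;

// atom type codes shared with R: 0=N 1=CA 2=C 3=O 4=CB 5=SG 6=other
enum { AT_N = 0, AT_CA = 1, AT_C = 2, AT_O = 3, AT_CB = 4 };

struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { return {x, y, z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator*(V3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(V3 a) { double n = norm(a); return {a.x / n, a.y / n, a.z / n}; }
static inline double dist2(V3 a, V3 b) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  return dx * dx + dy * dy + dz * dz;
}

// Place atom D given A-B-C, bond |CD|, angle B-C-D (deg), torsion A-B-C-D (deg).
static V3 nerf(V3 A, V3 B, V3 C, double bond, double angle, double torsion) {
  double th = angle * DEG, ph = torsion * DEG;
  V3 ab = unit(B - A), bc = unit(C - B);
  V3 n = unit(cross(ab, bc));
  V3 m = cross(n, bc);
  V3 d = bc * (-bond * std::cos(th)) + m * (bond * std::sin(th) * std::cos(ph)) +
         n * (bond * std::sin(th) * std::sin(ph));
  return C + d;
}

static double torsion_deg(V3 p1, V3 p2, V3 p3, V3 p4) {
  V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  V3 c1 = cross(b1, b2), c2 = cross(b2, b3);
  double x = dot(c1, c2);
  double y = dot(cross(c1, c2), unit(b2));
  double a = std::atan2(y, x) / DEG;
  if (a <= -180.0) a += 360.0; // report in (-180, 180]
  return a;
}

// ---------------------------------------------------------------------------
// Spatial hash grid over points for neighbour queries within `cutoff`.
struct Grid {
  double cell;
  std::unordered_map<long long, std::vector<int>> cells;
  const std::vector<V3> *pts;
  static long long key(int ix, int iy, int iz) {
    return ((long long)ix * 73856093LL) ^ ((long long)iy * 19349663LL) ^
           ((long long)iz * 83492791LL) ^ ((long long)ix << 40) ^
           ((long long)iy << 20) ^ (long long)iz;
  }
  void build(const std::vector<V3> &p, double cell_size) {
    cell = cell_size;
    pts = &p;
    cells.clear();
    for (size_t i = 0; i < p.size(); ++i) {
      int ix = (int)std::floor(p[i].x / cell), iy = (int)std::floor(p[i].y / cell),
          iz = (int)std::floor(p[i].z / cell);
      cells[key(ix, iy, iz)].push_back((int)i);
    }
  }
  // NOTE: hash keys of distinct cells can collide, in which case a
  // neighbour may be visited more than once; callers that enumerate
  // pairs deduplicate, boolean/early-exit callers are unaffected
  template <class F> void neighbours(V3 q, double cutoff, F fn) const {
    double c2 = cutoff * cutoff;
    int ix = (int)std::floor(q.x / cell), iy = (int)std::floor(q.y / cell),
        iz = (int)std::floor(q.z / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second)
            if (dist2(q, (*pts)[j]) < c2) fn(j);
        }
  }
};

// pairwise exclusion rule: intra-rigid-body pairs, and near-bonded
// neighbours approximated as same-chain residues no more than two apart
// (this also covers the covalent 1-3 pairs that run through a grafted
// junction residue, e.g. a bound pose continuing into a sampled chain).
static inline bool excluded(int ch_i, int res_i, int grp_i, int ch_j, int res_j,
                            int grp_j) {
  if (grp_i > 0 && grp_i == grp_j) return true;
  if (ch_i == ch_j && std::abs(res_i - res_j) <= 2) return true;
  return false;
}

static std::vector<V3> as_pts(const NumericMatrix &m) {
  std::vector<V3> p(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) p[i] = v3(m(i, 0), m(i, 1), m(i, 2));
  return p;
}

// ---------------------------------------------------------------------------
// Backbone construction.  phi[0] and omega[0] are ignored (undefined at the
// N-terminus); psi of the last residue only orients its carbonyl oxygen.
// start_triad: 3x3 matrix with rows N, CA, C of the first residue, or 0-row
// matrix for the canonical frame.
// [[Rcpp::export]]
List cpp_build_chain(NumericVector phi, NumericVector psi, NumericVector omega,
                     LogicalVector has_cb, NumericMatrix start_triad) {
  int n = phi.size();
  if (psi.size() != n || omega.size() != n || has_cb.size() != n)
    stop("dihedral/sequence length mismatch");
  std::vector<V3> N(n), CA(n), C(n), O(n), CB(n);
  if (start_triad.nrow() == 3) {
    N[0] = v3(start_triad(0, 0), start_triad(0, 1), start_triad(0, 2));
    CA[0] = v3(start_triad(1, 0), start_triad(1, 1), start_triad(1, 2));
    C[0] = v3(start_triad(2, 0), start_triad(2, 1), start_triad(2, 2));
  } else {
    N[0] = v3(0, 0, 0);
    CA[0] = v3(B_N_CA, 0, 0);
    double a = A_N_CA_C * DEG;
    C[0] = v3(B_N_CA - B_CA_C * std::cos(a), B_CA_C * std::sin(a), 0);
  }
  for (int i = 1; i < n; ++i) {
    N[i] = nerf(N[i - 1], CA[i - 1], C[i - 1], B_C_N, A_CA_C_N, psi[i - 1]);
    CA[i] = nerf(CA[i - 1], C[i - 1], N[i], B_N_CA, A_C_N_CA, omega[i]);
    C[i] = nerf(C[i - 1], N[i], CA[i], B_CA_C, A_N_CA_C, phi[i]);
  }
  for (int i = 0; i < n; ++i) {
    O[i] = nerf(N[i], CA[i], C[i], B_C_O, A_CA_C_O, psi[i] + 180.0);
    if (has_cb[i]) CB[i] = nerf(N[i], C[i], CA[i], B_CA_CB, A_C_CA_CB, T_N_C_CA_CB);
  }
  int nat = 0;
  for (int i = 0; i < n; ++i) nat += 4 + (has_cb[i] ? 1 : 0);
  NumericMatrix xyz(nat, 3);
  IntegerVector atype(nat), ridx(nat);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    V3 at[5] = {N[i], CA[i], C[i], O[i], CB[i]};
    int ntypes = has_cb[i] ? 5 : 4;
    for (int t = 0; t < ntypes; ++t, ++k) {
      xyz(k, 0) = at[t].x; xyz(k, 1) = at[t].y; xyz(k, 2) = at[t].z;
      atype[k] = t;
      ridx[k] = i + 1;
    }
  }
  return List::create(_["xyz"] = xyz, _["atype"] = atype, _["ridx"] = ridx);
}

// [[Rcpp::export]]
List cpp_measure_dihedrals(NumericMatrix Nm, NumericMatrix CAm, NumericMatrix Cm,
                           double max_gap) {
  int n = Nm.nrow();
  NumericVector phi(n, NA_REAL), psi(n, NA_REAL), omega(n, NA_REAL);
  std::vector<V3> N(n), CA(n), C(n);
  for (int i = 0; i < n; ++i) {
    N[i] = v3(Nm(i, 0), Nm(i, 1), Nm(i, 2));
    CA[i] = v3(CAm(i, 0), CAm(i, 1), CAm(i, 2));
    C[i] = v3(Cm(i, 0), Cm(i, 1), Cm(i, 2));
  }
  for (int i = 0; i + 1 < n; ++i) {
    double g = std::sqrt(dist2(C[i], N[i + 1]));
    if (g > max_gap)
      stop("chain discontinuity: C-N gap of %.2f A after residue position %d",
           g, i + 1);
  }
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      phi[i] = torsion_deg(C[i - 1], N[i], CA[i], C[i]);
      omega[i] = torsion_deg(CA[i - 1], C[i - 1], N[i], CA[i]);
    }
    if (i + 1 < n) psi[i] = torsion_deg(N[i], CA[i], C[i], N[i + 1]);
  }
  return List::create(_["phi"] = phi, _["psi"] = psi, _["omega"] = omega);
}

// ---------------------------------------------------------------------------
// Clash detection.
// [[Rcpp::export]]
IntegerMatrix cpp_clash_pairs(NumericMatrix xyz, IntegerVector chain,
                              IntegerVector resno, IntegerVector grp,
                              double cutoff, bool use_grid) {
  int n = xyz.nrow();
  std::vector<V3> p = as_pts(xyz);
  std::vector<std::pair<int, int>> out;
  double c2 = cutoff * cutoff;
  if (use_grid) {
    Grid g;
    g.build(p, cutoff);
    for (int i = 0; i < n; ++i) {
      g.neighbours(p[i], cutoff, [&](int j) {
        if (j <= i) return;
        if (!excluded(chain[i], resno[i], grp[i], chain[j], resno[j], grp[j]))
          out.push_back({i, j});
      });
    }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (dist2(p[i], p[j]) < c2 &&
            !excluded(chain[i], resno[i], grp[i], chain[j], resno[j], grp[j]))
          out.push_back({i, j});
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  IntegerMatrix res(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res(k, 0) = out[k].first + 1;
    res(k, 1) = out[k].second + 1;
  }
  return res;
}

// any clash between set A and set B (early exit)
// [[Rcpp::export]]
bool cpp_clash_any_between(NumericMatrix xyzA, IntegerVector chA, IntegerVector reA,
                           IntegerVector grA, NumericMatrix xyzB, IntegerVector chB,
                           IntegerVector reB, IntegerVector grB, double cutoff) {
  std::vector<V3> a = as_pts(xyzA), b = as_pts(xyzB);
  bool swap = a.size() < b.size();
  const std::vector<V3> &big = swap ? b : a, &small = swap ? a : b;
  const IntegerVector &chBig = swap ? chB : chA, &reBig = swap ? reB : reA,
                      &grBig = swap ? grB : grA;
  const IntegerVector &chS = swap ? chA : chB, &reS = swap ? reA : reB,
                      &grS = swap ? grA : grB;
  Grid g;
  g.build(big, cutoff);
  for (size_t i = 0; i < small.size(); ++i) {
    bool hit = false;
    g.neighbours(small[i], cutoff, [&](int j) {
      if (!excluded(chS[i], reS[i], grS[i], chBig[j], reBig[j], grBig[j])) hit = true;
    });
    if (hit) return true;
  }
  return false;
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_rows(NumericMatrix xyz, IntegerVector rows,
                              NumericVector p0v, NumericVector axv, double angle) {
  NumericMatrix out = clone(xyz);
  V3 p0 = v3(p0v[0], p0v[1], p0v[2]);
  V3 ax = unit(v3(axv[0], axv[1], axv[2]));
  double th = angle * DEG, c = std::cos(th), s = std::sin(th);
  for (int k = 0; k < rows.size(); ++k) {
    int i = rows[k] - 1;
    V3 v = v3(out(i, 0), out(i, 1), out(i, 2)) - p0;
    V3 r = v * c + cross(ax, v) * s + ax * (dot(ax, v) * (1 - c));
    out(i, 0) = r.x + p0.x; out(i, 1) = r.y + p0.y; out(i, 2) = r.z + p0.z;
  }
  return out;
}

// minimum RMSD over `nrot` uniform random rotations with optimal translation
// (centroid alignment); the brute-force oracle for Kabsch superposition.
// [[Rcpp::export]]
double cpp_min_rmsd_rotscan(NumericMatrix P, NumericMatrix Q, int nrot) {
  int n = P.nrow();
  std::vector<V3> p = as_pts(P), q = as_pts(Q);
  V3 cp = v3(0, 0, 0), cq = v3(0, 0, 0);
  for (int i = 0; i < n; ++i) { cp = cp + p[i]; cq = cq + q[i]; }
  cp = cp * (1.0 / n); cq = cq * (1.0 / n);
  for (int i = 0; i < n; ++i) { p[i] = p[i] - cp; q[i] = q[i] - cq; }
  double best = R_PosInf;
  for (int r = 0; r < nrot; ++r) {
    // uniform rotation via normalized quaternion of 4 std normals
    double a = norm_rand(), b = norm_rand(), c = norm_rand(), d = norm_rand();
    double qn = std::sqrt(a * a + b * b + c * c + d * d);
    a /= qn; b /= qn; c /= qn; d /= qn;
    double R[3][3] = {
        {1 - 2 * (c * c + d * d), 2 * (b * c - a * d), 2 * (b * d + a * c)},
        {2 * (b * c + a * d), 1 - 2 * (b * b + d * d), 2 * (c * d - a * b)},
        {2 * (b * d - a * c), 2 * (c * d + a * b), 1 - 2 * (b * b + c * c)}};
    double ss = 0;
    for (int i = 0; i < n; ++i) {
      V3 rp = v3(R[0][0] * p[i].x + R[0][1] * p[i].y + R[0][2] * p[i].z,
                 R[1][0] * p[i].x + R[1][1] * p[i].y + R[1][2] * p[i].z,
                 R[2][0] * p[i].x + R[2][1] * p[i].y + R[2][2] * p[i].z);
      ss += dist2(rp, q[i]);
    }
    double rmsd = std::sqrt(ss / n);
    if (rmsd < best) best = rmsd;
  }
  return best;
}

// ---------------------------------------------------------------------------
// Hierarchical chain growth.

struct Frag {
  // residue-ordered atoms for residues [lo, hi] (1-based along the segment)
  int lo, hi;
  std::vector<V3> xyz;
  std::vector<int> atype, ridx; // ridx: segment-local residue index
  std::vector<int> rowN, rowCA, rowC; // per local residue (ridx - lo)
};

struct LibClass {
  std::vector<double> phi, psi, cw; // cumulative weights
};

struct GrowCtx {
  std::vector<LibClass> lib;
  std::vector<int> class_idx; // per residue, 0-based class
  std::vector<bool> has_cb;
  int frag_len, retry_frag, retry_merge;
  bool anchor_end;
  bool anchored;
  V3 aN, aCA, aC;
  double z0;
  double cutoff;
  std::vector<V3> ctx_pts;
  std::vector<int> ctx_chain, ctx_resno, ctx_grp;
  Grid ctx_grid;
  int chain_code, resno_start;
  // optional terminal proximity window: once a product in the absolute
  // frame contains residues [win_lo, win_hi], their minimum CA distance
  // to win_center must not exceed win_dist (enforced with local retries,
  // like every other acceptance constraint)
  bool has_window;
  int win_lo, win_hi;
  V3 win_center;
  double win_dist;
  long draws, merge_fails;
};

static bool window_violated(const GrowCtx &g, const Frag &f) {
  if (!g.has_window) return false;
  int lo_res = g.resno_start + f.lo - 1, hi_res = g.resno_start + f.hi - 1;
  if (lo_res > g.win_lo || hi_res < g.win_hi) {
    // window not contained yet: reachability steering at 2.5 A per
    // remaining residue (a typical coil extension, far below the 3.8 A
    // contour limit).  Partial products whose free end could not plausibly
    // bring the window segment within range are redrawn locally; this
    // steers candidate tails toward the target and is documented as a
    // sampling heuristic of the bound-state candidate generator.
    if (lo_res <= g.win_hi || hi_res < g.win_hi) return false;
    double reach = 2.5 * (lo_res - g.win_lo) + g.win_dist;
    for (size_t i = 0; i < f.xyz.size(); ++i) {
      if (f.atype[i] != AT_CA) continue;
      if (g.resno_start + f.ridx[i] - 1 != lo_res) continue;
      return dist2(f.xyz[i], g.win_center) > reach * reach;
    }
    return false;
  }
  double best = R_PosInf;
  for (size_t i = 0; i < f.xyz.size(); ++i) {
    if (f.atype[i] != AT_CA) continue;
    int rn = g.resno_start + f.ridx[i] - 1;
    if (rn < g.win_lo || rn > g.win_hi) continue;
    double d = dist2(f.xyz[i], g.win_center);
    if (d < best) best = d;
  }
  return best > g.win_dist * g.win_dist;
}

static void draw_residue(const LibClass &lc, double &phi, double &psi) {
  double u = unif_rand();
  size_t k = 0;
  while (k + 1 < lc.cw.size() && u > lc.cw[k]) ++k;
  phi = lc.phi[k];
  psi = lc.psi[k];
}

// build fragment for residues [lo,hi] in canonical frame with freshly drawn
// dihedrals; returns atoms
static Frag build_frag(GrowCtx &g, int lo, int hi) {
  int n = hi - lo + 1;
  std::vector<double> phi(n), psi(n);
  for (int i = 0; i < n; ++i) {
    draw_residue(g.lib[g.class_idx[lo - 1 + i]], phi[i], psi[i]);
    g.draws++;
  }
  Frag f;
  f.lo = lo; f.hi = hi;
  std::vector<V3> N(n), CA(n), C(n);
  N[0] = v3(0, 0, 0);
  CA[0] = v3(B_N_CA, 0, 0);
  double a = A_N_CA_C * DEG;
  C[0] = v3(B_N_CA - B_CA_C * std::cos(a), B_CA_C * std::sin(a), 0);
  for (int i = 1; i < n; ++i) {
    N[i] = nerf(N[i - 1], CA[i - 1], C[i - 1], B_C_N, A_CA_C_N, psi[i - 1]);
    CA[i] = nerf(CA[i - 1], C[i - 1], N[i], B_N_CA, A_C_N_CA, 180.0);
    C[i] = nerf(C[i - 1], N[i], CA[i], B_CA_C, A_N_CA_C, phi[i]);
  }
  for (int i = 0; i < n; ++i) {
    int li = lo + i;
    bool cb = g.has_cb[li - 1];
    V3 O = nerf(N[i], CA[i], C[i], B_C_O, A_CA_C_O, psi[i] + 180.0);
    f.rowN.push_back((int)f.xyz.size());
    f.xyz.push_back(N[i]); f.atype.push_back(AT_N); f.ridx.push_back(li);
    f.rowCA.push_back((int)f.xyz.size());
    f.xyz.push_back(CA[i]); f.atype.push_back(AT_CA); f.ridx.push_back(li);
    f.rowC.push_back((int)f.xyz.size());
    f.xyz.push_back(C[i]); f.atype.push_back(AT_C); f.ridx.push_back(li);
    f.xyz.push_back(O); f.atype.push_back(AT_O); f.ridx.push_back(li);
    if (cb) {
      V3 CB = nerf(N[i], C[i], CA[i], B_CA_CB, A_C_CA_CB, T_N_C_CA_CB);
      f.xyz.push_back(CB); f.atype.push_back(AT_CB); f.ridx.push_back(li);
    }
  }
  return f;
}

static bool frag_internal_clash(const GrowCtx &g, const Frag &f) {
  double c2 = g.cutoff * g.cutoff;
  for (size_t i = 0; i < f.xyz.size(); ++i)
    for (size_t j = i + 1; j < f.xyz.size(); ++j) {
      if (std::abs(f.ridx[i] - f.ridx[j]) <= 2) continue;
      if (dist2(f.xyz[i], f.xyz[j]) < c2) return true;
    }
  return false;
}

// orthonormal frame at a residue triad (origin CA)
static void triad_frame(V3 N, V3 CA, V3 C, V3 &e1, V3 &e2, V3 &e3) {
  e1 = unit(C - CA);
  V3 v = N - CA;
  e2 = unit(v - e1 * dot(v, e1));
  e3 = cross(e1, e2);
}

// rigid transform mapping triad (fN,fCA,fC) onto (tN,tCA,tC); exact for
// congruent triads (ideal internal geometry on both sides)
struct RT { double R[3][3]; V3 t; };
static RT triad_transform(V3 fN, V3 fCA, V3 fC, V3 tN, V3 tCA, V3 tC) {
  V3 a1, a2, a3, b1, b2, b3;
  triad_frame(fN, fCA, fC, a1, a2, a3);
  triad_frame(tN, tCA, tC, b1, b2, b3);
  RT rt;
  // R = sum_k b_k a_k^T maps frame A onto frame B
  double R[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  V3 bs[3] = {b1, b2, b3}, as[3] = {a1, a2, a3};
  for (int k = 0; k < 3; ++k) {
    double bv[3] = {bs[k].x, bs[k].y, bs[k].z};
    double av[3] = {as[k].x, as[k].y, as[k].z};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] += bv[i] * av[j];
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) rt.R[i][j] = R[i][j];
  V3 RfCA = v3(R[0][0] * fCA.x + R[0][1] * fCA.y + R[0][2] * fCA.z,
               R[1][0] * fCA.x + R[1][1] * fCA.y + R[1][2] * fCA.z,
               R[2][0] * fCA.x + R[2][1] * fCA.y + R[2][2] * fCA.z);
  rt.t = tCA - RfCA;
  return rt;
}

static void apply_rt(const RT &rt, std::vector<V3> &p) {
  for (auto &v : p) {
    V3 r = v3(rt.R[0][0] * v.x + rt.R[0][1] * v.y + rt.R[0][2] * v.z,
              rt.R[1][0] * v.x + rt.R[1][1] * v.y + rt.R[1][2] * v.z,
              rt.R[2][0] * v.x + rt.R[2][1] * v.y + rt.R[2][2] * v.z);
    v = r + rt.t;
  }
}

// constraint checks over a set of points (membrane half-space + context clash)
static bool violates_constraints(GrowCtx &g, const std::vector<V3> &pts,
                                 const std::vector<int> &ridx) {
  if (R_FINITE(g.z0)) {
    for (const auto &p : pts)
      if (p.z <= g.z0) return true;
  }
  if (!g.ctx_pts.empty()) {
    for (size_t i = 0; i < pts.size(); ++i) {
      bool hit = false;
      int res_i = g.resno_start + ridx[i] - 1;
      g.ctx_grid.neighbours(pts[i], g.cutoff, [&](int j) {
        if (!excluded(g.chain_code, res_i, 0, g.ctx_chain[j], g.ctx_resno[j],
                      g.ctx_grp[j]))
          hit = true;
      });
      if (hit) return true;
    }
  }
  return false;
}

// clash between two partial products (shared boundary residue excluded by the
// adjacency rule); grid built on the larger product
static bool halves_clash(const GrowCtx &g, const Frag &A, const Frag &B) {
  const Frag &big = (A.xyz.size() >= B.xyz.size()) ? A : B;
  const Frag &small = (A.xyz.size() >= B.xyz.size()) ? B : A;
  Grid grid;
  grid.build(big.xyz, g.cutoff);
  for (size_t i = 0; i < small.xyz.size(); ++i) {
    bool hit = false;
    grid.neighbours(small.xyz[i], g.cutoff, [&](int j) {
      if (std::abs(small.ridx[i] - big.ridx[j]) > 2) hit = true;
    });
    if (hit) return true;
  }
  return false;
}

static bool assemble(GrowCtx &g, int lo_frag, int hi_frag,
                     const std::vector<int> &fs, const std::vector<int> &fe,
                     Frag &out);

// leaf with placement/constraint handling
static bool make_leaf(GrowCtx &g, int fi, const std::vector<int> &fs,
                      const std::vector<int> &fe, Frag &out) {
  int K = (int)fs.size();
  bool is_anchor_leaf =
      g.anchored && ((g.anchor_end && fi == K - 1) || (!g.anchor_end && fi == 0));
  for (int tr = 0; tr < g.retry_frag; ++tr) {
    Frag f = build_frag(g, fs[fi], fe[fi]);
    if (frag_internal_clash(g, f)) continue;
    if (is_anchor_leaf) {
      int local = g.anchor_end ? (f.hi - f.lo) : 0;
      RT rt = triad_transform(f.xyz[f.rowN[local]], f.xyz[f.rowCA[local]],
                              f.xyz[f.rowC[local]], g.aN, g.aCA, g.aC);
      apply_rt(rt, f.xyz);
      if (violates_constraints(g, f.xyz, f.ridx)) continue;
      if (window_violated(g, f)) continue;
    }
    out = std::move(f);
    return true;
  }
  return false;
}

// merge left [a..m] and right [m..b]: the product keeps the anchored side
// fixed and transforms the other onto the shared residue triad.
static bool merge_frags(GrowCtx &g, Frag &left, Frag &right, bool absolute,
                        Frag &out) {
  int m = left.hi; // shared residue
  Frag mob, fix;
  bool left_mobile = g.anchor_end;
  if (left_mobile) { mob = left; fix = right; } else { mob = right; fix = left; }
  int mloc_mob = m - mob.lo, mloc_fix = m - fix.lo;
  RT rt = triad_transform(
      mob.xyz[mob.rowN[mloc_mob]], mob.xyz[mob.rowCA[mloc_mob]],
      mob.xyz[mob.rowC[mloc_mob]], fix.xyz[fix.rowN[mloc_fix]],
      fix.xyz[fix.rowCA[mloc_fix]], fix.xyz[fix.rowC[mloc_fix]]);
  apply_rt(rt, mob.xyz);
  // drop the mobile copy of the shared residue
  Frag mkeep;
  mkeep.lo = mob.lo == m ? m + 1 : mob.lo;
  mkeep.hi = mob.hi == m ? m - 1 : mob.hi;
  for (size_t i = 0; i < mob.xyz.size(); ++i) {
    if (mob.ridx[i] == m) continue;
    mkeep.xyz.push_back(mob.xyz[i]);
    mkeep.atype.push_back(mob.atype[i]);
    mkeep.ridx.push_back(mob.ridx[i]);
  }
  // clash between the two halves
  if (halves_clash(g, mkeep, fix)) { g.merge_fails++; return false; }
  if (absolute && violates_constraints(g, mkeep.xyz, mkeep.ridx)) {
    g.merge_fails++;
    return false;
  }
  // concatenate residue-ordered
  const Frag &first = (mkeep.lo < fix.lo || fix.xyz.empty()) ? mkeep : fix;
  const Frag &second = (&first == &mkeep) ? fix : mkeep;
  out = Frag();
  out.lo = std::min(mkeep.lo, fix.lo);
  out.hi = std::max(mkeep.hi, fix.hi);
  auto push = [&](const Frag &f) {
    for (size_t i = 0; i < f.xyz.size(); ++i) {
      if (f.atype[i] == AT_N) out.rowN.push_back((int)out.xyz.size());
      if (f.atype[i] == AT_CA) out.rowCA.push_back((int)out.xyz.size());
      if (f.atype[i] == AT_C) out.rowC.push_back((int)out.xyz.size());
      out.xyz.push_back(f.xyz[i]);
      out.atype.push_back(f.atype[i]);
      out.ridx.push_back(f.ridx[i]);
    }
  };
  push(first);
  push(second);
  if (absolute && window_violated(g, out)) {
    g.merge_fails++;
    return false;
  }
  return true;
}

static bool assemble(GrowCtx &g, int lo_frag, int hi_frag,
                     const std::vector<int> &fs, const std::vector<int> &fe,
                     Frag &out) {
  if (lo_frag == hi_frag) return make_leaf(g, lo_frag, fs, fe, out);
  int mid = (lo_frag + hi_frag) / 2;
  // assemble the anchored (fixed) side first
  Frag left, right;
  bool absolute = g.anchored && ((g.anchor_end && hi_frag == (int)fs.size() - 1) ||
                                 (!g.anchor_end && lo_frag == 0));
  if (g.anchor_end) {
    if (!assemble(g, mid + 1, hi_frag, fs, fe, right)) return false;
    for (int tr = 0; tr < g.retry_merge; ++tr) {
      if (!assemble(g, lo_frag, mid, fs, fe, left)) continue;
      if (merge_frags(g, left, right, absolute, out)) return true;
    }
  } else {
    if (!assemble(g, lo_frag, mid, fs, fe, left)) return false;
    for (int tr = 0; tr < g.retry_merge; ++tr) {
      if (!assemble(g, mid + 1, hi_frag, fs, fe, right)) continue;
      if (merge_frags(g, left, right, absolute, out)) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_sample_chain(IntegerVector class_idx, List lib, LogicalVector has_cb,
                      int frag_len, int retry_frag, int retry_merge,
                      bool anchor_end, NumericMatrix anchor_triad, double z0,
                      NumericMatrix ctx_xyz, IntegerVector ctx_chain,
                      IntegerVector ctx_resno, IntegerVector ctx_grp,
                      int chain_code, int resno_start, double cutoff,
                      NumericVector window) {
  GrowCtx g;
  int n = class_idx.size();
  for (int c = 0; c < lib.size(); ++c) {
    NumericMatrix m = lib[c];
    LibClass lc;
    double acc = 0;
    for (int i = 0; i < m.nrow(); ++i) {
      lc.phi.push_back(m(i, 0));
      lc.psi.push_back(m(i, 1));
      acc += m(i, 2);
      lc.cw.push_back(acc);
    }
    for (auto &w : lc.cw) w /= acc;
    g.lib.push_back(lc);
  }
  g.class_idx.assign(class_idx.begin(), class_idx.end());
  for (auto &c : g.class_idx) c -= 1;
  g.has_cb.assign(has_cb.begin(), has_cb.end());
  g.frag_len = frag_len;
  g.retry_frag = retry_frag;
  g.retry_merge = retry_merge;
  g.anchor_end = anchor_end;
  g.anchored = anchor_triad.nrow() == 3;
  if (g.anchored) {
    g.aN = v3(anchor_triad(0, 0), anchor_triad(0, 1), anchor_triad(0, 2));
    g.aCA = v3(anchor_triad(1, 0), anchor_triad(1, 1), anchor_triad(1, 2));
    g.aC = v3(anchor_triad(2, 0), anchor_triad(2, 1), anchor_triad(2, 2));
  }
  g.z0 = z0;
  g.cutoff = cutoff;
  g.ctx_pts = as_pts(ctx_xyz);
  g.ctx_chain.assign(ctx_chain.begin(), ctx_chain.end());
  g.ctx_resno.assign(ctx_resno.begin(), ctx_resno.end());
  g.ctx_grp.assign(ctx_grp.begin(), ctx_grp.end());
  if (!g.ctx_pts.empty()) g.ctx_grid.build(g.ctx_pts, cutoff);
  g.chain_code = chain_code;
  g.resno_start = resno_start;
  g.has_window = window.size() == 6;
  if (g.has_window) {
    g.win_lo = (int)window[0];
    g.win_hi = (int)window[1];
    g.win_center = v3(window[2], window[3], window[4]);
    g.win_dist = window[5];
  }
  g.draws = 0;
  g.merge_fails = 0;
  // fragment boundaries with one-residue overlap
  std::vector<int> fs, fe;
  int s = 1;
  while (true) {
    int e = std::min(s + frag_len - 1, n);
    fs.push_back(s);
    fe.push_back(e);
    if (e == n) break;
    s = e; // shared residue
  }
  Frag out;
  bool ok;
  int fail_stage = -1; // -1 ok; otherwise the spine step index that failed
  // windowed candidate generation uses a spine of small subtrees so the
  // proximity constraint can steer growth with cheap local redraws; all
  // other chains (anchored or not) use the balanced pairwise hierarchy,
  // whose coarse-grained resampling preserves the entropic lift of
  // wall-confined chains
  if (g.anchored && g.has_window) {
    // anchored chains grow as a spine from the anchored end: subtrees of
    // a few fragments are assembled hierarchically in their local frame
    // and merged onto the absolute spine one at a time, so acceptance
    // constraints (half-space, context clash, proximity window) bind at
    // ~20-residue increments with cheap local redraws
    int K = (int)fs.size();
    const int step = 4;
    // per-step fragment windows, ordered from the anchored end
    std::vector<std::pair<int, int>> steps;
    if (g.anchor_end) {
      int hi = K - 1;
      while (hi >= 0) {
        int lo = std::max(0, hi - step + 1);
        steps.push_back({lo, hi});
        hi = lo - 1;
      }
    } else {
      int lo = 0;
      while (lo < K) {
        int hi = std::min(K - 1, lo + step - 1);
        steps.push_back({lo, hi});
        lo = hi + 1;
      }
    }
    int S = (int)steps.size();
    auto run_step = [&](int si, Frag &spine) {
      for (int tr = 0; tr < g.retry_merge; ++tr) {
        Frag sub;
        if (!assemble(g, steps[si].first, steps[si].second, fs, fe, sub))
          continue;
        Frag merged;
        bool okm = g.anchor_end ? merge_frags(g, sub, spine, true, merged)
                                : merge_frags(g, spine, sub, true, merged);
        if (okm) {
          spine = std::move(merged);
          return true;
        }
      }
      return false;
    };
    // base spine with bounded backtracking: a failed step reworks the
    // previous step (snapshots kept per step) instead of discarding the
    // whole chain; the terminal steps -- where the free-end constraints
    // (proximity window, attachment space) concentrate -- are retried as
    // a pair from the last snapshot
    ok = false;
    for (int tr = 0; tr < g.retry_merge && !ok; ++tr)
      ok = assemble(g, steps[0].first, steps[0].second, fs, fe, out);
    if (!ok) fail_stage = 0;
    int base_end = std::max(1, S - 2);
    if (ok) {
      std::vector<Frag> snap;
      snap.push_back(out);
      int si = 1, backs = 0;
      while (si < base_end) {
        if (run_step(si, out)) {
          snap.push_back(out);
          ++si;
          continue;
        }
        if (si > 1 && backs < 12) {
          ++backs;
          --si;
          snap.pop_back();
          out = snap.back();
        } else {
          ok = false;
          fail_stage = si;
          break;
        }
      }
    }
    if (ok && base_end < S) {
      bool done = false;
      for (int round = 0; round < 25 && !done; ++round) {
        Frag trial = out;
        bool t_ok = true;
        for (int si = base_end; si < S && t_ok; ++si)
          t_ok = run_step(si, trial);
        if (t_ok) {
          out = std::move(trial);
          done = true;
        }
      }
      ok = done;
      if (!ok) fail_stage = 1000 + S;
    }
  } else {
    ok = assemble(g, 0, (int)fs.size() - 1, fs, fe, out);
  }
  if (!ok)
    return List::create(_["ok"] = false, _["draws"] = (double)g.draws,
                        _["merge_fails"] = (double)g.merge_fails,
                        _["fail_stage"] = fail_stage);
  int nat = (int)out.xyz.size();
  NumericMatrix xyz(nat, 3);
  IntegerVector atype(nat), resno(nat);
  for (int i = 0; i < nat; ++i) {
    xyz(i, 0) = out.xyz[i].x; xyz(i, 1) = out.xyz[i].y; xyz(i, 2) = out.xyz[i].z;
    atype[i] = out.atype[i];
    resno[i] = resno_start + out.ridx[i] - 1;
  }
  return List::create(_["ok"] = true, _["xyz"] = xyz, _["atype"] = atype,
                      _["resno"] = resno, _["draws"] = (double)g.draws,
                      _["merge_fails"] = (double)g.merge_fails);
}

// ---------------------------------------------------------------------------
// Freely-jointed virtual-bond sampler (CA-only), the polymer reference system.
// [[Rcpp::export]]
List cpp_sample_fjc(int nbeads, double b, double cutoff, double z0,
                    int max_restarts) {
  for (int attempt = 0; attempt < max_restarts; ++attempt) {
    std::vector<V3> p;
    p.reserve(nbeads);
    p.push_back(v3(0, 0, 0));
    bool fail = false;
    for (int i = 1; i < nbeads; ++i) {
      // uniform direction on the sphere
      double u = 2 * unif_rand() - 1, phi = 2 * M_PI * unif_rand();
      double s = std::sqrt(1 - u * u);
      V3 step = v3(b * s * std::cos(phi), b * s * std::sin(phi), b * u);
      V3 np = p.back() + step;
      if (R_FINITE(z0) && np.z <= z0) { fail = true; break; }
      if (cutoff > 0) {
        double c2 = cutoff * cutoff;
        for (int j = 0; j < i - 2; ++j)
          if (dist2(np, p[j]) < c2) { fail = true; break; }
      }
      if (fail) break;
      p.push_back(np);
    }
    if (!fail) {
      NumericMatrix xyz(nbeads, 3);
      for (int i = 0; i < nbeads; ++i) {
        xyz(i, 0) = p[i].x; xyz(i, 1) = p[i].y; xyz(i, 2) = p[i].z;
      }
      return List::create(_["ok"] = true, _["xyz"] = xyz,
                          _["attempts"] = attempt + 1);
    }
  }
  return List::create(_["ok"] = false, _["attempts"] = max_restarts);
}

// ---------------------------------------------------------------------------
// Stochastic CCD.
//
// mode: 0 = point targets (paired rows of `target`), 1 = plane (|z - z0|),
// 2 = alignment (paired reference coordinates, no re-superposition).
// Convergence: plane -> every effector within tol of z0; align -> RMSD < tol;
// point -> objective <= tol.
// [[Rcpp::export]]
List cpp_ccd(NumericMatrix xyz_in, IntegerVector chain, IntegerVector resno,
             IntegerVector grp, IntegerVector atype, IntegerVector pseudo,
             int idr_chain, bool anchor_end, IntegerVector rotatable,
             IntegerVector effector_rows, int mode, NumericMatrix target,
             double z0, double sigma, int max_moves, double tol, double cutoff,
             bool check_clash, NumericMatrix ctx_xyz, IntegerVector ctx_chain,
             IntegerVector ctx_resno, IntegerVector ctx_grp, bool record_deltas,
             int stall_limit) {
  int nat = xyz_in.nrow();
  std::vector<V3> pts = as_pts(xyz_in);
  std::vector<V3> ctx = as_pts(ctx_xyz);
  Grid ctx_grid;
  if (!ctx.empty()) ctx_grid.build(ctx, cutoff);

  int nrot = rotatable.size();
  if (nrot == 0) stop("no rotatable residues");
  // rows of backbone N/CA/C per rotatable residue on the IDR chain
  std::vector<int> rN(nrot, -1), rCA(nrot, -1), rC(nrot, -1);
  std::unordered_map<int, int> rot_of;
  for (int k = 0; k < nrot; ++k) rot_of[rotatable[k]] = k;
  for (int i = 0; i < nat; ++i) {
    if (chain[i] != idr_chain || grp[i] > 0) continue;
    auto it = rot_of.find(resno[i]);
    if (it == rot_of.end()) continue;
    if (atype[i] == AT_N) rN[it->second] = i;
    else if (atype[i] == AT_CA) rCA[it->second] = i;
    else if (atype[i] == AT_C) rC[it->second] = i;
  }
  for (int k = 0; k < nrot; ++k)
    if (rN[k] < 0 || rCA[k] < 0 || rC[k] < 0)
      stop("rotatable residue %d lacks backbone atoms", (int)rotatable[k]);

  // movable rows per (hinge, kind): kind 0 = phi, 1 = psi
  std::vector<std::vector<int>> movable(2 * nrot);
  for (int k = 0; k < nrot; ++k) {
    int r = rotatable[k];
    for (int i = 0; i < nat; ++i) {
      int pr = pseudo[i];
      bool own = (chain[i] == idr_chain && grp[i] == 0 && resno[i] == r);
      bool mv_phi, mv_psi;
      if (!anchor_end) {
        mv_phi = pr > r || (own && (atype[i] == AT_C || atype[i] == AT_O ||
                                    atype[i] == AT_CB));
        mv_psi = pr > r || (own && atype[i] == AT_O);
      } else {
        mv_phi = pr < r;
        mv_psi = pr < r || (own && (atype[i] == AT_N || atype[i] == AT_CB));
      }
      if (own) { // axis atoms and the fixed-side atoms of the hinge residue
        if (atype[i] == AT_N || atype[i] == AT_CA) mv_phi = false;
        if (atype[i] == AT_CA || atype[i] == AT_C) mv_psi = false;
      }
      if (mv_phi) movable[2 * k].push_back(i);
      if (mv_psi) movable[2 * k + 1].push_back(i);
    }
  }
  std::vector<char> is_moved(nat, 0);

  int neff = effector_rows.size();
  std::vector<int> eff(neff);
  for (int i = 0; i < neff; ++i) eff[i] = effector_rows[i] - 1;
  // which effectors move under each hinge (static: movable sets are fixed
  // row sets)
  std::vector<std::vector<char>> eff_moves(2 * nrot,
                                           std::vector<char>(neff, 0));
  for (int h = 0; h < 2 * nrot; ++h) {
    for (int i : movable[h]) is_moved[i] = 1;
    for (int e = 0; e < neff; ++e) eff_moves[h][e] = is_moved[eff[e]];
    for (int i : movable[h]) is_moved[i] = 0;
  }
  std::vector<V3> tgt;
  if (mode != 1) {
    tgt = as_pts(target);
    if ((int)tgt.size() != neff) stop("target/effector pairing mismatch");
  }

  auto objective = [&](const std::vector<V3> &epos) {
    double ss = 0;
    for (int i = 0; i < neff; ++i) {
      if (mode == 1) {
        double d = epos[i].z - z0;
        ss += d * d;
      } else {
        ss += dist2(epos[i], tgt[i]);
      }
    }
    return std::sqrt(ss / neff);
  };
  auto converged_now = [&](const std::vector<V3> &epos, double obj) {
    if (mode == 1) {
      for (int i = 0; i < neff; ++i)
        if (std::fabs(epos[i].z - z0) > tol) return false;
      return true;
    }
    if (mode == 2) return obj < tol;
    return obj <= tol;
  };

  std::vector<V3> epos(neff);
  for (int i = 0; i < neff; ++i) epos[i] = pts[eff[i]];
  double obj = objective(epos);
  std::vector<double> trace;
  trace.push_back(obj);
  std::vector<double> deltas;
  int attempted = 0, accepted = 0, since_accept = 0;
  bool conv = converged_now(epos, obj);

  // one grid over current system + context coordinates, rebuilt only after
  // accepted moves; candidate queries mask out moved atoms (their grid
  // entries hold pre-move positions)
  int nctx = (int)ctx.size();
  std::vector<V3> allpts;
  Grid allgrid;
  auto rebuild_all = [&]() {
    allpts.resize(nat + nctx);
    for (int i = 0; i < nat; ++i) allpts[i] = pts[i];
    for (int i = 0; i < nctx; ++i) allpts[nat + i] = ctx[i];
    allgrid.build(allpts, cutoff);
  };
  if (check_clash) rebuild_all();

  std::vector<V3> moved_new;
  std::vector<V3> etry(neff);
  // last clash-vetoing pair per (hinge, kind, sign): moved atom, partner
  // index (system or nat+context), cleared on every accepted move
  std::vector<std::array<int, 2>> veto(4 * nrot, {-1, -1});
  for (int mv = 0; mv < max_moves && !conv; ++mv) {
    if (stall_limit > 0 && since_accept >= stall_limit) break;
    int k = (int)std::floor(unif_rand() * nrot);
    if (k == nrot) k = nrot - 1;
    int kind = unif_rand() < 0.5 ? 0 : 1;
    double delta = norm_rand() * sigma;
    if (record_deltas) deltas.push_back(delta);
    attempted++;
    const std::vector<int> &S = movable[2 * k + kind];
    if (S.empty()) continue;
    V3 p0, p1;
    if (kind == 0) { p0 = pts[rN[k]]; p1 = pts[rCA[k]]; }
    else { p0 = pts[rCA[k]]; p1 = pts[rC[k]]; }
    V3 ax = unit(p1 - p0);
    double th = delta * DEG, c = std::cos(th), s = std::sin(th);
    auto rot = [&](V3 v) {
      V3 u = v - p0;
      return p0 + u * c + cross(ax, u) * s + ax * (dot(ax, u) * (1 - c));
    };
    // effector-only objective first (no per-move bookkeeping on the
    // rejection path)
    const std::vector<char> &em = eff_moves[2 * k + kind];
    for (int i = 0; i < neff; ++i)
      etry[i] = em[i] ? rot(pts[eff[i]]) : pts[eff[i]];
    double obj_try = objective(etry);
    bool ok = obj_try < obj;
    int vslot = 4 * k + 2 * kind + (delta > 0 ? 1 : 0);
    if (ok && check_clash && veto[vslot][0] >= 0) {
      // re-test the cached blocking pair first: if it still collides at
      // the proposed rotation, reject in O(1)
      int a = veto[vslot][0], j = veto[vslot][1];
      V3 na = rot(pts[a]);
      V3 other = j < nat ? pts[j] : ctx[j - nat];
      if (dist2(na, other) < cutoff * cutoff) {
        since_accept++;
        continue;
      }
    }
    if (ok && check_clash) {
      for (int i : S) is_moved[i] = 1;
      // moved atoms (rotated) against the cached grid of all other atoms;
      // hits on moved atoms are stale entries and are skipped
      moved_new.resize(S.size());
      for (size_t i = 0; i < S.size() && ok; ++i) {
        moved_new[i] = rot(pts[S[i]]);
        int a = S[i];
        int hit_j = -1;
        allgrid.neighbours(moved_new[i], cutoff, [&](int j) {
          if (hit_j >= 0) return;
          if (j < nat) {
            if (is_moved[j]) return;
            if (!excluded(chain[a], resno[a], grp[a], chain[j], resno[j],
                          grp[j]))
              hit_j = j;
          } else {
            int kk = j - nat;
            if (!excluded(chain[a], resno[a], grp[a], ctx_chain[kk],
                          ctx_resno[kk], ctx_grp[kk]))
              hit_j = j;
          }
        });
        if (hit_j >= 0) {
          ok = false;
          veto[vslot] = {a, hit_j};
        }
      }
      if (ok) {
        for (size_t i = 0; i < S.size(); ++i) pts[S[i]] = moved_new[i];
      }
      for (int i : S) is_moved[i] = 0;
    } else if (ok) {
      for (int i : S) pts[i] = rot(pts[i]);
    }
    if (ok) {
      accepted++;
      since_accept = 0;
      obj = obj_try;
      for (int i = 0; i < neff; ++i) epos[i] = pts[eff[i]];
      trace.push_back(obj);
      conv = converged_now(epos, obj);
      if (check_clash && !conv) {
        rebuild_all();
        std::fill(veto.begin(), veto.end(), std::array<int, 2>{-1, -1});
      }
    } else {
      since_accept++;
    }
  }

  NumericMatrix out(nat, 3);
  for (int i = 0; i < nat; ++i) {
    out(i, 0) = pts[i].x; out(i, 1) = pts[i].y; out(i, 2) = pts[i].z;
  }
  List res = List::create(_["xyz"] = out, _["attempted"] = attempted,
                          _["accepted"] = accepted, _["objective"] = obj,
                          _["converged"] = conv,
                          _["trace"] = NumericVector(trace.begin(), trace.end()));
  if (record_deltas)
    res["deltas"] = NumericVector(deltas.begin(), deltas.end());
  return res;
}

// ---------------------------------------------------------------------------
// Exhaustive grid scan over up to 3 hinge dihedrals for toy closure problems:
// the brute-force oracle for ccd_minimize.  Hinges are applied upstream to
// downstream so each grid point corresponds to one dihedral offset vector.
// [[Rcpp::export]]
double cpp_grid_scan(NumericMatrix xyz_in, List movable_sets, List axis_rows,
                     int effector_row, NumericVector target, double step) {
  int nh = movable_sets.size();
  if (nh < 1 || nh > 3) stop("grid scan supports 1-3 hinges");
  std::vector<V3> base = as_pts(xyz_in);
  std::vector<std::vector<int>> S(nh);
  std::vector<std::pair<int, int>> ax(nh);
  for (int h = 0; h < nh; ++h) {
    IntegerVector s = movable_sets[h];
    for (int i = 0; i < s.size(); ++i) S[h].push_back(s[i] - 1);
    IntegerVector a = axis_rows[h];
    ax[h] = {a[0] - 1, a[1] - 1};
  }
  V3 tg = v3(target[0], target[1], target[2]);
  int eff = effector_row - 1;
  int nstep = (int)std::round(360.0 / step);
  double best = R_PosInf;
  auto rotate_set = [&](std::vector<V3> &p, int h, double ang) {
    V3 p0 = p[ax[h].first], ax1 = unit(p[ax[h].second] - p[ax[h].first]);
    double th = ang * DEG, c = std::cos(th), s = std::sin(th);
    for (int i : S[h]) {
      V3 u = p[i] - p0;
      p[i] = p0 + u * c + cross(ax1, u) * s + ax1 * (dot(ax1, u) * (1 - c));
    }
  };
  for (int i0 = 0; i0 < nstep; ++i0) {
    std::vector<V3> p0 = base;
    rotate_set(p0, 0, i0 * step);
    if (nh == 1) {
      double d = std::sqrt(dist2(p0[eff], tg));
      if (d < best) best = d;
      continue;
    }
    for (int i1 = 0; i1 < nstep; ++i1) {
      std::vector<V3> p1 = p0;
      rotate_set(p1, 1, i1 * step);
      if (nh == 2) {
        double d = std::sqrt(dist2(p1[eff], tg));
        if (d < best) best = d;
        continue;
      }
      for (int i2 = 0; i2 < nstep; ++i2) {
        std::vector<V3> p2 = p1;
        rotate_set(p2, 2, i2 * step);
        double d = std::sqrt(dist2(p2[eff], tg));
        if (d < best) best = d;
      }
    }
  }
  return best;
}
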