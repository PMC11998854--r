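// Monte Carlo engine for dynamically triangulated vesicles.
//
// The mesh is a closed, outward-oriented 2-manifold of sphere topology.
// Moves: vertex translation, edge flip, vertex insertion (edge split with
// the new vertex drawn uniformly from a cube centred on the edge midpoint)
// and vertex removal (collapse of a degree-4 vertex onto one of the two
// re-triangulating diagonals, valid only when the vertex lies inside the
// insertion cube of that diagonal, so that insertion and removal form an
// exactly reversible pair).
//
// Energies: discrete Helfrich bending (cotangent Laplacian, mixed Voronoi
// vertex areas), hard square-well tether on edge lengths, per-face quadratic
// area constraint. Acceptance uses Phi = Etot - mu*N - dp*V and the
// generation-rate ratio of the proposed move and its exact reverse; kind
// attempt rates scale with the current vertex/edge counts, and that scaling
// (through the per-slot weight W = N + E(pflip + 2 pexchange)) enters the
// ratio so that detailed balance holds exactly at mu = mu_eq.

// The toolchain enables libstdc++ container assertions by default; the
// structural invariants they guard are checked explicitly (check_mesh,
// paranoia mode in the tests), and the bounds checks dominate the Monte
// Carlo inner loop, so they are disabled for this translation unit.
#ifdef _GLIBCXX_ASSERTIONS
#undef _GLIBCXX_ASSERTIONS
#endif


#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>
#include <array>
#include <random>
#include <algorithm>

using namespace Rcpp;

typedef std::uint64_t ekey_t;

static inline ekey_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<ekey_t>(a) << 32) | static_cast<ekey_t>(b);
}
static inline int ekey_a(ekey_t k) { return static_cast<int>(k >> 32); }
static inline int ekey_b(ekey_t k) { return static_cast<int>(k & 0xffffffffu); }

struct RngMT {
  std::mt19937_64 gen;
  explicit RngMT(std::uint64_t seed) : gen(seed) {}
  double unif() {  // in [0, 1), 53-bit, platform-independent
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // uniform in [0, n), rejection to avoid modulo bias
    std::uint64_t lim = UINT64_MAX - (UINT64_MAX % static_cast<std::uint64_t>(n));
    std::uint64_t x;
    do { x = gen(); } while (x >= lim);
    return static_cast<int>(x % static_cast<std::uint64_t>(n));
  }
};

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

struct Params {
  double kappa, ka, a0, tmin, tmax;
  double mu, dp, kT;
  double pflip, pexch;
  double step, delta_ins;
  int min_vertices, max_vertices;
};

struct EdgeInfo { int f1, f2; };

struct Mesh {
  std::vector<Vec3> X;
  std::vector<std::array<int, 3>> F;          // oriented faces
  std::vector<std::vector<int>> nbr;          // neighbour lists
  std::unordered_map<ekey_t, EdgeInfo> edges; // edge -> adjacent faces
  std::vector<ekey_t> elist;                  // edge list for uniform draws
  std::unordered_map<ekey_t, int> epos;       // edge -> index in elist
  std::vector<int> remv;                      // degree-4 vertices
  std::vector<int> rempos;                    // vertex -> index in remv (-1)

  int nV() const { return static_cast<int>(X.size()); }
  int nE() const { return static_cast<int>(elist.size()); }
  int nF() const { return static_cast<int>(F.size()); }
  int nRem() const { return static_cast<int>(remv.size()); }
  int deg(int v) const { return static_cast<int>(nbr[v].size()); }

  void add_edge(ekey_t k, int f1, int f2) {
    edges[k] = {f1, f2};
    epos[k] = nE();
    elist.push_back(k);
  }
  void drop_edge(ekey_t k) {
    int p = epos[k];
    ekey_t last = elist.back();
    elist[p] = last;
    epos[last] = p;
    elist.pop_back();
    epos.erase(k);
    edges.erase(k);
  }
  void replace_face_ref(ekey_t k, int fold, int fnew) {
    EdgeInfo& e = edges[k];
    if (e.f1 == fold) e.f1 = fnew; else e.f2 = fnew;
  }
  void rem_update(int v) {
    bool want = (deg(v) == 4);
    bool have = (rempos[v] >= 0);
    if (want && !have) {
      rempos[v] = nRem();
      remv.push_back(v);
    } else if (!want && have) {
      int p = rempos[v];
      int last = remv.back();
      remv[p] = last;
      rempos[last] = p;
      remv.pop_back();
      rempos[v] = -1;
    }
  }
  void nbr_add(int a, int b) { nbr[a].push_back(b); rem_update(a); }
  void nbr_drop(int a, int b) {
    std::vector<int>& L = nbr[a];
    for (size_t i = 0; i < L.size(); ++i)
      if (L[i] == b) { L[i] = L.back(); L.pop_back(); break; }
    rem_update(a);
  }

  int third(int f, int a, int b) const {
    for (int c : F[f]) if (c != a && c != b) return c;
    return -1;
  }
  bool has_directed(int f, int a, int b) const {
    const std::array<int, 3>& t = F[f];
    for (int i = 0; i < 3; ++i)
      if (t[i] == a && t[(i + 1) % 3] == b) return true;
    return false;
  }

  double face_area(int f) const {
    const std::array<int, 3>& t = F[f];
    Vec3 u = X[t[1]] - X[t[0]], v = X[t[2]] - X[t[0]];
    return 0.5 * u.cross(v).norm();
  }
  double face_svol(int f) const {  // signed tetra volume against origin
    const std::array<int, 3>& t = F[f];
    return X[t[0]].dot(X[t[1]].cross(X[t[2]])) / 6.0;
  }

  void faces_of(int v, std::vector<int>& out) const {
    out.clear();
    for (int j : nbr[v]) {
      const EdgeInfo& e = edges.at(ekey(v, j));
      if (std::find(out.begin(), out.end(), e.f1) == out.end()) out.push_back(e.f1);
      if (std::find(out.begin(), out.end(), e.f2) == out.end()) out.push_back(e.f2);
    }
  }

  // discrete Helfrich bending contribution of vertex v:
  // (kappa/8) |sum_j (cot a_ij + cot b_ij)(x_v - x_j)|^2 / A_mix(v)
  // with the mixed Voronoi vertex area (circumcentric for non-obtuse
  // triangles, area/2 or area/4 for obtuse ones), which keeps the
  // effective spectral rigidity much closer to the input kappa on rough
  // thermal meshes than the barycentric area does
  double bend_vertex(int v, double kappa) const {
    Vec3 C(0, 0, 0);
    double Amix = 0.0;
    const Vec3& xv = X[v];
    for (int j : nbr[v]) {
      const EdgeInfo& e = edges.at(ekey(v, j));
      double w = 0.0;
      for (int f : {e.f1, e.f2}) {
        int o = third(f, v, j);
        Vec3 u = xv - X[o], t = X[j] - X[o];
        Vec3 cr = u.cross(t);
        double crn = cr.norm();
        if (crn < 1e-14) crn = 1e-14;
        double cot_o = u.dot(t) / crn;  // cot of the angle at o (opposite edge v-j)
        w += cot_o;
        // mixed-area contribution of face f at v, counted once per
        // (face, edge-at-v) pair: for a non-obtuse face, the Voronoi area
        // at v is (1/8)|v-j|^2 cot_o summed over the two edges at v; for
        // an obtuse face, half the face area if the obtuse corner is at
        // v, else a quarter
        Vec3 ev = X[j] - xv;          // edge v -> j
        Vec3 eo = X[o] - xv;          // edge v -> o
        double cos_v = ev.dot(eo);
        Vec3 jv = xv - X[j], jo = X[o] - X[j];
        double cos_j = jv.dot(jo);
        if (cos_v < 0)       Amix += crn / 8.0;   // obtuse at v: area/2, split over 2 edges
        else if (cos_j < 0 || u.dot(t) < 0)
                             Amix += crn / 16.0;  // obtuse elsewhere: area/4, split over 2 edges
        else                 Amix += ev.dot(ev) * cot_o / 8.0;
      }
      C = C + (xv - X[j]) * w;
    }
    if (Amix <= 0) stop("degenerate vertex area in bending energy");
    return kappa / 8.0 * C.dot(C) / Amix;
  }

  double area_energy_face(int f, double ka, double a0) const {
    double d = face_area(f) - a0;
    return 0.5 * ka * d * d;
  }
  bool edge_ok(int a, int b, double tmin, double tmax) const {
    double l = (X[a] - X[b]).norm();
    return l > tmin && l < tmax;
  }
};

static Mesh build_mesh(const NumericMatrix& V, const IntegerMatrix& Fm) {
  Mesh m;
  int nv = V.nrow(), nf = Fm.nrow();
  m.X.resize(nv);
  for (int i = 0; i < nv; ++i) m.X[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  m.F.resize(nf);
  m.nbr.assign(nv, {});
  m.rempos.assign(nv, -1);
  std::unordered_map<ekey_t, std::vector<int>> ef;
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) {
      int a = Fm(f, c) - 1;  // R is 1-based
      if (a < 0 || a >= nv) stop("face index out of range");
      m.F[f][c] = a;
    }
    for (int c = 0; c < 3; ++c) {
      int a = m.F[f][c], b = m.F[f][(c + 1) % 3];
      ef[ekey(a, b)].push_back(f);
    }
  }
  // deterministic edge ordering: sorted keys, not hash order
  std::vector<ekey_t> keys;
  keys.reserve(ef.size());
  for (auto& kv : ef) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  for (ekey_t k : keys) {
    const std::vector<int>& fl = ef[k];
    if (fl.size() != 2)
      stop("mesh is not a closed 2-manifold (edge bordered by %d faces)",
           (int)fl.size());
    m.add_edge(k, fl[0], fl[1]);
    int a = ekey_a(k), b = ekey_b(k);
    m.nbr[a].push_back(b);
    m.nbr[b].push_back(a);
  }
  for (int v = 0; v < nv; ++v) m.rem_update(v);
  return m;
}

static void check_mesh(const Mesh& m) {
  int V = m.nV(), E = m.nE(), F = m.nF();
  if (V - E + F != 2) stop("Euler characteristic != 2");
  for (int v = 0; v < V; ++v)
    if (m.deg(v) < 3) stop("vertex degree < 3");
  for (const ekey_t k : m.elist) {
    int a = ekey_a(k), b = ekey_b(k);
    const EdgeInfo& e = m.edges.at(k);
    if (e.f1 == e.f2) stop("edge with identical faces");
    int fwd = (m.has_directed(e.f1, a, b) ? 1 : 0) +
              (m.has_directed(e.f2, a, b) ? 1 : 0);
    int rev = (m.has_directed(e.f1, b, a) ? 1 : 0) +
              (m.has_directed(e.f2, b, a) ? 1 : 0);
    if (fwd != 1 || rev != 1) stop("inconsistent face orientation at an edge");
  }
}

struct Totals { double Ebend, Earea, Vol, Area; };

static Totals full_totals(const Mesh& m, const Params& p) {
  Totals t{0, 0, 0, 0};
  for (int v = 0; v < m.nV(); ++v) t.Ebend += m.bend_vertex(v, p.kappa);
  for (int f = 0; f < m.nF(); ++f) {
    t.Earea += m.area_energy_face(f, p.ka, p.a0);
    t.Vol += m.face_svol(f);
    t.Area += m.face_area(f);
  }
  return t;
}

struct Tally {
  long att[4] = {0, 0, 0, 0};
  long acc[4] = {0, 0, 0, 0};
  void reset() { for (int i = 0; i < 4; ++i) { att[i] = 0; acc[i] = 0; } }
};

struct PatchSum { double Ebend, Earea, Vol, Area; };

static PatchSum patch_sum(const Mesh& m, const Params& p,
                          const std::vector<int>& verts,
                          const std::vector<int>& faces) {
  PatchSum s{0, 0, 0, 0};
  for (int v : verts) s.Ebend += m.bend_vertex(v, p.kappa);
  for (int f : faces) {
    s.Earea += m.area_energy_face(f, p.ka, p.a0);
    s.Vol += m.face_svol(f);
    s.Area += m.face_area(f);
  }
  return s;
}

static inline double slot_weight(const Mesh& m, const Params& p) {
  return m.nV() + m.nE() * (p.pflip + 2.0 * p.pexch);
}

class Engine {
public:
  Mesh m;
  Params p;
  RngMT rng;
  Totals tot;
  Tally tally;
  bool paranoia;
  // exact cache of per-vertex bending energies: every move whose
  // acceptance can change the bending energy of a vertex carries that
  // vertex in its patch set, so updating the cache for accepted patches
  // keeps it bitwise identical to a fresh evaluation
  std::vector<double> bendCache;

  double cached_bend_sum(const std::vector<int>& verts) const {
    double s = 0;
    for (int v : verts) s += bendCache[v];
    return s;
  }
  // patch sums: "before" reads the bending cache, "after" recomputes and
  // returns the per-vertex values for a later cache update on acceptance
  PatchSum patch_before(const std::vector<int>& verts,
                        const std::vector<int>& faces) const {
    PatchSum s{0, 0, 0, 0};
    s.Ebend = cached_bend_sum(verts);
    for (int f : faces) {
      s.Earea += m.area_energy_face(f, p.ka, p.a0);
      s.Vol += m.face_svol(f);
      s.Area += m.face_area(f);
    }
    return s;
  }
  PatchSum patch_after(const std::vector<int>& verts,
                       const std::vector<int>& faces,
                       std::vector<double>& bvals) const {
    PatchSum s{0, 0, 0, 0};
    bvals.resize(verts.size());
    for (size_t i = 0; i < verts.size(); ++i) {
      bvals[i] = m.bend_vertex(verts[i], p.kappa);
      s.Ebend += bvals[i];
    }
    for (int f : faces) {
      s.Earea += m.area_energy_face(f, p.ka, p.a0);
      s.Vol += m.face_svol(f);
      s.Area += m.face_area(f);
    }
    return s;
  }
  void cache_store(const std::vector<int>& verts,
                   const std::vector<double>& bvals) {
    for (size_t i = 0; i < verts.size(); ++i) bendCache[verts[i]] = bvals[i];
  }
  // exchange-attempt log for chemical-potential reweighting: for each
  // logged attempt, the mu-independent acceptance factor
  // a = gen_ratio * exp(-(dE - dp*dV)/kT); the acceptance probability at
  // chemical potential mu is min(1, a * exp(+mu/kT)) for insertions and
  // min(1, a * exp(-mu/kT)) for removals. Invalid (auto-rejected)
  // proposals are logged as a = 0.
  bool log_exchange = false;
  int log_stride = 1;
  long log_count_ins = 0, log_count_rem = 0;
  std::vector<double> log_ins, log_rem;

  void log_attempt(bool ins, double a) {
    if (!log_exchange) return;
    if (ins) {
      if (log_count_ins++ % log_stride == 0) log_ins.push_back(a);
    } else {
      if (log_count_rem++ % log_stride == 0) log_rem.push_back(a);
    }
  }

  Engine(const NumericMatrix& V, const IntegerMatrix& F, const Params& par,
         std::uint64_t seed, bool paranoia_)
      : m(build_mesh(V, F)), p(par), rng(seed), paranoia(paranoia_) {
    check_mesh(m);
    tot = full_totals(m, p);
    bendCache.resize(m.nV());
    for (int v = 0; v < m.nV(); ++v)
      bendCache[v] = m.bend_vertex(v, p.kappa);
  }

  double phi() const {
    return tot.Ebend + tot.Earea - p.mu * m.nV() - p.dp * tot.Vol;
  }

  bool metropolis(double dphi, double gen_ratio) {
    double a = gen_ratio * std::exp(-dphi / p.kT);
    return a >= 1.0 || rng.unif() < a;
  }

  void accept_totals(const PatchSum& b, const PatchSum& a) {
    tot.Ebend += a.Ebend - b.Ebend;
    tot.Earea += a.Earea - b.Earea;
    tot.Vol += a.Vol - b.Vol;
    tot.Area += a.Area - b.Area;
  }

  void translate() {
    tally.att[0]++;
    int i = rng.unif_int(m.nV());
    Vec3 d((2 * rng.unif() - 1) * p.step, (2 * rng.unif() - 1) * p.step,
           (2 * rng.unif() - 1) * p.step);
    Vec3 xold = m.X[i];
    Vec3 xnew = xold + d;
    for (int j : m.nbr[i]) {
      double l = (xnew - m.X[j]).norm();
      if (l <= p.tmin || l >= p.tmax) return;  // hard tether: reject
    }
    std::vector<int> verts = m.nbr[i];
    verts.push_back(i);
    std::vector<int> faces;
    m.faces_of(i, faces);
    PatchSum b = patch_before(verts, faces);
    m.X[i] = xnew;
    std::vector<double> bvals;
    PatchSum a = patch_after(verts, faces, bvals);
    double dphi = (a.Ebend - b.Ebend) + (a.Earea - b.Earea) -
                  p.dp * (a.Vol - b.Vol);
    if (metropolis(dphi, 1.0)) {
      tally.acc[0]++;
      accept_totals(b, a);
      cache_store(verts, bvals);
    } else {
      m.X[i] = xold;
    }
  }

  // flip edge (i,j), fa containing directed i->j with third vertex k, fb the
  // other face with third vertex l; afterwards fa = (k,i,l), fb = (l,j,k)
  void apply_flip(int i, int j, int k, int l, int fa, int fb) {
    m.drop_edge(ekey(i, j));
    m.F[fa] = {k, i, l};
    m.F[fb] = {l, j, k};
    m.add_edge(ekey(k, l), fa, fb);
    m.replace_face_ref(ekey(j, k), fa, fb);
    m.replace_face_ref(ekey(i, l), fb, fa);
    m.nbr_drop(i, j); m.nbr_drop(j, i);
    m.nbr_add(k, l); m.nbr_add(l, k);
  }

  void flip() {
    tally.att[1]++;
    ekey_t k0 = m.elist[rng.unif_int(m.nE())];
    int i = ekey_a(k0), j = ekey_b(k0);
    EdgeInfo e = m.edges[k0];
    int fa = e.f1, fb = e.f2;
    if (!m.has_directed(fa, i, j)) std::swap(fa, fb);
    int k = m.third(fa, i, j), l = m.third(fb, i, j);
    if (k == l) return;
    if (m.deg(i) <= 3 || m.deg(j) <= 3) return;
    if (m.edges.count(ekey(k, l))) return;
    if (!m.edge_ok(k, l, p.tmin, p.tmax)) return;
    std::vector<int> verts = {i, j, k, l};
    std::vector<int> faces = {fa, fb};
    PatchSum b = patch_before(verts, faces);
    apply_flip(i, j, k, l, fa, fb);
    std::vector<double> bvals;
    PatchSum a = patch_after(verts, faces, bvals);
    double dphi = (a.Ebend - b.Ebend) + (a.Earea - b.Earea) -
                  p.dp * (a.Vol - b.Vol);
    if (metropolis(dphi, 1.0)) {
      tally.acc[1]++;
      accept_totals(b, a);
      cache_store(verts, bvals);
    } else {
      apply_flip(k, l, j, i, fb, fa);  // exact reverse flip
    }
    if (paranoia) check_mesh(m);
  }

  void insertion() {
    tally.att[2]++;
    if (p.max_vertices > 0 && m.nV() >= p.max_vertices) { log_attempt(true, 0); return; }
    double Wb = slot_weight(m, p);
    ekey_t k0 = m.elist[rng.unif_int(m.nE())];
    int i = ekey_a(k0), j = ekey_b(k0);
    EdgeInfo e = m.edges[k0];
    int fa = e.f1, fb = e.f2;
    if (!m.has_directed(fa, i, j)) std::swap(fa, fb);
    int k = m.third(fa, i, j), l = m.third(fb, i, j);
    if (k == l) { log_attempt(true, 0); return; }
    Vec3 mid = (m.X[i] + m.X[j]) * 0.5;
    Vec3 x(mid.x + (2 * rng.unif() - 1) * p.delta_ins,
           mid.y + (2 * rng.unif() - 1) * p.delta_ins,
           mid.z + (2 * rng.unif() - 1) * p.delta_ins);
    for (int q : {i, j, k, l}) {
      double d = (x - m.X[q]).norm();
      if (d <= p.tmin || d >= p.tmax) { log_attempt(true, 0); return; }
    }
    std::vector<int> verts = {i, j, k, l};
    std::vector<int> faces2 = {fa, fb};
    PatchSum b = patch_before(verts, faces2);

    // split (i,j): faces (i,j,k),(j,i,l) -> (i,v,k),(v,j,k),(j,v,l),(v,i,l)
    int v = m.nV();
    m.X.push_back(x);
    m.nbr.push_back({});
    m.rempos.push_back(-1);
    int fc = m.nF(), fd = m.nF() + 1;
    m.F.push_back({j, v, l});
    m.F.push_back({v, i, l});
    m.F[fa] = {i, v, k};
    m.F[fb] = {v, j, k};
    m.drop_edge(ekey(i, j));
    m.add_edge(ekey(v, i), fa, fd);
    m.add_edge(ekey(v, j), fb, fc);
    m.add_edge(ekey(v, k), fa, fb);
    m.add_edge(ekey(v, l), fc, fd);
    m.replace_face_ref(ekey(j, k), fa, fb);
    m.replace_face_ref(ekey(j, l), fb, fc);
    m.replace_face_ref(ekey(i, l), fb, fd);
    m.nbr_drop(i, j); m.nbr_drop(j, i);
    m.nbr_add(i, v); m.nbr_add(j, v); m.nbr_add(k, v); m.nbr_add(l, v);
    m.nbr[v] = {i, j, k, l};
    m.rem_update(v);

    std::vector<int> verts5 = {i, j, k, l, v};
    std::vector<int> faces4 = {fa, fb, fc, fd};
    std::vector<double> bvals;
    PatchSum a = patch_after(verts5, faces4, bvals);
    double dphi = (a.Ebend - b.Ebend) + (a.Earea - b.Earea) - p.mu -
                  p.dp * (a.Vol - b.Vol);
    double Wa = slot_weight(m, p);
    double vc = 8.0 * p.delta_ins * p.delta_ins * p.delta_ins;
    // Pgen(fwd) rate = pexch / (Wb * vc); Pgen(rev) = removal of v on the new
    // mesh = (E' * pexch / Wa) * (1 / nrem') * (1/2)
    double g = (Wb * vc * m.nE()) / (2.0 * Wa * m.nRem());
    log_attempt(true, g * std::exp(-(dphi + p.mu) / p.kT));
    if (metropolis(dphi, g)) {
      tally.acc[2]++;
      accept_totals(b, a);
      for (size_t q = 0; q < 4; ++q) bendCache[verts5[q]] = bvals[q];
      bendCache.push_back(bvals[4]);  // the new vertex is the last index
      if (paranoia) { try { check_mesh(m); } catch (std::exception& e) { stop("after accepted insertion: %s", e.what()); } }
    } else {
      undo_insertion(v, i, j, k, l, fa, fb, fc, fd);
      if (paranoia) { try { check_mesh(m); } catch (std::exception& e) { stop("after rejected insertion: %s", e.what()); } }
    }
  }

  void undo_insertion(int v, int i, int j, int k, int l, int fa, int fb,
                      int fc, int fd) {
    // v is the last vertex; fc, fd the last two face slots
    m.drop_edge(ekey(v, i));
    m.drop_edge(ekey(v, j));
    m.drop_edge(ekey(v, k));
    m.drop_edge(ekey(v, l));
    m.F[fa] = {i, j, k};
    m.F[fb] = {j, i, l};
    m.F.pop_back();
    m.F.pop_back();
    m.add_edge(ekey(i, j), fa, fb);
    m.replace_face_ref(ekey(j, k), fb, fa);
    m.replace_face_ref(ekey(j, l), fc, fb);
    m.replace_face_ref(ekey(i, l), fd, fb);
    m.nbr_drop(i, v); m.nbr_drop(j, v); m.nbr_drop(k, v); m.nbr_drop(l, v);
    m.nbr_add(i, j); m.nbr_add(j, i);
    m.nbr[v].clear();
    m.rem_update(v);  // drop v from the removable list before shrinking
    m.nbr.pop_back();
    m.rempos.pop_back();
    m.X.pop_back();
  }

  // oriented link cycle c0->c1->c2->c3 of a degree-4 vertex v, with
  // fv[q] = face (v, c[q], c[q+1])
  bool link_cycle(int v, int c[4], int fv[4]) {
    if (m.deg(v) != 4) return false;
    int a = m.nbr[v][0];
    for (int q = 0; q < 4; ++q) {
      const EdgeInfo& e = m.edges[ekey(v, a)];
      int f = m.has_directed(e.f1, v, a) ? e.f1 : e.f2;
      c[q] = a;
      fv[q] = f;
      a = m.third(f, v, a);
    }
    return a == c[0];
  }

  void move_face(int from, int to, int& fa, int& fb) {
    if (from == to) return;
    m.F[to] = m.F[from];
    const std::array<int, 3>& t = m.F[to];
    for (int c = 0; c < 3; ++c)
      m.replace_face_ref(ekey(t[c], t[(c + 1) % 3]), from, to);
    if (from == fa) fa = to;
    else if (from == fb) fb = to;
  }

  // drop face slots g1, g2 by swap-with-last; fa, fb updated if relocated
  void drop_faces_pair(int g1, int g2, int& fa, int& fb) {
    int hi = std::max(g1, g2), lo = std::min(g1, g2);
    move_face(m.nF() - 1, hi, fa, fb);
    m.F.pop_back();
    move_face(m.nF() - 1, lo, fa, fb);
    m.F.pop_back();
  }

  void removal() {
    tally.att[3]++;
    if (m.nRem() == 0 || m.nV() <= p.min_vertices) { log_attempt(false, 0); return; }
    double Wb = slot_weight(m, p);
    int nrem_b = m.nRem();
    int Eb = m.nE();
    int v = m.remv[rng.unif_int(nrem_b)];
    int c[4], fv[4];
    if (!link_cycle(v, c, fv)) { log_attempt(false, 0); return; }
    if (rng.unif() < 0.5) {  // other diagonal: rotate the cycle by one
      int t0 = c[0], tf0 = fv[0];
      c[0] = c[1]; c[1] = c[2]; c[2] = c[3]; c[3] = t0;
      fv[0] = fv[1]; fv[1] = fv[2]; fv[2] = fv[3]; fv[3] = tf0;
    }
    int d1 = c[0], o1 = c[1], d2 = c[2], o2 = c[3];
    if (m.edges.count(ekey(d1, d2))) { log_attempt(false, 0); return; }
    if (m.deg(o1) <= 3 || m.deg(o2) <= 3) { log_attempt(false, 0); return; }
    if (!m.edge_ok(d1, d2, p.tmin, p.tmax)) { log_attempt(false, 0); return; }
    // reversibility: v must lie inside the insertion cube of the diagonal
    Vec3 mid = (m.X[d1] + m.X[d2]) * 0.5;
    Vec3 r = m.X[v] - mid;
    if (std::fabs(r.x) >= p.delta_ins || std::fabs(r.y) >= p.delta_ins ||
        std::fabs(r.z) >= p.delta_ins) {
      log_attempt(false, 0);
      return;
    }

    std::vector<int> verts5 = {v, d1, o1, d2, o2};
    std::vector<int> faces4 = {fv[0], fv[1], fv[2], fv[3]};
    PatchSum b = patch_before(verts5, faces4);

    // faces (v,d1,o1),(v,o1,d2),(v,d2,o2),(v,o2,d1) -> (d1,o1,d2),(d1,d2,o2);
    // vertex slot v left orphaned until the move is accepted
    int fa = fv[0], fb = fv[1], fc = fv[2], fd = fv[3];
    Vec3 xv = m.X[v];
    m.drop_edge(ekey(v, d1));
    m.drop_edge(ekey(v, o1));
    m.drop_edge(ekey(v, d2));
    m.drop_edge(ekey(v, o2));
    m.F[fa] = {d1, o1, d2};
    m.F[fb] = {d1, d2, o2};
    m.add_edge(ekey(d1, d2), fa, fb);
    m.replace_face_ref(ekey(o1, d2), fb, fa);
    m.replace_face_ref(ekey(d2, o2), fc, fb);
    m.replace_face_ref(ekey(o2, d1), fd, fb);
    m.nbr_drop(d1, v); m.nbr_drop(o1, v); m.nbr_drop(d2, v); m.nbr_drop(o2, v);
    m.nbr_add(d1, d2); m.nbr_add(d2, d1);
    std::vector<int> saved_nbr_v = m.nbr[v];
    m.nbr[v].clear();
    m.rem_update(v);
    drop_faces_pair(fc, fd, fa, fb);

    std::vector<int> verts4 = {d1, o1, d2, o2};
    std::vector<int> faces2 = {fa, fb};
    std::vector<double> bvals;
    PatchSum a = patch_after(verts4, faces2, bvals);
    double dphi = (a.Ebend - b.Ebend) + (a.Earea - b.Earea) + p.mu -
                  p.dp * (a.Vol - b.Vol);
    double Wa = slot_weight(m, p);
    double vc = 8.0 * p.delta_ins * p.delta_ins * p.delta_ins;
    // Pgen(fwd) rate = (Eb * pexch / Wb) * (1/nrem_b) * (1/2);
    // Pgen(rev) = insertion on the new diagonal = pexch / (Wa * vc)
    double g = (2.0 * Wb * nrem_b) / (Wa * vc * Eb);
    log_attempt(false, g * std::exp(-(dphi - p.mu) / p.kT));
    if (metropolis(dphi, g)) {
      tally.acc[3]++;
      accept_totals(b, a);
      cache_store(verts4, bvals);
      // mirror the vertex compaction in the bending cache
      int last_v = m.nV() - 1;
      if (v != last_v) bendCache[v] = bendCache[last_v];
      bendCache.pop_back();
      compact_vertex(v);
      if (paranoia) { try { check_mesh(m); } catch (std::exception& e) { stop("after accepted removal: %s", e.what()); } }
    } else {
      undo_removal(v, xv, d1, o1, d2, o2, fa, fb, saved_nbr_v);
      if (paranoia) { try { check_mesh(m); } catch (std::exception& e) { stop("after rejected removal: %s", e.what()); } }
    }
  }

  void undo_removal(int v, const Vec3& xv, int d1, int o1, int d2, int o2,
                    int fa, int fb, const std::vector<int>& nbrs) {
    m.drop_edge(ekey(d1, d2));
    int fc = m.nF(), fd = m.nF() + 1;
    m.F.push_back({v, d2, o2});
    m.F.push_back({v, o2, d1});
    m.F[fa] = {v, d1, o1};
    m.F[fb] = {v, o1, d2};
    m.add_edge(ekey(v, d1), fa, fd);
    m.add_edge(ekey(v, o1), fa, fb);
    m.add_edge(ekey(v, d2), fb, fc);
    m.add_edge(ekey(v, o2), fc, fd);
    m.replace_face_ref(ekey(o1, d2), fa, fb);
    m.replace_face_ref(ekey(d2, o2), fb, fc);
    m.replace_face_ref(ekey(o2, d1), fb, fd);
    m.nbr_drop(d1, d2); m.nbr_drop(d2, d1);
    m.nbr[v] = nbrs;
    m.nbr_add(d1, v); m.nbr_add(o1, v); m.nbr_add(d2, v); m.nbr_add(o2, v);
    m.X[v] = xv;
    m.rem_update(v);
  }

  void compact_vertex(int v) {
    int last = m.nV() - 1;
    if (v != last) {
      std::vector<int> ln = m.nbr[last];
      for (int u : ln) {
        EdgeInfo e = m.edges[ekey(last, u)];
        m.drop_edge(ekey(last, u));
        m.add_edge(ekey(v, u), e.f1, e.f2);
        for (int f : {e.f1, e.f2})
          for (int c = 0; c < 3; ++c)
            if (m.F[f][c] == last) m.F[f][c] = v;
        for (size_t q = 0; q < m.nbr[u].size(); ++q)
          if (m.nbr[u][q] == last) m.nbr[u][q] = v;
      }
      m.X[v] = m.X[last];
      m.nbr[v] = ln;
      if (m.rempos[last] >= 0) {
        m.remv[m.rempos[last]] = v;
        m.rempos[v] = m.rempos[last];
      } else {
        m.rempos[v] = -1;
      }
    }
    m.X.pop_back();
    m.nbr.pop_back();
    m.rempos.pop_back();
  }

  void sweep() {
    int M = static_cast<int>(std::lround(slot_weight(m, p)));
    if (M < 1) M = 1;
    for (int s = 0; s < M; ++s) {
      double w = slot_weight(m, p);
      double u = rng.unif() * w;
      double nV = m.nV(), nE = m.nE();
      if (u < nV) translate();
      else if (u < nV + nE * p.pflip) flip();
      else if (u < nV + nE * (p.pflip + p.pexch)) insertion();
      else removal();
    }
  }

  double mean_radius() const {
    Vec3 c(0, 0, 0);
    for (const Vec3& x : m.X) c = c + x;
    c = c * (1.0 / m.nV());
    double r = 0;
    for (const Vec3& x : m.X) r += (x - c).norm();
    return r / m.nV();
  }
};

static Params params_from_list(const List& par) {
  Params p;
  p.kappa = as<double>(par["kappa"]);
  p.ka = as<double>(par["k_a"]);
  p.a0 = as<double>(par["a0"]);
  p.tmin = as<double>(par["tether_min"]);
  p.tmax = as<double>(par["tether_max"]);
  p.mu = as<double>(par["mu"]);
  p.dp = as<double>(par["dp"]);
  p.kT = as<double>(par["kT"]);
  p.pflip = as<double>(par["pflip"]);
  p.pexch = as<double>(par["pexchange"]);
  p.step = as<double>(par["step_size"]);
  p.delta_ins = as<double>(par["insert_halfwidth"]);
  p.min_vertices = as<int>(par["min_vertices"]);
  p.max_vertices = as<int>(par["max_vertices"]);
  return p;
}

static NumericMatrix mesh_V(const Mesh& m) {
  NumericMatrix V(m.nV(), 3);
  for (int i = 0; i < m.nV(); ++i) {
    V(i, 0) = m.X[i].x; V(i, 1) = m.X[i].y; V(i, 2) = m.X[i].z;
  }
  return V;
}
static IntegerMatrix mesh_F(const Mesh& m) {
  IntegerMatrix F(m.nF(), 3);
  for (int f = 0; f < m.nF(); ++f)
    for (int c = 0; c < 3; ++c) F(f, c) = m.F[f][c] + 1;
  return F;
}

// [[Rcpp::export]]
List cpp_run_sweeps(NumericMatrix V, IntegerMatrix F, List par, int nsweeps,
                    int checkpoint_every, double seed, int snapshot_every,
                    bool tune_step, bool paranoia, int log_exchange_stride) {
  Params p = params_from_list(par);
  Engine eng(V, F, p, static_cast<std::uint64_t>(seed), paranoia);
  if (log_exchange_stride > 0) {
    eng.log_exchange = true;
    eng.log_stride = log_exchange_stride;
  }
  std::vector<std::array<double, 17>> rec;
  int nsnap = (snapshot_every > 0) ? nsweeps / snapshot_every : 0;
  List snaps(nsnap);
  IntegerVector snap_t(nsnap);
  int isnap = 0;
  long tr_att_win = 0, tr_acc_win = 0;
  auto record = [&](int t) {
    std::array<double, 17> r;
    r[0] = t;
    r[1] = eng.m.nV();
    r[2] = eng.tot.Vol;
    r[3] = eng.tot.Area;
    r[4] = eng.mean_radius();
    r[5] = eng.tot.Ebend;
    r[6] = eng.tot.Earea;
    r[7] = 0.0;  // tether energy is identically zero in any valid state
    r[8] = eng.phi();
    r[9] = eng.tally.att[0];  r[10] = eng.tally.acc[0];
    r[11] = eng.tally.att[1]; r[12] = eng.tally.acc[1];
    r[13] = eng.tally.att[2]; r[14] = eng.tally.acc[2];
    r[15] = eng.tally.att[3]; r[16] = eng.tally.acc[3];
    rec.push_back(r);
    eng.tally.reset();
  };
  record(0);
  for (int t = 1; t <= nsweeps; ++t) {
    eng.sweep();
    if (tune_step && t % 25 == 0) {
      long att = eng.tally.att[0] - tr_att_win;
      long acc = eng.tally.acc[0] - tr_acc_win;
      if (att > 0) {
        double rate = static_cast<double>(acc) / att;
        if (rate > 0.45) eng.p.step = std::min(eng.p.step * 1.15, 0.5 * eng.p.tmax);
        else if (rate < 0.35) eng.p.step = std::max(eng.p.step / 1.15, 1e-3);
      }
      tr_att_win = eng.tally.att[0];
      tr_acc_win = eng.tally.acc[0];
    }
    if (t % checkpoint_every == 0) {
      record(t);
      tr_att_win = tr_acc_win = 0;
    }
    if (snapshot_every > 0 && t % snapshot_every == 0 && isnap < nsnap) {
      snaps[isnap] = List::create(_["vertices"] = mesh_V(eng.m),
                                  _["faces"] = mesh_F(eng.m));
      snap_t[isnap] = t;
      ++isnap;
    }
    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }
  check_mesh(eng.m);
  NumericMatrix R(static_cast<int>(rec.size()), 17);
  for (size_t i = 0; i < rec.size(); ++i)
    for (int c = 0; c < 17; ++c) R(i, c) = rec[i][c];
  colnames(R) = CharacterVector::create(
      "t", "N", "V", "A", "R", "E_bend", "E_area", "E_tether", "Phi",
      "att_translate", "acc_translate", "att_flip", "acc_flip", "att_insert",
      "acc_insert", "att_remove", "acc_remove");
  return List::create(_["records"] = R, _["vertices"] = mesh_V(eng.m),
                      _["faces"] = mesh_F(eng.m), _["snapshots"] = snaps,
                      _["snapshot_t"] = snap_t, _["step_size"] = eng.p.step,
                      _["log_ins"] = wrap(eng.log_ins),
                      _["log_rem"] = wrap(eng.log_rem));
}

// [[Rcpp::export]]
List cpp_mesh_totals(NumericMatrix V, IntegerMatrix F, double kappa, double ka,
                     double a0, double tmin, double tmax) {
  Params p;
  p.kappa = kappa; p.ka = ka; p.a0 = a0; p.tmin = tmin; p.tmax = tmax;
  Mesh m = build_mesh(V, F);
  Totals t = full_totals(m, p);
  bool teth_ok = true;
  for (const ekey_t k : m.elist)
    if (!m.edge_ok(ekey_a(k), ekey_b(k), tmin, tmax)) teth_ok = false;
  return List::create(_["E_bend"] = t.Ebend, _["E_area"] = t.Earea,
                      _["volume"] = t.Vol, _["area"] = t.Area,
                      _["tether_ok"] = teth_ok);
}

// [[Rcpp::export]]
void cpp_check_mesh(NumericMatrix V, IntegerMatrix F) {
  Mesh m = build_mesh(V, F);
  check_mesh(m);
}
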