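// Dynamically triangulated Monte Carlo engine.
//
// Metropolis sampling of a closed genus-0 triangulated membrane with
// discretized Helfrich bending energy, tethered edges with edge flips for
// fluidity, harmonic area / volume / area-difference constraints, an
// optional umbrella bias on the area difference, and optional bead-chain
// proteins with square-well membrane adhesion. Energy bookkeeping is
// incremental per move; caches are refreshed by full recomputation at a
// fixed sweep interval to keep floating-point drift bounded.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <random>
#include <cstring>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
};
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// squared point-triangle distance with closest point (Ericson, RTCD 5.1.5)
static double pointTriDist2(const V3& p, const V3& a, const V3& b, const V3& c,
                            V3& closest) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { closest = a; V3 d = p - a; return dot(d, d); }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { closest = b; V3 d = p - b; return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    closest = a + ab * v; V3 d = p - closest; return dot(d, d);
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { closest = c; V3 d = p - c; return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    closest = a + ac * w; V3 d = p - closest; return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    closest = b + (c - b) * w; V3 d = p - closest; return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  closest = a + ab * v + ac * w;
  V3 d = p - closest; return dot(d, d);
}

struct Chain {
  int off, nb;                 // offset into bead arrays, bead count
  std::vector<double> theta0;  // nb-2
  std::vector<double> gamma0;  // nb-3, empty => dihedral term off (straight)
};

struct Engine {
  // mesh
  int nv, nt, ne;
  std::vector<V3> X;
  std::vector<std::array<int,3>> T;
  std::vector<std::array<int,2>> EV, ET;
  std::vector<std::array<int,3>> TE;
  std::vector<std::vector<int>> vtris, vedges;
  std::vector<V3> tn;                 // unit normals
  std::vector<double> tarea, tvol;
  std::vector<double> ephi;           // l*phi per edge
  std::vector<double> vM, vA;
  double Atot, Vtot, sumM, sumMM;
  double lmin2, lmax2;
  // model
  double kappa, KA, KV, Kda, Aref, U, d0, d1, Kbond, Kang, Kdih;
  double bias_k, bias_c;
  double Vref, da0;                   // current schedule values
  bool has_da;                        // Kda term active
  bool repair;                        // tether-repair mode: moves that do not
                                      // worsen an existing violation pass

  double tetherViol(double l2) const {
    double l = std::sqrt(l2);
    double lo = std::sqrt(lmin2), hi = std::sqrt(lmax2);
    if (l < lo) return lo - l;
    if (l > hi) return l - hi;
    return 0.0;
  }
  // chains
  std::vector<Chain> chains;
  int nbeads;
  std::vector<V3> B;
  std::vector<int> bchain;            // chain index per bead
  std::vector<double> beadD;
  std::vector<int> beadTri, beadSide;
  double Ebd, Ed;
  // scratch
  std::vector<int> markT, markE, markV;  int stampT, stampE, stampV;
  std::mt19937_64 rng;

  double unif() { return std::uniform_real_distribution<double>(0.0, 1.0)(rng); }
  int unifInt(int n) { return (int)(unif() * n) % n; }

  double daVal() const { return sumM / (2.0 * std::sqrt(M_PI * Atot)); }

  double scalarEnergy() const {
    double e = 2.0 * kappa * sumMM;
    if (KA > 0) { double t = 1.0 - Atot / Aref; e += KA * t * t; }
    if (KV > 0) { double t = 1.0 - Vtot / Vref; e += KV * t * t; }
    double da = daVal();
    if (has_da) { double t = 1.0 - da / da0; e += Kda * t * t; }
    if (bias_k > 0) { double t = da - bias_c; e += 0.5 * bias_k * t * t; }
    return e + Ebd;
  }

  void triGeom(int t) {
    const V3 &a = X[T[t][0]], &b = X[T[t][1]], &c = X[T[t][2]];
    V3 n = cross(b - a, c - a);
    double a2 = norm(n);
    tarea[t] = 0.5 * a2;
    tn[t] = n * (1.0 / a2);
    tvol[t] = dot(a, cross(b, c)) / 6.0;
  }

  // signed dihedral for edge e: angle between outward normals of the two
  // adjacent triangles, sign from triple product with the directed edge as
  // oriented in triangle ET[e][0]; stores l * phi.
  void edgeDihedral(int e) {
    int t1 = ET[e][0], t2 = ET[e][1];
    int i = EV[e][0], j = EV[e][1];
    // direction i->j as traversed by t1?
    const std::array<int,3>& tr = T[t1];
    bool fwd = false;
    for (int k = 0; k < 3; ++k)
      if (tr[k] == i && tr[(k + 1) % 3] == j) { fwd = true; break; }
    V3 ed = fwd ? (X[j] - X[i]) : (X[i] - X[j]);
    double len = norm(ed);
    ed = ed * (1.0 / len);
    const V3 &n1 = tn[t1], &n2 = tn[t2];
    double s = dot(cross(n1, n2), ed);
    double c = dot(n1, n2);
    if (c > 1) c = 1; if (c < -1) c = -1;
    ephi[e] = len * std::atan2(s, c);
  }

  void vertexMA(int v) {
    double m = 0;
    for (int e : vedges[v]) m += ephi[e];
    vM[v] = 0.25 * m;
    double a = 0;
    for (int t : vtris[v]) a += tarea[t];
    vA[v] = a / 3.0;
  }

  void fullRecompute() {
    Atot = Vtot = 0;
    for (int t = 0; t < nt; ++t) { triGeom(t); Atot += tarea[t]; Vtot += tvol[t]; }
    for (int e = 0; e < ne; ++e) edgeDihedral(e);
    sumM = sumMM = 0;
    for (int v = 0; v < nv; ++v) {
      vertexMA(v);
      sumM += vM[v];
      sumMM += vM[v] * vM[v] / vA[v];
    }
    if (nbeads) {
      for (int b = 0; b < nbeads; ++b) beadScanFull(b);
      recomputeEbd();
      recomputeEd();
    }
  }

  void beadScanFull(int b) {
    double best = 1e300; int bt = -1; V3 foot, bestFoot;
    const V3& p = B[b];
    for (int t = 0; t < nt; ++t) {
      // cheap lower bound via first vertex
      V3 dv = p - X[T[t][0]];
      double lb = std::sqrt(dot(dv, dv)) - std::sqrt(lmax2);
      if (lb > 0 && lb * lb > best) continue;
      double d2 = pointTriDist2(p, X[T[t][0]], X[T[t][1]], X[T[t][2]], foot);
      if (d2 < best) { best = d2; bt = t; bestFoot = foot; }
    }
    beadD[b] = std::sqrt(best);
    beadTri[b] = bt;
    beadSide[b] = dot(p - bestFoot, tn[bt]) >= 0 ? 1 : -1;
  }

  void recomputeEbd() {
    Ebd = 0;
    for (int b = 0; b < nbeads; ++b)
      if (beadD[b] <= d1) Ebd -= U * tarea[beadTri[b]];
  }

  double chainEnergy(const Chain& ch) const {
    double e = 0;
    for (int i = 0; i < ch.nb - 1; ++i) {
      double dl = norm(B[ch.off + i + 1] - B[ch.off + i]) - 1.0;
      e += 0.5 * Kbond * dl * dl;
    }
    for (int i = 1; i < ch.nb - 1; ++i) {
      V3 u = B[ch.off + i - 1] - B[ch.off + i];
      V3 w = B[ch.off + i + 1] - B[ch.off + i];
      double c = dot(u, w) / (norm(u) * norm(w));
      if (c > 1) c = 1; if (c < -1) c = -1;
      double dth = std::acos(c) - ch.theta0[i - 1];
      e += 0.5 * Kang * dth * dth;
    }
    if (!ch.gamma0.empty()) {
      for (int i = 0; i < ch.nb - 3; ++i) {
        V3 b1 = B[ch.off + i + 1] - B[ch.off + i];
        V3 b2 = B[ch.off + i + 2] - B[ch.off + i + 1];
        V3 b3 = B[ch.off + i + 3] - B[ch.off + i + 2];
        V3 c1 = cross(b1, b2), c2 = cross(b2, b3);
        double n1 = norm(c1), n2 = norm(c2);
        if (n1 < 1e-12 || n2 < 1e-12) continue;
        double g = std::atan2(dot(cross(c1, c2), b2) / norm(b2), dot(c1, c2));
        double dg = g - ch.gamma0[i];
        while (dg > M_PI) dg -= 2 * M_PI;
        while (dg <= -M_PI) dg += 2 * M_PI;
        e += 0.5 * Kdih * dg * dg;
      }
    }
    return e;
  }

  void recomputeEd() {
    Ed = 0;
    for (const Chain& ch : chains) Ed += chainEnergy(ch);
  }

  // ---- move machinery -------------------------------------------------

  // undo buffers
  std::vector<int> affT, affE, affV, affB;
  std::vector<V3> sav_tn;
  std::vector<double> sav_area, sav_vol, sav_phi, sav_vM, sav_vA;
  std::vector<double> sav_bD; std::vector<int> sav_bT, sav_bS;
  double sav_A, sav_V, sav_sM, sav_sMM, sav_Ebd;

  void collectAffected(const std::vector<int>& tris) {
    affT.clear(); affE.clear(); affV.clear();
    ++stampT; ++stampE; ++stampV;
    for (int t : tris) { if (markT[t] != stampT) { markT[t] = stampT; affT.push_back(t); } }
    for (int t : affT)
      for (int e : TE[t])
        if (markE[e] != stampE) { markE[e] = stampE; affE.push_back(e); }
    for (int e : affE)
      for (int k = 0; k < 2; ++k) {
        int v = EV[e][k];
        if (markV[v] != stampV) { markV[v] = stampV; affV.push_back(v); }
      }
  }

  void saveGeom() {
    sav_tn.clear(); sav_area.clear(); sav_vol.clear();
    for (int t : affT) { sav_tn.push_back(tn[t]); sav_area.push_back(tarea[t]); sav_vol.push_back(tvol[t]); }
    sav_phi.clear();
    for (int e : affE) sav_phi.push_back(ephi[e]);
    sav_vM.clear(); sav_vA.clear();
    for (int v : affV) { sav_vM.push_back(vM[v]); sav_vA.push_back(vA[v]); }
    sav_A = Atot; sav_V = Vtot; sav_sM = sumM; sav_sMM = sumMM; sav_Ebd = Ebd;
  }

  void restoreGeom() {
    for (size_t k = 0; k < affT.size(); ++k) {
      int t = affT[k]; tn[t] = sav_tn[k]; tarea[t] = sav_area[k]; tvol[t] = sav_vol[k];
    }
    for (size_t k = 0; k < affE.size(); ++k) ephi[affE[k]] = sav_phi[k];
    for (size_t k = 0; k < affV.size(); ++k) { vM[affV[k]] = sav_vM[k]; vA[affV[k]] = sav_vA[k]; }
    Atot = sav_A; Vtot = sav_V; sumM = sav_sM; sumMM = sav_sMM; Ebd = sav_Ebd;
  }

  void applyGeom() {
    for (int t : affT) { Atot -= tarea[t]; Vtot -= tvol[t]; }
    for (int v : affV) { sumM -= vM[v]; sumMM -= vM[v] * vM[v] / vA[v]; }
    for (int t : affT) { triGeom(t); Atot += tarea[t]; Vtot += tvol[t]; }
    for (int e : affE) edgeDihedral(e);
    for (int v : affV) { vertexMA(v); sumM += vM[v]; sumMM += vM[v] * vM[v] / vA[v]; }
  }

  // update bead states after triangles in affT moved/changed.
  // returns false -> hard rejection (hard core or membrane crossing).
  bool updateBeads() {
    if (!nbeads) return true;
    affB.clear(); sav_bD.clear(); sav_bT.clear(); sav_bS.clear();
    for (int b = 0; b < nbeads; ++b) {
      bool touch = (markT[beadTri[b]] == stampT);
      double bestd2 = -1; int bestt = -1; V3 foot, bf;
      if (!touch) {
        // could a moved triangle now be closer?
        double cur2 = beadD[b] * beadD[b];
        for (int t : affT) {
          double d2 = pointTriDist2(B[b], X[T[t][0]], X[T[t][1]], X[T[t][2]], foot);
          if (d2 < cur2 && (bestd2 < 0 || d2 < bestd2)) { bestd2 = d2; bestt = t; bf = foot; }
        }
        if (bestt < 0) continue;  // state unchanged
      }
      affB.push_back(b);
      sav_bD.push_back(beadD[b]); sav_bT.push_back(beadTri[b]); sav_bS.push_back(beadSide[b]);
      if (touch) {
        beadScanFull(b);
      } else {
        beadD[b] = std::sqrt(bestd2); beadTri[b] = bestt;
        beadSide[b] = dot(B[b] - bf, tn[bestt]) >= 0 ? 1 : -1;
      }
      if (beadD[b] <= d0) return false;
      if (beadSide[b] != sav_bS.back()) return false;
    }
    // recompute adhesion contributions of affected beads and beads bound to
    // affected triangles (area changes): simplest exact update is a full Ebd
    // recompute over the (small) bead set.
    recomputeEbd();
    return true;
  }

  void restoreBeads() {
    for (size_t k = 0; k < affB.size(); ++k) {
      int b = affB[k];
      beadD[b] = sav_bD[k]; beadTri[b] = sav_bT[k]; beadSide[b] = sav_bS[k];
    }
  }

  bool vertexMove(double width, double T_) {
    int v = unifInt(nv);
    V3 disp((unif() - 0.5) * 2 * width, (unif() - 0.5) * 2 * width,
            (unif() - 0.5) * 2 * width);
    V3 old = X[v], nw = old + disp;
    // tether
    for (int e : vedges[v]) {
      int u = EV[e][0] == v ? EV[e][1] : EV[e][0];
      V3 d = nw - X[u];
      double l2 = dot(d, d);
      if (l2 < lmin2 || l2 > lmax2) {
        if (!repair) return false;
        V3 dold = old - X[u];
        if (tetherViol(l2) > tetherViol(dot(dold, dold)) + 1e-12) return false;
      }
    }
    double e0 = scalarEnergy();
    collectAffected(vtris[v]);
    saveGeom();
    X[v] = nw;
    applyGeom();
    bool ok = updateBeads();
    double e1 = ok ? scalarEnergy() : 0;
    if (!ok || (e1 > e0 && (T_ <= 0 || unif() >= std::exp(-(e1 - e0) / T_)))) {
      X[v] = old;
      restoreGeom();
      restoreBeads();
      return false;
    }
    return true;
  }

  bool edgeExists(int a, int b) const {
    for (int e : vedges[a]) {
      if (EV[e][0] == b || EV[e][1] == b) return true;
    }
    return false;
  }

  bool flipMove(double T_) {
    int e = unifInt(ne);
    int t1 = ET[e][0], t2 = ET[e][1];
    int i = EV[e][0], j = EV[e][1];
    int k = -1, m = -1;
    for (int c = 0; c < 3; ++c) {
      int w = T[t1][c]; if (w != i && w != j) k = w;
      int w2 = T[t2][c]; if (w2 != i && w2 != j) m = w2;
    }
    if (k < 0 || m < 0 || k == m) return false;
    if ((int)vedges[i].size() <= 3 || (int)vedges[j].size() <= 3) return false;
    if (edgeExists(k, m)) return false;
    {
      V3 d = X[k] - X[m];
      double l2 = dot(d, d);
      if (l2 < lmin2 || l2 > lmax2) {
        if (!repair) return false;
        V3 dold = X[i] - X[j];
        if (tetherViol(l2) > tetherViol(dot(dold, dold)) + 1e-12) return false;
      }
    }
    // orientation: does t1 traverse i->j?
    bool fwd = false;
    for (int c = 0; c < 3; ++c)
      if (T[t1][c] == i && T[t1][(c + 1) % 3] == j) { fwd = true; break; }
    std::array<int,3> n1t, n2t;
    if (fwd) { n1t = {i, m, k}; n2t = {j, k, m}; }
    else     { n1t = {i, k, m}; n2t = {j, m, k}; }
    // degenerate new triangles?
    {
      V3 c1 = cross(X[n1t[1]] - X[n1t[0]], X[n1t[2]] - X[n1t[0]]);
      V3 c2 = cross(X[n2t[1]] - X[n2t[0]], X[n2t[2]] - X[n2t[0]]);
      if (norm(c1) < 1e-12 || norm(c2) < 1e-12) return false;
    }
    double e0 = scalarEnergy();
    // save connectivity
    std::array<int,3> o1 = T[t1], o2 = T[t2];
    std::array<int,2> oEV = EV[e];
    std::array<int,3> oTE1 = TE[t1], oTE2 = TE[t2];
    collectAffected({t1, t2});
    saveGeom();
    // --- commit connectivity ---
    T[t1] = n1t; T[t2] = n2t;
    EV[e][0] = std::min(k, m); EV[e][1] = std::max(k, m);
    // vedges: e moves from i,j to k,m
    eraseVal(vedges[i], e); eraseVal(vedges[j], e);
    vedges[k].push_back(e); vedges[m].push_back(e);
    // vtris: t1 loses j gains m; t2 loses i gains k
    eraseVal(vtris[j], t1); vtris[m].push_back(t1);
    eraseVal(vtris[i], t2); vtris[k].push_back(t2);
    // TE rebuild for t1,t2; boundary edges (j,k) and (i,m) swap triangle slot
    int e_jk = findEdge(j, k), e_im = findEdge(i, m);
    replaceVal(ET[e_jk], t1, t2);
    replaceVal(ET[e_im], t2, t1);
    rebuildTE(t1); rebuildTE(t2);
    // affected edge set must include the 4 quad edges + e (collectAffected
    // used old TE; rebuild affE from new TE plus old to be safe)
    ++stampE;
    std::vector<int> ae;
    for (int t : affT) for (int eg : TE[t]) if (markE[eg] != stampE) { markE[eg] = stampE; ae.push_back(eg); }
    for (int eg : affE) if (markE[eg] != stampE) { markE[eg] = stampE; ae.push_back(eg); }
    // affV: endpoints (i,j,k,m) already in affV via old edges
    std::vector<int> oldAffE = affE;
    std::vector<double> oldSavPhi = sav_phi;
    affE = ae;
    sav_phi.clear();
    // phi values for edges not saved yet: those in ae but not oldAffE have
    // unchanged values until applyGeom; save from current cache
    sav_phi.resize(affE.size());
    for (size_t q = 0; q < affE.size(); ++q) sav_phi[q] = ephi[affE[q]];
    // overwrite with original saved values where available
    for (size_t q = 0; q < oldAffE.size(); ++q)
      for (size_t r = 0; r < affE.size(); ++r)
        if (affE[r] == oldAffE[q]) { sav_phi[r] = oldSavPhi[q]; break; }
    applyGeom();
    bool ok = updateBeads();
    // beads may also now be closer to the two re-shaped triangles; updateBeads
    // handles that via affT (t1,t2 are in affT).
    double e1 = ok ? scalarEnergy() : 0;
    if (!ok || (e1 > e0 && (T_ <= 0 || unif() >= std::exp(-(e1 - e0) / T_)))) {
      // undo connectivity
      T[t1] = o1; T[t2] = o2;
      EV[e] = oEV;
      eraseVal(vedges[k], e); eraseVal(vedges[m], e);
      vedges[i].push_back(e); vedges[j].push_back(e);
      eraseVal(vtris[m], t1); vtris[j].push_back(t1);
      eraseVal(vtris[k], t2); vtris[i].push_back(t2);
      replaceVal(ET[e_jk], t2, t1);
      replaceVal(ET[e_im], t1, t2);
      TE[t1] = oTE1; TE[t2] = oTE2;
      restoreGeom();
      restoreBeads();
      return false;
    }
    return true;
  }

  static void eraseVal(std::vector<int>& v, int val) {
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i] == val) { v[i] = v.back(); v.pop_back(); return; }
  }
  static void replaceVal(std::array<int,2>& a, int oldv, int newv) {
    if (a[0] == oldv) a[0] = newv; else if (a[1] == oldv) a[1] = newv;
  }
  int findEdge(int a, int b) const {
    for (int e : vedges[a]) if (EV[e][0] == b || EV[e][1] == b) return e;
    return -1;
  }
  void rebuildTE(int t) {
    for (int c = 0; c < 3; ++c)
      TE[t][c] = findEdge(T[t][c], T[t][(c + 1) % 3]);
  }

  // local chain energy terms involving bead b (global index)
  double localChainEnergy(int b) const {
    const Chain& ch = chains[bchain[b]];
    int i = b - ch.off;  // local index
    double e = 0;
    for (int q = std::max(0, i - 1); q <= std::min(ch.nb - 2, i); ++q) {
      double dl = norm(B[ch.off + q + 1] - B[ch.off + q]) - 1.0;
      e += 0.5 * Kbond * dl * dl;
    }
    for (int q = std::max(1, i - 1); q <= std::min(ch.nb - 2, i + 1); ++q) {
      V3 u = B[ch.off + q - 1] - B[ch.off + q];
      V3 w = B[ch.off + q + 1] - B[ch.off + q];
      double c = dot(u, w) / (norm(u) * norm(w));
      if (c > 1) c = 1; if (c < -1) c = -1;
      double dth = std::acos(c) - ch.theta0[q - 1];
      e += 0.5 * Kang * dth * dth;
    }
    if (!ch.gamma0.empty()) {
      for (int q = std::max(0, i - 3); q <= std::min(ch.nb - 4, i); ++q) {
        V3 b1 = B[ch.off + q + 1] - B[ch.off + q];
        V3 b2 = B[ch.off + q + 2] - B[ch.off + q + 1];
        V3 b3 = B[ch.off + q + 3] - B[ch.off + q + 2];
        V3 c1 = cross(b1, b2), c2 = cross(b2, b3);
        double nn1 = norm(c1), nn2 = norm(c2);
        if (nn1 < 1e-12 || nn2 < 1e-12) continue;
        double g = std::atan2(dot(cross(c1, c2), b2) / norm(b2), dot(c1, c2));
        double dg = g - ch.gamma0[q];
        while (dg > M_PI) dg -= 2 * M_PI;
        while (dg <= -M_PI) dg += 2 * M_PI;
        e += 0.5 * Kdih * dg * dg;
      }
    }
    return e;
  }

  bool beadMove(double width, double T_) {
    int b = unifInt(nbeads);
    V3 old = B[b];
    V3 nw(old.x + (unif() - 0.5) * 2 * width,
          old.y + (unif() - 0.5) * 2 * width,
          old.z + (unif() - 0.5) * 2 * width);
    // inter-chain repulsion (hard core at 1 l)
    for (int q = 0; q < nbeads; ++q) {
      if (bchain[q] == bchain[b]) continue;
      V3 d = nw - B[q];
      if (dot(d, d) < 1.0) return false;
    }
    // membrane distance
    double oldD = beadD[b]; int oldT = beadTri[b]; int oldS = beadSide[b];
    double eloc0 = localChainEnergy(b);
    double ebd0 = (oldD <= d1) ? -U * tarea[oldT] : 0.0;
    B[b] = nw;
    beadScanFull(b);
    if (beadD[b] <= d0 || beadSide[b] != oldS) {
      B[b] = old; beadD[b] = oldD; beadTri[b] = oldT; beadSide[b] = oldS;
      return false;
    }
    double eloc1 = localChainEnergy(b);
    double ebd1 = (beadD[b] <= d1) ? -U * tarea[beadTri[b]] : 0.0;
    double dE = (eloc1 - eloc0) + (ebd1 - ebd0);
    if (dE > 0 && (T_ <= 0 || unif() >= std::exp(-dE / T_))) {
      B[b] = old; beadD[b] = oldD; beadTri[b] = oldT; beadSide[b] = oldS;
      return false;
    }
    Ebd += ebd1 - ebd0;
    Ed += eloc1 - eloc0;
    return true;
  }
};

static void buildEdgesCpp(Engine& E) {
  int nv = E.nv, nt = E.nt;
  // map (min,max) -> edge id via per-vertex adjacency
  E.EV.clear(); E.ET.clear();
  std::vector<std::vector<std::pair<int,int>>> vmap(nv); // (other, edge id)
  auto getEdge = [&](int a, int b) -> int {
    int lo = std::min(a, b), hi = std::max(a, b);
    for (auto& pr : vmap[lo]) if (pr.first == hi) return pr.second;
    int id = (int)E.EV.size();
    E.EV.push_back({lo, hi});
    E.ET.push_back({-1, -1});
    vmap[lo].push_back({hi, id});
    return id;
  };
  E.TE.assign(nt, {-1, -1, -1});
  for (int t = 0; t < nt; ++t) {
    for (int c = 0; c < 3; ++c) {
      int e = getEdge(E.T[t][c], E.T[t][(c + 1) % 3]);
      E.TE[t][c] = e;
      if (E.ET[e][0] < 0) E.ET[e][0] = t;
      else if (E.ET[e][1] < 0) E.ET[e][1] = t;
      else stop("non-manifold edge");
    }
  }
  E.ne = (int)E.EV.size();
  for (int e = 0; e < E.ne; ++e)
    if (E.ET[e][1] < 0) stop("mesh not closed (boundary edge)");
  E.vedges.assign(nv, {});
  E.vtris.assign(nv, {});
  for (int e = 0; e < E.ne; ++e) {
    E.vedges[E.EV[e][0]].push_back(e);
    E.vedges[E.EV[e][1]].push_back(e);
  }
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) E.vtris[E.T[t][c]].push_back(t);
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix Vm, IntegerMatrix Tm,
                double lmin, double lmax,
                List chainList, List model,
                NumericVector Tvec, NumericVector Vrefvec, NumericVector da0vec,
                double wv, double wb,
                bool tune, int tune_interval, double target_acc,
                int stride, double seed, bool record_da,
                int refresh_every, bool repair) {
  Engine E;
  E.nv = Vm.nrow(); E.nt = Tm.nrow();
  E.X.resize(E.nv);
  for (int v = 0; v < E.nv; ++v) E.X[v] = V3(Vm(v,0), Vm(v,1), Vm(v,2));
  E.T.resize(E.nt);
  for (int t = 0; t < E.nt; ++t) E.T[t] = {Tm(t,0), Tm(t,1), Tm(t,2)};
  buildEdgesCpp(E);
  E.lmin2 = lmin * lmin; E.lmax2 = lmax * lmax;
  E.tn.resize(E.nt); E.tarea.resize(E.nt); E.tvol.resize(E.nt);
  E.ephi.resize(E.ne); E.vM.resize(E.nv); E.vA.resize(E.nv);
  E.markT.assign(E.nt, 0); E.markE.assign(E.ne, 0); E.markV.assign(E.nv, 0);
  E.stampT = E.stampE = E.stampV = 0;

  E.kappa = as<double>(model["kappa"]);
  E.KA = as<double>(model["K_A"]); E.KV = as<double>(model["K_V"]);
  E.Kda = as<double>(model["K_da"]);
  E.Aref = as<double>(model["A_ref"]);
  E.U = as<double>(model["U"]); E.d0 = as<double>(model["d0"]); E.d1 = as<double>(model["d1"]);
  E.Kbond = as<double>(model["K_bond"]); E.Kang = as<double>(model["K_ang"]);
  E.Kdih = as<double>(model["K_dih"]);
  E.bias_k = as<double>(model["bias_k"]); E.bias_c = as<double>(model["bias_c"]);
  E.has_da = E.Kda > 0;
  E.repair = repair;

  // chains
  E.nbeads = 0;
  for (int c = 0; c < chainList.size(); ++c) {
    List ch = chainList[c];
    NumericMatrix bx = ch["x"];
    Chain C;
    C.off = E.nbeads; C.nb = bx.nrow();
    C.theta0 = as<std::vector<double>>(ch["theta0"]);
    if (!Rf_isNull(ch["gamma0"])) {
      NumericVector g0 = ch["gamma0"];
      if (g0.size() && !NumericVector::is_na(g0[0]))
        C.gamma0 = as<std::vector<double>>(g0);
    }
    for (int b = 0; b < C.nb; ++b) {
      E.B.push_back(V3(bx(b,0), bx(b,1), bx(b,2)));
      E.bchain.push_back(c);
    }
    E.nbeads += C.nb;
    E.chains.push_back(C);
  }
  E.beadD.resize(E.nbeads); E.beadTri.resize(E.nbeads); E.beadSide.resize(E.nbeads);
  E.Ebd = E.Ed = 0;

  E.rng.seed((uint64_t)seed);

  int nsweeps = Tvec.size();
  bool schedV = Vrefvec.size() > 1, schedD = da0vec.size() > 1;
  E.Vref = Vrefvec[0]; E.da0 = da0vec[0];
  E.fullRecompute();

  int nrec = (stride > 0) ? (nsweeps / stride) : 0;
  NumericMatrix obs(nrec, 14);
  NumericVector daSeries(record_da ? nsweeps : 0);
  long accV = 0, attV = 0, accF = 0, attF = 0, accB = 0, attB = 0;
  long winAccV = 0, winAttV = 0, winAccB = 0, winAttB = 0;
  int irec = 0;

  for (int s = 0; s < nsweeps; ++s) {
    double T_ = Tvec[s];
    if (schedV) E.Vref = Vrefvec[s];
    if (schedD) E.da0 = da0vec[s];
    int nmove = E.nv + E.ne + E.nbeads;
    for (int a = 0; a < nmove; ++a) {
      double r = E.unif() * nmove;
      if (r < E.nv) {
        ++attV; ++winAttV;
        if (E.vertexMove(wv, T_)) { ++accV; ++winAccV; }
      } else if (r < E.nv + E.ne) {
        ++attF;
        if (E.flipMove(T_)) ++accF;
      } else {
        ++attB; ++winAttB;
        if (E.beadMove(wb, T_)) { ++accB; ++winAccB; }
      }
    }
    if (tune && (s + 1) % tune_interval == 0) {
      if (winAttV > 0) {
        double r = (double)winAccV / winAttV;
        if (r > target_acc + 0.05) wv *= 1.2;
        else if (r < target_acc - 0.05) wv /= 1.2;
        winAccV = winAttV = 0;
      }
      if (winAttB > 0) {
        double r = (double)winAccB / winAttB;
        if (r > target_acc + 0.05) wb *= 1.2;
        else if (r < target_acc - 0.05) wb /= 1.2;
        winAccB = winAttB = 0;
      }
    }
    if (refresh_every > 0 && (s + 1) % refresh_every == 0) E.fullRecompute();
    if (record_da) daSeries[s] = E.daVal();
    if (stride > 0 && (s + 1) % stride == 0 && irec < nrec) {
      double da = E.daVal();
      double Eb = 2 * E.kappa * E.sumMM;
      double ea = E.KA > 0 ? E.KA * std::pow(1 - E.Atot / E.Aref, 2) : 0;
      double ev = E.KV > 0 ? E.KV * std::pow(1 - E.Vtot / E.Vref, 2) : 0;
      double eda = E.has_da ? E.Kda * std::pow(1 - da / E.da0, 2) : 0;
      double ebias = E.bias_k > 0 ? 0.5 * E.bias_k * std::pow(da - E.bias_c, 2) : 0;
      obs(irec, 0) = s + 1; obs(irec, 1) = Eb; obs(irec, 2) = ea; obs(irec, 3) = ev;
      obs(irec, 4) = eda; obs(irec, 5) = ebias; obs(irec, 6) = E.Ebd; obs(irec, 7) = E.Ed;
      obs(irec, 8) = E.Atot; obs(irec, 9) = E.Vtot;
      obs(irec, 10) = 6 * std::sqrt(M_PI) * E.Vtot / std::pow(E.Atot, 1.5);
      obs(irec, 11) = da;
      obs(irec, 12) = attV ? (double)accV / attV : NA_REAL;
      obs(irec, 13) = attF ? (double)accF / attF : NA_REAL;
      ++irec;
    }
  }
  E.fullRecompute();

  NumericMatrix Xout(E.nv, 3);
  for (int v = 0; v < E.nv; ++v) { Xout(v,0) = E.X[v].x; Xout(v,1) = E.X[v].y; Xout(v,2) = E.X[v].z; }
  IntegerMatrix Tout(E.nt, 3);
  for (int t = 0; t < E.nt; ++t) { Tout(t,0) = E.T[t][0]; Tout(t,1) = E.T[t][1]; Tout(t,2) = E.T[t][2]; }
  List chOut(E.chains.size());
  for (size_t c = 0; c < E.chains.size(); ++c) {
    const Chain& C = E.chains[c];
    NumericMatrix bx(C.nb, 3);
    for (int b = 0; b < C.nb; ++b) {
      bx(b,0) = E.B[C.off + b].x; bx(b,1) = E.B[C.off + b].y; bx(b,2) = E.B[C.off + b].z;
    }
    chOut[c] = bx;
  }
  double da = E.daVal();
  return List::create(
    _["x"] = Xout, _["tri"] = Tout, _["chains"] = chOut,
    _["obs"] = obs, _["da_series"] = daSeries,
    _["E_b"] = 2 * E.kappa * E.sumMM, _["A"] = E.Atot, _["V"] = E.Vtot,
    _["da"] = da,
    _["v"] = 6 * std::sqrt(M_PI) * E.Vtot / std::pow(E.Atot, 1.5),
    _["E_bd"] = E.Ebd, _["E_d"] = E.Ed,
    _["acc_vertex"] = attV ? (double)accV / attV : NA_REAL,
    _["acc_flip"] = attF ? (double)accF / attF : NA_REAL,
    _["acc_bead"] = attB ? (double)accB / attB : NA_REAL,
    _["width_vertex"] = wv, _["width_bead"] = wb);
}

// [[Rcpp::export]]
List cpp_point_mesh_distance(NumericVector p, NumericMatrix Vm, IntegerMatrix Tm) {
  V3 pt(p[0], p[1], p[2]);
  int nt = Tm.nrow();
  std::vector<V3> X(Vm.nrow());
  for (int v = 0; v < Vm.nrow(); ++v) X[v] = V3(Vm(v,0), Vm(v,1), Vm(v,2));
  double best = 1e300; int bt = -1; V3 foot, bestFoot;
  for (int t = 0; t < nt; ++t) {
    double d2 = pointTriDist2(pt, X[Tm(t,0)], X[Tm(t,1)], X[Tm(t,2)], foot);
    if (d2 < best) { best = d2; bt = t; bestFoot = foot; }
  }
  V3 a = X[Tm(bt,0)], b = X[Tm(bt,1)], c = X[Tm(bt,2)];
  V3 n = cross(b - a, c - a);
  int side = dot(pt - bestFoot, n) >= 0 ? 1 : -1;
  return List::create(_["d"] = std::sqrt(best), _["triangle"] = bt, _["side"] = side);
}

// Count ray-surface crossings from an origin along given directions and
// return the sorted hit distances per direction (Moller-Trumbore).
// [[Rcpp::export]]
List cpp_ray_crossings(NumericVector origin, NumericMatrix dirs,
                       NumericMatrix Vm, IntegerMatrix Tm) {
  V3 o(origin[0], origin[1], origin[2]);
  int nd = dirs.nrow(), nt = Tm.nrow();
  std::vector<V3> X(Vm.nrow());
  for (int v = 0; v < Vm.nrow(); ++v) X[v] = V3(Vm(v,0), Vm(v,1), Vm(v,2));
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    V3 dir(dirs(d,0), dirs(d,1), dirs(d,2));
    std::vector<double> hits;
    for (int t = 0; t < nt; ++t) {
      V3 a = X[Tm(t,0)], b = X[Tm(t,1)], c = X[Tm(t,2)];
      V3 e1 = b - a, e2 = c - a;
      V3 h = cross(dir, e2);
      double det = dot(e1, h);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      V3 s = o - a;
      double u = dot(s, h) * inv;
      if (u < 0 || u > 1) continue;
      V3 q = cross(s, e1);
      double vv = dot(dir, q) * inv;
      if (vv < 0 || u + vv > 1) continue;
      double tt = dot(e2, q) * inv;
      if (tt > 1e-12) hits.push_back(tt);
    }
    std::sort(hits.begin(), hits.end());
    out[d] = NumericVector(hits.begin(), hits.end());
  }
  return out;
}
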