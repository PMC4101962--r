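#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vadd(const Vec3& a, const Vec3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 vscale(const Vec3& a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double vdot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vnorm2(const Vec3& a) { return vdot(a, a); }
inline double vnorm(const Vec3& a) { return std::sqrt(vnorm2(a)); }

inline Vec3 asVec(const NumericVector& v) { return {v[0], v[1], v[2]}; }

inline double clamp01(double t) { return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t); }

// Closest point on segment [a,b] to point p; returns parameter t in [0,1].
inline double closestParamPointSegment(const Vec3& p, const Vec3& a, const Vec3& b) {
  Vec3 ab = vsub(b, a);
  double denom = vnorm2(ab);
  if (denom <= 0.0) return 0.0;
  return clamp01(vdot(vsub(p, a), ab) / denom);
}

// Closest point on triangle (t0,t1,t2) to point p (Ericson, Real-Time Collision Detection 5.1.5).
inline Vec3 closestPtPointTriangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

// Closest points between segments [p1,q1] and [p2,q2] (Ericson 5.1.9).
inline void closestPtSegSeg(const Vec3& p1, const Vec3& q1, const Vec3& p2, const Vec3& q2,
                            double& s, double& t, Vec3& c1, Vec3& c2) {
  Vec3 d1 = vsub(q1, p1), d2 = vsub(q2, p2), r = vsub(p1, p2);
  double a = vnorm2(d1), e = vnorm2(d2), f = vdot(d2, r);
  const double EPS = 1e-30;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0; c1 = p1; c2 = p2; return;
  }
  if (a <= EPS) {
    s = 0.0; t = clamp01(f / e);
  } else {
    double c = vdot(d1, r);
    if (e <= EPS) {
      t = 0.0; s = clamp01(-c / a);
    } else {
      double b = vdot(d1, d2);
      double denom = a * e - b * b;
      s = (denom > 0.0) ? clamp01((b * f - c * e) / denom) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = clamp01(-c / a); }
      else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
    }
  }
  c1 = vadd(p1, vscale(d1, s));
  c2 = vadd(p2, vscale(d2, t));
}

// Minimum distance between segment [a,b] and triangle (t0,t1,t2),
// with witness points pa (on segment) and pm (on triangle).
double segTriDistance(const Vec3& a, const Vec3& b,
                      const Vec3& t0, const Vec3& t1, const Vec3& t2,
                      Vec3& pa, Vec3& pm) {
  double best = std::numeric_limits<double>::infinity();
  // segment endpoints against the triangle
  {
    Vec3 q = closestPtPointTriangle(a, t0, t1, t2);
    double d = vnorm(vsub(a, q));
    if (d < best) { best = d; pa = a; pm = q; }
    q = closestPtPointTriangle(b, t0, t1, t2);
    d = vnorm(vsub(b, q));
    if (d < best) { best = d; pa = b; pm = q; }
  }
  // segment against the three triangle edges
  const Vec3* e0[3] = {&t0, &t1, &t2};
  const Vec3* e1[3] = {&t1, &t2, &t0};
  for (int i = 0; i < 3; ++i) {
    double s, t; Vec3 c1, c2;
    closestPtSegSeg(a, b, *e0[i], *e1[i], s, t, c1, c2);
    double d = vnorm(vsub(c1, c2));
    if (d < best) { best = d; pa = c1; pm = c2; }
  }
  // piercing through the interior
  Vec3 n = vcross(vsub(t1, t0), vsub(t2, t0));
  double da = vdot(vsub(a, t0), n), db = vdot(vsub(b, t0), n);
  if (da * db < 0.0) {
    double t = da / (da - db);
    Vec3 p = vadd(a, vscale(vsub(b, a), t));
    // barycentric containment
    Vec3 v0 = vsub(t1, t0), v1 = vsub(t2, t0), v2 = vsub(p, t0);
    double d00 = vdot(v0, v0), d01 = vdot(v0, v1), d11 = vdot(v1, v1);
    double d20 = vdot(v2, v0), d21 = vdot(v2, v1);
    double denom = d00 * d11 - d01 * d01;
    if (denom > 0.0) {
      double v = (d11 * d20 - d01 * d21) / denom;
      double w = (d00 * d21 - d01 * d20) / denom;
      if (v >= 0.0 && w >= 0.0 && v + w <= 1.0) {
        best = 0.0; pa = p; pm = p;
      }
    }
  }
  return best;
}

// ------------------------------------------------------------------
// BVH over mesh triangles; sphere bounds per node give a valid lower
// bound on segment-to-node distance for pruning.
// ------------------------------------------------------------------
struct BVHNode {
  Vec3 center;      // bounding-sphere center
  double radius;    // bounding-sphere radius
  int left, right;  // children, or -1 for leaf
  int start, count; // triangle range for leaves
};

struct BVH {
  std::vector<Vec3> v0, v1, v2; // per-triangle vertices, in tree order
  std::vector<int> triIdx;      // original triangle index, in tree order
  std::vector<BVHNode> nodes;
  int root;
};

int buildNode(BVH& bvh, std::vector<int>& order, std::vector<Vec3>& cent,
              const std::vector<Vec3>& V0, const std::vector<Vec3>& V1, const std::vector<Vec3>& V2,
              int start, int count) {
  BVHNode node;
  Vec3 lo = {1e300, 1e300, 1e300}, hi = {-1e300, -1e300, -1e300};
  for (int i = start; i < start + count; ++i) {
    const Vec3* pts[3] = {&V0[order[i]], &V1[order[i]], &V2[order[i]]};
    for (int k = 0; k < 3; ++k) {
      lo.x = std::min(lo.x, pts[k]->x); hi.x = std::max(hi.x, pts[k]->x);
      lo.y = std::min(lo.y, pts[k]->y); hi.y = std::max(hi.y, pts[k]->y);
      lo.z = std::min(lo.z, pts[k]->z); hi.z = std::max(hi.z, pts[k]->z);
    }
  }
  node.center = vscale(vadd(lo, hi), 0.5);
  double r = 0.0;
  for (int i = start; i < start + count; ++i) {
    const Vec3* pts[3] = {&V0[order[i]], &V1[order[i]], &V2[order[i]]};
    for (int k = 0; k < 3; ++k) r = std::max(r, vnorm(vsub(*pts[k], node.center)));
  }
  node.radius = r;
  if (count <= 8) {
    node.left = node.right = -1;
    node.start = start; node.count = count;
    int id = (int)bvh.nodes.size();
    bvh.nodes.push_back(node);
    return id;
  }
  // split at median along the widest centroid axis; ties broken by index
  Vec3 clo = {1e300, 1e300, 1e300}, chi = {-1e300, -1e300, -1e300};
  for (int i = start; i < start + count; ++i) {
    const Vec3& c = cent[order[i]];
    clo.x = std::min(clo.x, c.x); chi.x = std::max(chi.x, c.x);
    clo.y = std::min(clo.y, c.y); chi.y = std::max(chi.y, c.y);
    clo.z = std::min(clo.z, c.z); chi.z = std::max(chi.z, c.z);
  }
  double ex = chi.x - clo.x, ey = chi.y - clo.y, ez = chi.z - clo.z;
  int axis = (ex >= ey && ex >= ez) ? 0 : (ey >= ez ? 1 : 2);
  int mid = start + count / 2;
  std::nth_element(order.begin() + start, order.begin() + mid, order.begin() + start + count,
                   [&](int ia, int ib) {
                     double ca = axis == 0 ? cent[ia].x : (axis == 1 ? cent[ia].y : cent[ia].z);
                     double cb = axis == 0 ? cent[ib].x : (axis == 1 ? cent[ib].y : cent[ib].z);
                     if (ca != cb) return ca < cb;
                     return ia < ib;
                   });
  node.start = start; node.count = count;
  int id = (int)bvh.nodes.size();
  bvh.nodes.push_back(node);
  int l = buildNode(bvh, order, cent, V0, V1, V2, start, mid - start);
  int r2 = buildNode(bvh, order, cent, V0, V1, V2, mid, start + count - mid);
  bvh.nodes[id].left = l;
  bvh.nodes[id].right = r2;
  return id;
}

void queryNode(const BVH& bvh, int id, const Vec3& a, const Vec3& b,
               double& best, int& bestTri, Vec3& bestPa, Vec3& bestPm) {
  const BVHNode& node = bvh.nodes[id];
  // lower bound: distance from segment to bounding sphere
  double t = closestParamPointSegment(node.center, a, b);
  Vec3 q = vadd(a, vscale(vsub(b, a), t));
  double lb = vnorm(vsub(node.center, q)) - node.radius;
  if (lb > best) return;
  if (node.left < 0) {
    for (int i = node.start; i < node.start + node.count; ++i) {
      Vec3 pa, pm;
      double d = segTriDistance(a, b, bvh.v0[i], bvh.v1[i], bvh.v2[i], pa, pm);
      if (d < best || (d == best && bvh.triIdx[i] < bestTri)) {
        best = d; bestTri = bvh.triIdx[i]; bestPa = pa; bestPm = pm;
      }
    }
    return;
  }
  // visit the nearer child first
  const BVHNode& L = bvh.nodes[node.left];
  const BVHNode& R = bvh.nodes[node.right];
  double tl = closestParamPointSegment(L.center, a, b);
  Vec3 ql = vadd(a, vscale(vsub(b, a), tl));
  double dl = vnorm(vsub(L.center, ql)) - L.radius;
  double tr = closestParamPointSegment(R.center, a, b);
  Vec3 qr = vadd(a, vscale(vsub(b, a), tr));
  double dr = vnorm(vsub(R.center, qr)) - R.radius;
  if (dl <= dr) {
    queryNode(bvh, node.left, a, b, best, bestTri, bestPa, bestPm);
    queryNode(bvh, node.right, a, b, best, bestTri, bestPa, bestPm);
  } else {
    queryNode(bvh, node.right, a, b, best, bestTri, bestPa, bestPm);
    queryNode(bvh, node.left, a, b, best, bestTri, bestPa, bestPm);
  }
}

void meshToVecs(const NumericMatrix& V, const IntegerMatrix& F,
                std::vector<Vec3>& v0, std::vector<Vec3>& v1, std::vector<Vec3>& v2) {
  int m = F.nrow();
  v0.resize(m); v1.resize(m); v2.resize(m);
  for (int i = 0; i < m; ++i) {
    int i0 = F(i, 0), i1 = F(i, 1), i2 = F(i, 2);
    v0[i] = {V(i0, 0), V(i0, 1), V(i0, 2)};
    v1[i] = {V(i1, 0), V(i1, 1), V(i1, 2)};
    v2[i] = {V(i2, 0), V(i2, 1), V(i2, 2)};
  }
}

List clearanceResult(double best, int tri, const Vec3& pa, const Vec3& pm) {
  return List::create(
    _["distance"] = best,
    _["triangle"] = tri + 1, // 1-based for R
    _["point_axis"] = NumericVector::create(pa.x, pa.y, pa.z),
    _["point_mesh"] = NumericVector::create(pm.x, pm.y, pm.z));
}

} // namespace

// [[Rcpp::export]]
double cpp_point_segment_distance(NumericVector p, NumericVector a, NumericVector b) {
  Vec3 P = asVec(p), A = asVec(a), B = asVec(b);
  double t = closestParamPointSegment(P, A, B);
  return vnorm(vsub(P, vadd(A, vscale(vsub(B, A), t))));
}

// [[Rcpp::export]]
NumericVector cpp_segment_segment(NumericVector p1, NumericVector q1,
                                  NumericVector p2, NumericVector q2) {
  double s, t; Vec3 c1, c2;
  closestPtSegSeg(asVec(p1), asVec(q1), asVec(p2), asVec(q2), s, t, c1, c2);
  return NumericVector::create(vnorm(vsub(c1, c2)), s, t);
}

// [[Rcpp::export]]
List cpp_segment_triangle(NumericVector a, NumericVector b,
                          NumericVector t0, NumericVector t1, NumericVector t2) {
  Vec3 pa, pm;
  double d = segTriDistance(asVec(a), asVec(b), asVec(t0), asVec(t1), asVec(t2), pa, pm);
  return clearanceResult(d, -1, pa, pm);
}

// [[Rcpp::export]]
List cpp_mesh_clearance_brute(NumericVector a, NumericVector b,
                              NumericMatrix V, IntegerMatrix F) {
  std::vector<Vec3> v0, v1, v2;
  meshToVecs(V, F, v0, v1, v2);
  Vec3 A = asVec(a), B = asVec(b);
  double best = std::numeric_limits<double>::infinity();
  int bestTri = -1; Vec3 bestPa = A, bestPm = A;
  for (int i = 0; i < (int)v0.size(); ++i) {
    Vec3 pa, pm;
    double d = segTriDistance(A, B, v0[i], v1[i], v2[i], pa, pm);
    if (d < best) { best = d; bestTri = i; bestPa = pa; bestPm = pm; }
  }
  return clearanceResult(best, bestTri, bestPa, bestPm);
}

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  BVH* bvh = new BVH();
  std::vector<Vec3> v0, v1, v2;
  meshToVecs(V, F, v0, v1, v2);
  int m = F.nrow();
  std::vector<Vec3> cent(m);
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) {
    order[i] = i;
    cent[i] = vscale(vadd(vadd(v0[i], v1[i]), v2[i]), 1.0 / 3.0);
  }
  bvh->root = buildNode(*bvh, order, cent, v0, v1, v2, 0, m);
  bvh->v0.resize(m); bvh->v1.resize(m); bvh->v2.resize(m); bvh->triIdx.resize(m);
  for (int i = 0; i < m; ++i) {
    bvh->v0[i] = v0[order[i]];
    bvh->v1[i] = v1[order[i]];
    bvh->v2[i] = v2[order[i]];
    bvh->triIdx[i] = order[i];
  }
  XPtr<BVH> ptr(bvh, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_bvh_clearance(SEXP bvh_ptr, NumericVector a, NumericVector b) {
  XPtr<BVH> bvh(bvh_ptr);
  Vec3 A = asVec(a), B = asVec(b);
  double best = std::numeric_limits<double>::infinity();
  int bestTri = std::numeric_limits<int>::max();
  Vec3 bestPa = A, bestPm = A;
  queryNode(*bvh, bvh->root, A, B, best, bestTri, bestPa, bestPm);
  return clearanceResult(best, bestTri, bestPa, bestPm);
}

// [[Rcpp::export]]
List cpp_bvh_clearance_batch(SEXP bvh_ptr, NumericMatrix A, NumericVector b) {
  XPtr<BVH> bvh(bvh_ptr);
  int n = A.nrow();
  Vec3 B = asVec(b);
  NumericVector dist(n);
  IntegerVector tri(n);
  NumericMatrix pax(n, 3), pmx(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 Ai = {A(i, 0), A(i, 1), A(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    int bestTri = std::numeric_limits<int>::max();
    Vec3 bestPa = Ai, bestPm = Ai;
    queryNode(*bvh, bvh->root, Ai, B, best, bestTri, bestPa, bestPm);
    dist[i] = best; tri[i] = bestTri + 1;
    pax(i, 0) = bestPa.x; pax(i, 1) = bestPa.y; pax(i, 2) = bestPa.z;
    pmx(i, 0) = bestPm.x; pmx(i, 1) = bestPm.y; pmx(i, 2) = bestPm.z;
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri,
                      _["point_axis"] = pax, _["point_mesh"] = pmx);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  std::vector<Vec3> v0, v1, v2;
  meshToVecs(V, F, v0, v1, v2);
  int m = (int)v0.size();
  // fixed, irrational-looking ray directions; fall back on ambiguous hits
  const double dirs[8][3] = {
    {0.5409906546737646, 0.6545861021157312, 0.5278735551265323},
    {-0.3612576311764241, 0.8293789554522412, 0.4262345103448172},
    {0.7415716815840387, -0.1983257416132843, 0.6408723518820115},
    {0.2540781344524912, 0.5412873051967121, -0.8015623447210317},
    {-0.6512873456210978, -0.4123789065412309, 0.6370912345678123},
    {0.8912345678012345, 0.3312345678901234, 0.3098765432101234},
    {-0.2012345678901234, -0.7312345678901234, -0.6518273645123456},
    {0.4512345678901234, -0.8612345678901234, 0.2298765432109876}};
  int n = P.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p = {P(i, 0), P(i, 1), P(i, 2)};
    bool decided = false, inside = false;
    for (int di = 0; di < 8 && !decided; ++di) {
      Vec3 d = {dirs[di][0], dirs[di][1], dirs[di][2]};
      int crossings = 0;
      bool ambiguous = false;
      for (int f = 0; f < m && !ambiguous; ++f) {
        // Moeller-Trumbore, ray p + t d, t > 0
        Vec3 e1 = vsub(v1[f], v0[f]), e2 = vsub(v2[f], v0[f]);
        Vec3 h = vcross(d, e2);
        double det = vdot(e1, h);
        double scale = vnorm(e1) * vnorm(e2);
        if (std::fabs(det) < 1e-12 * scale) continue; // parallel
        double inv = 1.0 / det;
        Vec3 s = vsub(p, v0[f]);
        double u = vdot(s, h) * inv;
        Vec3 q = vcross(s, e1);
        double v = vdot(d, q) * inv;
        double t = vdot(e2, q) * inv;
        const double tol = 1e-9;
        if (u > -tol && v > -tol && u + v < 1.0 + tol && t > -tol) {
          bool edgeHit = (u < tol || v < tol || u + v > 1.0 - tol);
          bool originHit = (t < tol);
          if (edgeHit || originHit) { ambiguous = true; break; }
          crossings++;
        }
      }
      if (!ambiguous) {
        inside = (crossings % 2) == 1;
        decided = true;
      }
    }
    out[i] = inside;
  }
  return out;
}
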