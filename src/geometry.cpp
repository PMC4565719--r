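// Triangle-mesh proximity kernel: exact triangle-triangle distance and
// intersection tests, a median-split AABB tree over one mesh, point-in-mesh
// parity tests, and the rotational collision sweep used for joint mobility.
// All geometry is double precision; face indices arrive 0-based from R.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using Rcpp::NumericMatrix;
using Rcpp::IntegerMatrix;

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

struct Tri {
  Vec3 a, b, c;
};

// Ericson, Real-Time Collision Detection, 5.1.5
Vec3 closestPtPointTriangle(const Vec3& p, const Tri& t) {
  Vec3 ab = vsub(t.b, t.a), ac = vsub(t.c, t.a), ap = vsub(p, t.a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return t.a;
  Vec3 bp = vsub(p, t.b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return t.b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(t.a, vscale(ab, v));
  }
  Vec3 cp = vsub(p, t.c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return t.c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(t.a, vscale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(t.b, vscale(vsub(t.c, t.b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(t.a, vadd(vscale(ab, v), vscale(ac, w)));
}

// Ericson 5.1.9: closest points of segments p1+s*d1, p2+t*d2
double segSegDist2(const Vec3& p1, const Vec3& q1, const Vec3& p2, const Vec3& q2) {
  Vec3 d1 = vsub(q1, p1), d2 = vsub(q2, p2), r = vsub(p1, p2);
  double a = vnorm2(d1), e = vnorm2(d2), f = vdot(d2, r);
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) return vnorm2(r);
  if (a <= EPS) {
    s = 0.0;
    t = std::min(std::max(f / e, 0.0), 1.0);
  } else {
    double c = vdot(d1, r);
    if (e <= EPS) {
      t = 0.0;
      s = std::min(std::max(-c / a, 0.0), 1.0);
    } else {
      double b = vdot(d1, d2);
      double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(std::max((b * f - c * e) / denom, 0.0), 1.0) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(std::max(-c / a, 0.0), 1.0);
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(std::max((b - c) / a, 0.0), 1.0);
      }
    }
  }
  Vec3 c1 = vadd(p1, vscale(d1, s)), c2 = vadd(p2, vscale(d2, t));
  return vnorm2(vsub(c1, c2));
}

// ---- Moller 1997 triangle-triangle intersection (with coplanar handling) ----

inline void isect(double vv0, double vv1, double vv2, double d0, double d1, double d2,
                  double& a, double& b) {
  a = vv0 + (vv1 - vv0) * d0 / (d0 - d1);
  b = vv0 + (vv2 - vv0) * d0 / (d0 - d2);
}

bool edgeEdge2d(const double v0[2], const double v1[2], const double u0[2], const double u1[2]) {
  double ax = v1[0] - v0[0], ay = v1[1] - v0[1];
  double bx = u0[0] - u1[0], by = u0[1] - u1[1];
  double cx = v0[0] - u0[0], cy = v0[1] - u0[1];
  double f = ay * bx - ax * by;
  double d = by * cx - bx * cy;
  if ((f > 0 && d >= 0 && d <= f) || (f < 0 && d <= 0 && d >= f)) {
    double e = ax * cy - ay * cx;
    if (f > 0) {
      if (e >= 0 && e <= f) return true;
    } else {
      if (e <= 0 && e >= f) return true;
    }
  }
  return false;
}

bool pointInTri2d(const double p[2], const double a[2], const double b[2], const double c[2]) {
  double d1 = (b[0] - a[0]) * (p[1] - a[1]) - (b[1] - a[1]) * (p[0] - a[0]);
  double d2 = (c[0] - b[0]) * (p[1] - b[1]) - (c[1] - b[1]) * (p[0] - b[0]);
  double d3 = (a[0] - c[0]) * (p[1] - c[1]) - (a[1] - c[1]) * (p[0] - c[0]);
  bool hasNeg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool hasPos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(hasNeg && hasPos);
}

bool coplanarTriTri(const Vec3& n, const Tri& t1, const Tri& t2) {
  // project to dominant axis plane
  double ax = std::fabs(n.x), ay = std::fabs(n.y), az = std::fabs(n.z);
  int i0, i1;
  if (ax >= ay && ax >= az) {
    i0 = 1; i1 = 2;
  } else if (ay >= az) {
    i0 = 0; i1 = 2;
  } else {
    i0 = 0; i1 = 1;
  }
  auto comp = [](const Vec3& v, int i) { return i == 0 ? v.x : (i == 1 ? v.y : v.z); };
  double V[3][2] = {{comp(t1.a, i0), comp(t1.a, i1)},
                    {comp(t1.b, i0), comp(t1.b, i1)},
                    {comp(t1.c, i0), comp(t1.c, i1)}};
  double U[3][2] = {{comp(t2.a, i0), comp(t2.a, i1)},
                    {comp(t2.b, i0), comp(t2.b, i1)},
                    {comp(t2.c, i0), comp(t2.c, i1)}};
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3;
    for (int k = 0; k < 3; ++k) {
      int l = (k + 1) % 3;
      if (edgeEdge2d(V[i], V[j], U[k], U[l])) return true;
    }
  }
  if (pointInTri2d(V[0], U[0], U[1], U[2])) return true;
  if (pointInTri2d(U[0], V[0], V[1], V[2])) return true;
  return false;
}

bool triTriIntersect(const Tri& t1, const Tri& t2) {
  Vec3 e1 = vsub(t1.b, t1.a), e2 = vsub(t1.c, t1.a);
  Vec3 n1 = vcross(e1, e2);
  double d1 = -vdot(n1, t1.a);
  double du0 = vdot(n1, t2.a) + d1;
  double du1 = vdot(n1, t2.b) + d1;
  double du2 = vdot(n1, t2.c) + d1;
  const double EPS = 1e-12;
  double scale1 = vnorm(n1);
  if (std::fabs(du0) < EPS * scale1) du0 = 0.0;
  if (std::fabs(du1) < EPS * scale1) du1 = 0.0;
  if (std::fabs(du2) < EPS * scale1) du2 = 0.0;
  if (du0 * du1 > 0.0 && du0 * du2 > 0.0) return false;

  Vec3 f1 = vsub(t2.b, t2.a), f2 = vsub(t2.c, t2.a);
  Vec3 n2 = vcross(f1, f2);
  double d2 = -vdot(n2, t2.a);
  double dv0 = vdot(n2, t1.a) + d2;
  double dv1 = vdot(n2, t1.b) + d2;
  double dv2 = vdot(n2, t1.c) + d2;
  double scale2 = vnorm(n2);
  if (std::fabs(dv0) < EPS * scale2) dv0 = 0.0;
  if (std::fabs(dv1) < EPS * scale2) dv1 = 0.0;
  if (std::fabs(dv2) < EPS * scale2) dv2 = 0.0;
  if (dv0 * dv1 > 0.0 && dv0 * dv2 > 0.0) return false;

  Vec3 D = vcross(n1, n2);
  double max = std::fabs(D.x);
  int index = 0;
  double bb = std::fabs(D.y), cc = std::fabs(D.z);
  if (bb > max) { max = bb; index = 1; }
  if (cc > max) { max = cc; index = 2; }
  if (max < EPS * scale1 * scale2) {
    // coplanar
    return coplanarTriTri(n1, t1, t2);
  }
  auto comp = [index](const Vec3& v) { return index == 0 ? v.x : (index == 1 ? v.y : v.z); };
  double vp0 = comp(t1.a), vp1 = comp(t1.b), vp2 = comp(t1.c);
  double up0 = comp(t2.a), up1 = comp(t2.b), up2 = comp(t2.c);

  auto computeIntervals = [](double VV0, double VV1, double VV2, double D0, double D1,
                             double D2, double& isect0, double& isect1) -> bool {
    double D0D1 = D0 * D1, D0D2 = D0 * D2;
    if (D0D1 > 0.0) {
      isect(VV2, VV0, VV1, D2, D0, D1, isect0, isect1);
    } else if (D0D2 > 0.0) {
      isect(VV1, VV0, VV2, D1, D0, D2, isect0, isect1);
    } else if (D1 * D2 > 0.0 || D0 != 0.0) {
      isect(VV0, VV1, VV2, D0, D1, D2, isect0, isect1);
    } else if (D1 != 0.0) {
      isect(VV1, VV0, VV2, D1, D0, D2, isect0, isect1);
    } else if (D2 != 0.0) {
      isect(VV2, VV0, VV1, D2, D0, D1, isect0, isect1);
    } else {
      return false;  // coplanar
    }
    return true;
  };
  double isect1a, isect1b, isect2a, isect2b;
  if (!computeIntervals(vp0, vp1, vp2, dv0, dv1, dv2, isect1a, isect1b))
    return coplanarTriTri(n1, t1, t2);
  if (!computeIntervals(up0, up1, up2, du0, du1, du2, isect2a, isect2b))
    return coplanarTriTri(n1, t1, t2);
  if (isect1a > isect1b) std::swap(isect1a, isect1b);
  if (isect2a > isect2b) std::swap(isect2a, isect2b);
  return !(isect1b < isect2a || isect2b < isect1a);
}

double triTriDist2(const Tri& t1, const Tri& t2) {
  if (triTriIntersect(t1, t2)) return 0.0;
  double best = std::numeric_limits<double>::infinity();
  const Vec3* v1[3] = {&t1.a, &t1.b, &t1.c};
  const Vec3* v2[3] = {&t2.a, &t2.b, &t2.c};
  for (int i = 0; i < 3; ++i) {
    Vec3 cp = closestPtPointTriangle(*v1[i], t2);
    best = std::min(best, vnorm2(vsub(*v1[i], cp)));
    Vec3 cq = closestPtPointTriangle(*v2[i], t1);
    best = std::min(best, vnorm2(vsub(*v2[i], cq)));
  }
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3;
    for (int k = 0; k < 3; ++k) {
      int l = (k + 1) % 3;
      best = std::min(best, segSegDist2(*v1[i], *v1[j], *v2[k], *v2[l]));
    }
  }
  return best;
}

// ---------------- AABB tree (median split over centroids) ----------------

struct AABB {
  Vec3 lo, hi;
};

inline AABB triBox(const Tri& t) {
  AABB b;
  b.lo = {std::min({t.a.x, t.b.x, t.c.x}), std::min({t.a.y, t.b.y, t.c.y}),
          std::min({t.a.z, t.b.z, t.c.z})};
  b.hi = {std::max({t.a.x, t.b.x, t.c.x}), std::max({t.a.y, t.b.y, t.c.y}),
          std::max({t.a.z, t.b.z, t.c.z})};
  return b;
}

inline AABB merge(const AABB& a, const AABB& b) {
  return {{std::min(a.lo.x, b.lo.x), std::min(a.lo.y, b.lo.y), std::min(a.lo.z, b.lo.z)},
          {std::max(a.hi.x, b.hi.x), std::max(a.hi.y, b.hi.y), std::max(a.hi.z, b.hi.z)}};
}

inline bool boxOverlap(const AABB& a, const AABB& b) {
  return a.lo.x <= b.hi.x && b.lo.x <= a.hi.x && a.lo.y <= b.hi.y && b.lo.y <= a.hi.y &&
         a.lo.z <= b.hi.z && b.lo.z <= a.hi.z;
}

inline double boxDist2(const AABB& a, const AABB& b) {
  double d = 0.0;
  double dx = std::max({0.0, b.lo.x - a.hi.x, a.lo.x - b.hi.x});
  double dy = std::max({0.0, b.lo.y - a.hi.y, a.lo.y - b.hi.y});
  double dz = std::max({0.0, b.lo.z - a.hi.z, a.lo.z - b.hi.z});
  d = dx * dx + dy * dy + dz * dz;
  return d;
}

struct BVHNode {
  AABB box;
  int left = -1, right = -1;  // children, or -1
  int start = 0, count = 0;   // leaf triangle range into index array
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;  // triangle indices
  const std::vector<Tri>* tris = nullptr;

  int build(int start, int count) {
    BVHNode node;
    node.box = triBox((*tris)[order[start]]);
    for (int i = 1; i < count; ++i) node.box = merge(node.box, triBox((*tris)[order[start + i]]));
    int idx = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 4) {
      nodes[idx].start = start;
      nodes[idx].count = count;
      return idx;
    }
    Vec3 ext = vsub(node.box.hi, node.box.lo);
    int axis = 0;
    if (ext.y > ext.x && ext.y >= ext.z) axis = 1;
    else if (ext.z > ext.x && ext.z > ext.y) axis = 2;
    auto cent = [this, axis](int ti) {
      const Tri& t = (*tris)[ti];
      double c = (axis == 0) ? (t.a.x + t.b.x + t.c.x)
               : (axis == 1) ? (t.a.y + t.b.y + t.c.y)
                             : (t.a.z + t.b.z + t.c.z);
      return c;
    };
    int mid = count / 2;
    std::nth_element(order.begin() + start, order.begin() + start + mid,
                     order.begin() + start + count,
                     [&cent](int a, int b) { return cent(a) < cent(b); });
    int l = build(start, mid);
    int r = build(start + mid, count - mid);
    nodes[idx].left = l;
    nodes[idx].right = r;
    return idx;
  }
};

BVH makeBVH(const std::vector<Tri>& tris) {
  BVH bvh;
  bvh.tris = &tris;
  bvh.order.resize(tris.size());
  for (size_t i = 0; i < tris.size(); ++i) bvh.order[i] = (int)i;
  if (!tris.empty()) bvh.build(0, (int)tris.size());
  return bvh;
}

bool queryIntersect(const BVH& bvh, const Tri& t, const AABB& tb) {
  if (bvh.nodes.empty()) return false;
  std::vector<int> stack = {0};
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVHNode& n = bvh.nodes[ni];
    if (!boxOverlap(n.box, tb)) continue;
    if (n.left < 0) {
      for (int i = 0; i < n.count; ++i) {
        const Tri& u = (*bvh.tris)[bvh.order[n.start + i]];
        if (triTriIntersect(t, u)) return true;
      }
    } else {
      stack.push_back(n.left);
      stack.push_back(n.right);
    }
  }
  return false;
}

void queryMinDist2(const BVH& bvh, const Tri& t, const AABB& tb, double& best) {
  if (bvh.nodes.empty()) return;
  std::vector<int> stack = {0};
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVHNode& n = bvh.nodes[ni];
    if (boxDist2(n.box, tb) >= best) continue;
    if (n.left < 0) {
      for (int i = 0; i < n.count; ++i) {
        const Tri& u = (*bvh.tris)[bvh.order[n.start + i]];
        best = std::min(best, triTriDist2(t, u));
        if (best == 0.0) return;
      }
    } else {
      stack.push_back(n.left);
      stack.push_back(n.right);
    }
  }
}

std::vector<Tri> toTris(const NumericMatrix& V, const IntegerMatrix& F) {
  std::vector<Tri> tris(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    int a = F(i, 0), b = F(i, 1), c = F(i, 2);
    tris[i] = {{V(a, 0), V(a, 1), V(a, 2)},
               {V(b, 0), V(b, 1), V(b, 2)},
               {V(c, 0), V(c, 1), V(c, 2)}};
  }
  return tris;
}

// Ray casting parity along a fixed direction chosen to dodge edges/vertices.
bool pointInside(const std::vector<Tri>& tris, const Vec3& p) {
  const Vec3 dir = {0.5773502691896258, 0.5773502691896258, 0.5773502691896258};
  for (int attempt = 0; attempt < 3; ++attempt) {
    Vec3 d = dir;
    if (attempt == 1) d = {0.267261241912424, 0.534522483824849, 0.801783725737273};
    if (attempt == 2) d = {0.840168050416806, 0.480096028809603, 0.252050415125042};
    int crossings = 0;
    bool degenerate = false;
    for (const Tri& t : tris) {
      // Moller-Trumbore
      Vec3 e1 = vsub(t.b, t.a), e2 = vsub(t.c, t.a);
      Vec3 pv = vcross(d, e2);
      double det = vdot(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      Vec3 tv = vsub(p, t.a);
      double u = vdot(tv, pv) * inv;
      if (u < -1e-10 || u > 1 + 1e-10) continue;
      Vec3 qv = vcross(tv, e1);
      double v = vdot(d, qv) * inv;
      if (v < -1e-10 || u + v > 1 + 1e-10) continue;
      double tt = vdot(e2, qv) * inv;
      if (tt > 1e-12) {
        if (u < 1e-9 || v < 1e-9 || u + v > 1 - 1e-9) {
          degenerate = true;  // grazing an edge; retry with another direction
          break;
        }
        ++crossings;
      }
    }
    if (!degenerate) return (crossings % 2) == 1;
  }
  return false;
}

inline Tri rotTri(const Tri& t, const double R[3][3], const Vec3& o) {
  auto rot = [&](const Vec3& p) {
    Vec3 q = vsub(p, o);
    return Vec3{o.x + R[0][0] * q.x + R[0][1] * q.y + R[0][2] * q.z,
                o.y + R[1][0] * q.x + R[1][1] * q.y + R[1][2] * q.z,
                o.z + R[2][0] * q.x + R[2][1] * q.y + R[2][2] * q.z};
  };
  return {rot(t.a), rot(t.b), rot(t.c)};
}

void rodrigues(const Vec3& axis, double theta, double R[3][3]) {
  double c = std::cos(theta), s = std::sin(theta), C = 1 - c;
  double x = axis.x, y = axis.y, z = axis.z;
  R[0][0] = c + x * x * C;     R[0][1] = x * y * C - z * s; R[0][2] = x * z * C + y * s;
  R[1][0] = y * x * C + z * s; R[1][1] = c + y * y * C;     R[1][2] = y * z * C - x * s;
  R[2][0] = z * x * C - y * s; R[2][1] = z * y * C + x * s; R[2][2] = c + z * z * C;
}

}  // namespace

// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix va, IntegerMatrix fa, NumericMatrix vb, IntegerMatrix fb) {
  std::vector<Tri> ta = toTris(va, fa), tb = toTris(vb, fb);
  BVH bvh = makeBVH(tb);
  double best = std::numeric_limits<double>::infinity();
  for (const Tri& t : ta) {
    AABB box = triBox(t);
    queryMinDist2(bvh, t, box, best);
    if (best == 0.0) break;
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
bool cpp_surface_intersects(NumericMatrix va, IntegerMatrix fa, NumericMatrix vb,
                            IntegerMatrix fb) {
  std::vector<Tri> ta = toTris(va, fa), tb = toTris(vb, fb);
  BVH bvh = makeBVH(tb);
  for (const Tri& t : ta) {
    AABB box = triBox(t);
    if (queryIntersect(bvh, t, box)) return true;
  }
  return false;
}

// [[Rcpp::export]]
bool cpp_point_in_mesh(NumericMatrix v, IntegerMatrix f, Rcpp::NumericVector p) {
  std::vector<Tri> tris = toTris(v, f);
  return pointInside(tris, {p[0], p[1], p[2]});
}

// Sweep the mobile mesh about `axis` through `origin` in steps of `step_rad`,
// up to `nsteps`; return the 1-based index of the first colliding pose
// (surface intersection or full containment), or 0 if none collides.
// [[Rcpp::export]]
int cpp_first_collision(NumericMatrix gv, IntegerMatrix gf, NumericMatrix bv, IntegerMatrix bf,
                        Rcpp::NumericVector origin, Rcpp::NumericVector axis, double step_rad,
                        int nsteps) {
  std::vector<Tri> gt = toTris(gv, gf);
  std::vector<Tri> bt0 = toTris(bv, bf);
  BVH bvh = makeBVH(gt);
  Vec3 o = {origin[0], origin[1], origin[2]};
  double an = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
  Vec3 ax = {axis[0] / an, axis[1] / an, axis[2] / an};
  AABB gbox = bvh.nodes.empty() ? AABB{{0, 0, 0}, {0, 0, 0}} : bvh.nodes[0].box;
  for (int k = 1; k <= nsteps; ++k) {
    double R[3][3];
    rodrigues(ax, step_rad * k, R);
    bool hit = false;
    for (const Tri& t0 : bt0) {
      Tri t = rotTri(t0, R, o);
      AABB box = triBox(t);
      if (!boxOverlap(box, gbox)) continue;
      if (queryIntersect(bvh, t, box)) {
        hit = true;
        break;
      }
    }
    if (!hit && !gt.empty() && !bt0.empty()) {
      // containment without surface contact
      Tri b0 = rotTri(bt0[0], R, o);
      if (pointInside(gt, b0.a)) {
        hit = true;
      } else {
        // girdle vertex inside the rotated bone: test in the bone frame
        double Rt[3][3];
        rodrigues(ax, -step_rad * k, Rt);
        Tri g0 = rotTri(gt[0], Rt, o);
        if (pointInside(bt0, g0.a)) hit = true;
      }
    }
    if (hit) return k;
  }
  return 0;
}
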