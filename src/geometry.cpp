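#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Planar polygon kernels for ROI handling.  A polygon is a List of rings,
// each an n x 2 matrix of vertices (not closed); ring 1 is the outer
// boundary, further rings are holes.  All routines treat ring boundaries as
// part of the interior ("boundary counts as inside").

namespace {

struct Pt { double x, y; };

static inline double cross(const Pt &o, const Pt &a, const Pt &b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

static std::vector<Pt> ringToVec(const NumericMatrix &m) {
  std::vector<Pt> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Pt{m(i, 0), m(i, 1)};
  return v;
}

// signed (shoelace) area, positive for counter-clockwise
static double signedArea(const std::vector<Pt> &r) {
  double a = 0.0;
  const int n = (int)r.size();
  for (int i = 0; i < n; ++i) {
    const Pt &p = r[i], &q = r[(i + 1) % n];
    a += p.x * q.y - q.x * p.y;
  }
  return 0.5 * a;
}

static bool onSegment(const Pt &p, const Pt &a, const Pt &b, double eps) {
  double c = cross(a, b, p);
  double len = std::hypot(b.x - a.x, b.y - a.y);
  if (len == 0.0) return (std::hypot(p.x - a.x, p.y - a.y) <= eps);
  if (std::fabs(c) > eps * len) return false;
  double d = (p.x - a.x) * (b.x - a.x) + (p.y - a.y) * (b.y - a.y);
  return d >= -eps * len && d <= len * len + eps * len;
}

// winding-number point in polygon; boundary resolved separately
static bool insideRing(const Pt &p, const std::vector<Pt> &r) {
  int wn = 0;
  const int n = (int)r.size();
  for (int i = 0; i < n; ++i) {
    const Pt &a = r[i], &b = r[(i + 1) % n];
    if (a.y <= p.y) {
      if (b.y > p.y && cross(a, b, p) > 0) ++wn;
    } else {
      if (b.y <= p.y && cross(a, b, p) < 0) --wn;
    }
  }
  return wn != 0;
}

static bool onRingBoundary(const Pt &p, const std::vector<Pt> &r, double eps) {
  const int n = (int)r.size();
  for (int i = 0; i < n; ++i)
    if (onSegment(p, r[i], r[(i + 1) % n], eps)) return true;
  return false;
}

static std::vector<std::vector<Pt> > polyToRings(const List &poly) {
  std::vector<std::vector<Pt> > rings;
  for (int k = 0; k < poly.size(); ++k)
    rings.push_back(ringToVec(as<NumericMatrix>(poly[k])));
  return rings;
}

// ---- convex clipping of a polygon against a CCW triangle --------------

static void clipEdge(const std::vector<Pt> &in, std::vector<Pt> &out,
                     const Pt &a, const Pt &b) {
  out.clear();
  const int n = (int)in.size();
  if (n == 0) return;
  for (int i = 0; i < n; ++i) {
    const Pt &p = in[i], &q = in[(i + 1) % n];
    double dp = cross(a, b, p), dq = cross(a, b, q);
    if (dp >= 0) out.push_back(p);
    if ((dp > 0 && dq < 0) || (dp < 0 && dq > 0)) {
      double t = dp / (dp - dq);
      out.push_back(Pt{p.x + t * (q.x - p.x), p.y + t * (q.y - p.y)});
    }
  }
}

// area of intersection of two CCW triangles
static double triTriArea(const Pt *A, const Pt *B) {
  std::vector<Pt> cur(A, A + 3), nxt;
  for (int e = 0; e < 3; ++e) {
    clipEdge(cur, nxt, B[e], B[(e + 1) % 3]);
    cur.swap(nxt);
    if (cur.empty()) return 0.0;
  }
  return std::fabs(signedArea(cur));
}

struct SignedTri { Pt v[3]; int sign; double xmin, xmax, ymin, ymax; };

// fan decomposition: indicator of the polygon-with-holes equals the signed
// sum of the fan triangles' indicators (a.e.)
static std::vector<SignedTri> fanTriangles(
    const std::vector<std::vector<Pt> > &rings) {
  std::vector<SignedTri> tris;
  // fan origin: outer-ring vertex mean keeps triangles reasonably small
  Pt o{0, 0};
  for (const Pt &p : rings[0]) { o.x += p.x; o.y += p.y; }
  o.x /= rings[0].size(); o.y /= rings[0].size();
  for (size_t k = 0; k < rings.size(); ++k) {
    const std::vector<Pt> &r = rings[k];
    const int n = (int)r.size();
    // the fan's signed indicators sum to the ring's winding number; flip
    // so the outer ring contributes +1 inside and each hole -1
    int want = (k == 0) ? 1 : -1;
    int flip = (signedArea(r) > 0 ? 1 : -1) == want ? 1 : -1;
    for (int i = 0; i < n; ++i) {
      SignedTri t;
      t.v[0] = o; t.v[1] = r[i]; t.v[2] = r[(i + 1) % n];
      double a2 = cross(t.v[0], t.v[1], t.v[2]);
      if (a2 == 0.0) continue;
      t.sign = (a2 > 0 ? 1 : -1) * flip;
      if (a2 < 0) std::swap(t.v[1], t.v[2]);  // store CCW
      t.xmin = std::min({t.v[0].x, t.v[1].x, t.v[2].x});
      t.xmax = std::max({t.v[0].x, t.v[1].x, t.v[2].x});
      t.ymin = std::min({t.v[0].y, t.v[1].y, t.v[2].y});
      t.ymax = std::max({t.v[0].y, t.v[1].y, t.v[2].y});
      tris.push_back(t);
    }
  }
  return tris;
}

static double overlapFromTris(const std::vector<SignedTri> &tris,
                              double dx, double dy) {
  double area = 0.0;
  const size_t m = tris.size();
  for (size_t i = 0; i < m; ++i) {
    const SignedTri &ti = tris[i];
    for (size_t j = 0; j < m; ++j) {
      const SignedTri &tj = tris[j];
      if (tj.xmin + dx > ti.xmax || tj.xmax + dx < ti.xmin ||
          tj.ymin + dy > ti.ymax || tj.ymax + dy < ti.ymin) continue;
      Pt shifted[3] = {Pt{tj.v[0].x + dx, tj.v[0].y + dy},
                       Pt{tj.v[1].x + dx, tj.v[1].y + dy},
                       Pt{tj.v[2].x + dx, tj.v[2].y + dy}};
      double a = triTriArea(ti.v, shifted);
      if (a > 0.0) area += ti.sign * tj.sign * a;
    }
  }
  return area;
}

static bool segProperIntersect(const Pt &a, const Pt &b,
                               const Pt &c, const Pt &d) {
  double d1 = cross(c, d, a), d2 = cross(c, d, b);
  double d3 = cross(a, b, c), d4 = cross(a, b, d);
  return ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
         ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0));
}

}  // namespace

// [[Rcpp::export(name = ".polyAreaCpp")]]
double polyAreaCpp(List poly) {
  std::vector<std::vector<Pt> > rings = polyToRings(poly);
  double a = std::fabs(signedArea(rings[0]));
  for (size_t k = 1; k < rings.size(); ++k) a -= std::fabs(signedArea(rings[k]));
  return a;
}

// [[Rcpp::export(name = ".ringSimpleCpp")]]
bool ringSimpleCpp(NumericMatrix ring) {
  std::vector<Pt> r = ringToVec(ring);
  const int n = (int)r.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (j == i || (j + 1) % n == i || (i + 1) % n == j) continue;
      if (segProperIntersect(r[i], r[(i + 1) % n], r[j], r[(j + 1) % n]))
        return false;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".containsCpp")]]
LogicalVector containsCpp(List poly, NumericVector x, NumericVector y,
                          double eps = 1e-9) {
  std::vector<std::vector<Pt> > rings = polyToRings(poly);
  const int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Pt p{x[i], y[i]};
    bool in = insideRing(p, rings[0]) || onRingBoundary(p, rings[0], eps);
    if (in) {
      for (size_t k = 1; k < rings.size() && in; ++k) {
        // strictly inside a hole (not on its boundary) -> excluded
        if (insideRing(p, rings[k]) && !onRingBoundary(p, rings[k], eps))
          in = false;
      }
    }
    out[i] = in;
  }
  return out;
}

// [[Rcpp::export(name = ".translationOverlapCpp")]]
NumericVector translationOverlapCpp(List poly, NumericVector dx,
                                    NumericVector dy) {
  std::vector<std::vector<Pt> > rings = polyToRings(poly);
  std::vector<SignedTri> tris = fanTriangles(rings);
  const int n = dx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = overlapFromTris(tris, dx[i], dy[i]);
  return out;
}

// ---- bivariate summary statistics -------------------------------------

// nearest-neighbour distance from each point of pattern 1 to pattern 2
// [[Rcpp::export(name = ".crossNNDistCpp")]]
NumericVector crossNNDistCpp(NumericVector x1, NumericVector y1,
                             NumericVector x2, NumericVector y2) {
  const int n1 = x1.size(), n2 = x2.size();
  NumericVector out(n1);
  for (int i = 0; i < n1; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n2; ++j) {
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Cross-pair distances and translation-correction weights up to rmax.
// rectWH: c(W, H) for an exact axis-aligned-rectangle fast path, or NULL.
// Returns list(d, w, dropped) with one entry per cross pair with d <= rmax;
// w = |Omega| / |Omega cap (Omega + v_ij)|; pairs whose displacement gives
// zero overlap are dropped (counted).
// [[Rcpp::export(name = ".crossPairsCpp")]]
List crossPairsCpp(NumericVector x1, NumericVector y1,
                   NumericVector x2, NumericVector y2,
                   double rmax, List poly, double area,
                   bool translation, Nullable<NumericVector> rectWH) {
  const int n1 = x1.size(), n2 = x2.size();
  bool isRect = rectWH.isNotNull();
  double W = 0, H = 0;
  if (isRect) {
    NumericVector wh(rectWH);
    W = wh[0]; H = wh[1];
  }
  std::vector<SignedTri> tris;
  if (translation && !isRect) tris = fanTriangles(polyToRings(poly));
  std::vector<double> dv, wv;
  dv.reserve(256); wv.reserve(256);
  int dropped = 0;
  const double r2max = rmax * rmax;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double dx = x2[j] - x1[i], dy = y2[j] - y1[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > r2max) continue;
      double w = 1.0;
      if (translation) {
        double ov;
        if (isRect)
          ov = std::max(0.0, W - std::fabs(dx)) *
               std::max(0.0, H - std::fabs(dy));
        else
          ov = overlapFromTris(tris, dx, dy);
        if (ov <= 0.0) { ++dropped; continue; }
        w = area / ov;
      }
      dv.push_back(std::sqrt(d2));
      wv.push_back(w);
    }
  }
  return List::create(_["d"] = NumericVector(dv.begin(), dv.end()),
                      _["w"] = NumericVector(wv.begin(), wv.end()),
                      _["dropped"] = dropped);
}
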