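// Position-based dynamics core for the 2.5D painting world.
//
// Bodies are rigid 2D poses (x, y, angle) on one of three depth layers.
// Each solver step optionally applies a Brownian kick, then runs
// `iterations` Gauss-Seidel sweeps of (a) pairwise overlap resolution over
// collidable fixture pairs and (b) constraint projection (hinges, springs,
// pin-to distance constraints, membrane rails). Overlap resolution moves
// positions only (no torque); hinge and pin-to projections use the standard
// anchored-point response with generalized inverse masses, so articulated
// chains can bend. Everything is sequential and order-fixed: given the same
// inputs (and R RNG state for diffusion) the result is bit-identical.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vec2 {
  double x, y;
  Vec2(double x_ = 0, double y_ = 0) : x(x_), y(y_) {}
  Vec2 operator+(const Vec2& o) const { return Vec2(x + o.x, y + o.y); }
  Vec2 operator-(const Vec2& o) const { return Vec2(x - o.x, y - o.y); }
  Vec2 operator*(double s) const { return Vec2(x * s, y * s); }
  double dot(const Vec2& o) const { return x * o.x + y * o.y; }
  double cross(const Vec2& o) const { return x * o.y - y * o.x; }
  double len() const { return std::sqrt(x * x + y * y); }
};

static inline Vec2 rot(const Vec2& v, double c, double s) {
  return Vec2(c * v.x - s * v.y, s * v.x + c * v.y);
}

// World-space geometry of one fixture: circle (center + radius) or convex
// polygon (vertex list).
struct Geo {
  bool isCircle;
  Vec2 c;          // circle center or polygon centroid
  double r;        // circle radius
  std::vector<Vec2> v;
};

// ---- Separating-axis MTV --------------------------------------------------

static void projectPoly(const std::vector<Vec2>& v, const Vec2& axis,
                        double& lo, double& hi) {
  lo = hi = v[0].dot(axis);
  for (size_t i = 1; i < v.size(); ++i) {
    double p = v[i].dot(axis);
    if (p < lo) lo = p;
    if (p > hi) hi = p;
  }
}

// Directed separation depth on one axis: the smallest translation of B
// along +axis or -axis that separates the two projected intervals. Handles
// containment correctly (interval intersection does not). Returns false and
// sets depth <= 0 when already separated.
static inline bool axisDepth(double loA, double hiA, double loB, double hiB,
                             double& depth, int& dir) {
  double pushPos = hiA - loB;   // move B toward +axis
  double pushNeg = hiB - loA;   // move B toward -axis
  if (pushPos <= 0 || pushNeg <= 0) { depth = 0; return false; }
  if (pushPos <= pushNeg) { depth = pushPos; dir = +1; }
  else { depth = pushNeg; dir = -1; }
  return true;
}

// MTV pushing B away from A; returns false when separated.
static bool mtvPair(const Geo& A, const Geo& B, Vec2& axis, double& depth) {
  if (A.isCircle && B.isCircle) {
    Vec2 d = B.c - A.c;
    double dist = d.len();
    double pen = A.r + B.r - dist;
    if (pen <= 0) return false;
    axis = dist > 1e-12 ? d * (1.0 / dist) : Vec2(1, 0);
    depth = pen;
    return true;
  }
  double best = R_PosInf;
  Vec2 bestAxis;
  bool circleCase = A.isCircle || B.isCircle;
  const Geo& P = A.isCircle ? B : A;       // a polygon
  const Geo* C = A.isCircle ? &A : (B.isCircle ? &B : nullptr);
  // candidate axes: edge normals of both polygons (or of the one polygon
  // plus the closest-vertex axis for the circle case)
  for (int which = 0; which < 2; ++which) {
    const std::vector<Vec2>* vv;
    if (which == 0) vv = &P.v;
    else if (!circleCase) vv = (&P == &A) ? &B.v : &A.v;
    else break;
    size_t m = vv->size();
    for (size_t i = 0; i < m; ++i) {
      Vec2 e = (*vv)[(i + 1) % m] - (*vv)[i];
      double el = e.len();
      if (el < 1e-12) continue;
      Vec2 ax(-e.y / el, e.x / el);
      double loA_, hiA_, loB_, hiB_;
      if (A.isCircle) { double p = A.c.dot(ax); loA_ = p - A.r; hiA_ = p + A.r; }
      else projectPoly(A.v, ax, loA_, hiA_);
      if (B.isCircle) { double p = B.c.dot(ax); loB_ = p - B.r; hiB_ = p + B.r; }
      else projectPoly(B.v, ax, loB_, hiB_);
      double d; int dir;
      if (!axisDepth(loA_, hiA_, loB_, hiB_, d, dir)) return false;
      if (d < best) { best = d; bestAxis = ax * (double)dir; }
    }
  }
  if (circleCase) {
    // axis from the circle center to the closest polygon vertex
    double dmin = R_PosInf;
    Vec2 closest;
    for (size_t i = 0; i < P.v.size(); ++i) {
      double d = (P.v[i] - C->c).len();
      if (d < dmin) { dmin = d; closest = P.v[i]; }
    }
    Vec2 d = closest - C->c;
    double dl = d.len();
    if (dl > 1e-12) {
      Vec2 ax = d * (1.0 / dl);
      double loA_, hiA_, loB_, hiB_;
      if (A.isCircle) { double p = A.c.dot(ax); loA_ = p - A.r; hiA_ = p + A.r; }
      else projectPoly(A.v, ax, loA_, hiA_);
      if (B.isCircle) { double p = B.c.dot(ax); loB_ = p - B.r; hiB_ = p + B.r; }
      else projectPoly(B.v, ax, loB_, hiB_);
      double dd; int dir;
      if (!axisDepth(loA_, hiA_, loB_, hiB_, dd, dir)) return false;
      if (dd < best) { best = dd; bestAxis = ax * (double)dir; }
    }
  }
  axis = bestAxis;
  depth = best;
  return true;
}

// Exposed for the R-level narrow-phase wrapper (mp_resolve_pair) and tests.
// kind: 0 = circle (geo = c(cx, cy, r)), 1 = polygon (geo = n x 2 matrix).
// [[Rcpp::export(name = ".mtv_geo")]]
NumericVector mtv_geo(int kindA, SEXP geoA, int kindB, SEXP geoB) {
  Geo A, B;
  if (kindA == 0) {
    NumericVector g(geoA);
    A.isCircle = true; A.c = Vec2(g[0], g[1]); A.r = g[2];
  } else {
    NumericMatrix g(geoA);
    A.isCircle = false;
    Vec2 cen;
    for (int i = 0; i < g.nrow(); ++i) { A.v.push_back(Vec2(g(i,0), g(i,1))); cen = cen + A.v.back(); }
    A.c = cen * (1.0 / g.nrow());
  }
  if (kindB == 0) {
    NumericVector g(geoB);
    B.isCircle = true; B.c = Vec2(g[0], g[1]); B.r = g[2];
  } else {
    NumericMatrix g(geoB);
    B.isCircle = false;
    Vec2 cen;
    for (int i = 0; i < g.nrow(); ++i) { B.v.push_back(Vec2(g(i,0), g(i,1))); cen = cen + B.v.back(); }
    B.c = cen * (1.0 / g.nrow());
  }
  Vec2 axis; double depth;
  if (!mtvPair(A, B, axis, depth))
    return NumericVector::create(0.0, 0.0, 0.0);
  return NumericVector::create(axis.x, axis.y, depth);
}

// ---- Solver ----------------------------------------------------------------

struct Fixture {
  int body;
  int kind;        // 0 circle, 1 rect, 2 polygon
  double ox, oy;   // local offset of shape center
  double p1, p2;   // radius | half-width, half-height
  double lang;     // local angle (rect)
  int cls;         // 1 protein, 2 fiber, 3 membrane, 4 lock
  int role;        // 0 main, 1 end-circle, 2 wheel, 3 box, 4 spacer, 5 hull
  std::vector<Vec2> poly; // local vertices (polygon kind)
};

// [[Rcpp::export(name = ".pbd_step")]]
List pbd_step(NumericVector x_, NumericVector y_, NumericVector angle_,
              IntegerVector layer, NumericVector invm, NumericVector invI,
              IntegerVector excl, IntegerVector lockid,
              IntegerVector chain, IntegerVector subidx,
              IntegerVector rail_chain,
              IntegerVector chain_len, LogicalVector chain_closed,
              DataFrame fixtures, List fix_poly,
              NumericMatrix hinges, NumericMatrix springs,
              NumericMatrix pintos, List rails,
              LogicalVector toggles,
              int nsteps, int iterations, bool diffuse,
              NumericVector diff_sd, NumericVector diff_sd_ang,
              bool collisions) {
  int nb = x_.size();
  std::vector<double> x(x_.begin(), x_.end());
  std::vector<double> y(y_.begin(), y_.end());
  std::vector<double> ang(angle_.begin(), angle_.end());

  // unpack fixtures
  IntegerVector f_body = fixtures["body"], f_kind = fixtures["kind"],
                f_class = fixtures["class"], f_role = fixtures["role"];
  NumericVector f_ox = fixtures["ox"], f_oy = fixtures["oy"],
                f_p1 = fixtures["p1"], f_p2 = fixtures["p2"],
                f_lang = fixtures["lang"];
  int nf = f_body.size();
  std::vector<Fixture> fx(nf);
  for (int i = 0; i < nf; ++i) {
    Fixture& f = fx[i];
    f.body = f_body[i]; f.kind = f_kind[i];
    f.ox = f_ox[i]; f.oy = f_oy[i];
    f.p1 = f_p1[i]; f.p2 = f_p2[i]; f.lang = f_lang[i];
    f.cls = f_class[i]; f.role = f_role[i];
    if (f.kind == 2) {
      NumericMatrix pv(as<NumericMatrix>(fix_poly[i]));
      for (int k = 0; k < pv.nrow(); ++k) f.poly.push_back(Vec2(pv(k,0), pv(k,1)));
    }
  }

  bool tpp = toggles[0], tfp = toggles[1], tff = toggles[2], tmm = toggles[3];
  RNGScope rng;
  double maxCorr = 0.0;

  std::vector<double> aabb(4 * nf);

  for (int step = 0; step < nsteps; ++step) {
    if (diffuse) {
      for (int i = 0; i < nb; ++i) {
        if (invm[i] <= 0) continue;
        x[i]  += norm_rand() * diff_sd[i];
        y[i]  += norm_rand() * diff_sd[i];
        ang[i] += norm_rand() * diff_sd_ang[i];
      }
    }
    maxCorr = 0.0;
    for (int it = 0; it < iterations; ++it) {
      // ---- (a) overlap resolution ----
      if (collisions && nf > 1) {
        // broad-phase AABBs from the sweep-start poses (margin absorbs the
        // small within-sweep drift)
        const double margin = 0.5;
        for (int i = 0; i < nf; ++i) {
          const Fixture& f = fx[i];
          double c = std::cos(ang[f.body]), s = std::sin(ang[f.body]);
          Vec2 cen = Vec2(x[f.body], y[f.body]) + rot(Vec2(f.ox, f.oy), c, s);
          double r;
          if (f.kind == 0) r = f.p1;
          else if (f.kind == 1) r = std::sqrt(f.p1 * f.p1 + f.p2 * f.p2);
          else {
            cen = Vec2(x[f.body], y[f.body]); // polygon verts are body-local
            r = 0;
            for (size_t k = 0; k < f.poly.size(); ++k)
              r = std::max(r, f.poly[k].len());
          }
          aabb[4*i]   = cen.x - r - margin;
          aabb[4*i+1] = cen.x + r + margin;
          aabb[4*i+2] = cen.y - r - margin;
          aabb[4*i+3] = cen.y + r + margin;
        }
        // sweep and prune on x
        std::vector<int> order(nf);
        for (int i = 0; i < nf; ++i) order[i] = i;
        std::sort(order.begin(), order.end(), [&](int i, int j) {
          return aabb[4*i] < aabb[4*j];
        });
        for (int oi = 0; oi < nf - 1; ++oi) {
          int i = order[oi];
          const Fixture& fa = fx[i];
          int a = fa.body;
          double xmax_i = aabb[4*i+1];
          for (int oj = oi + 1; oj < nf; ++oj) {
            int j = order[oj];
            if (aabb[4*j] > xmax_i) break;
            if (aabb[4*i+2] > aabb[4*j+3] || aabb[4*j+2] > aabb[4*i+3])
              continue;
            const Fixture& fb = fx[j];
            int b = fb.body;
            if (a == b) continue;
            if (invm[a] <= 0 && invm[b] <= 0) continue;
            // layer rule: front layer ignores other layers; the two
            // background layers ignore the front but see each other
            if (layer[a] != layer[b] && (layer[a] == 0 || layer[b] == 0))
              continue;
            if (excl[a] > 0 && excl[a] == excl[b]) continue;
            if (lockid[a] > 0 && lockid[a] == lockid[b]) continue;
            // railed proteins ignore their own membrane chain (the rail
            // projection replaces the wheel-on-rail contact)
            if ((rail_chain[a] > 0 && rail_chain[a] == chain[b]) ||
                (rail_chain[b] > 0 && rail_chain[b] == chain[a])) continue;
            // class matrix (lock collides with everything)
            int c1 = fa.cls, c2 = fb.cls;
            if (c1 != 4 && c2 != 4) {
              int lo = std::min(c1, c2), hi = std::max(c1, c2);
              bool ok;
              if      (lo == 1 && hi == 1) ok = tpp;
              else if (lo == 1 && hi == 2) ok = tfp;
              else if (lo == 2 && hi == 2) ok = tff;
              else if (lo == 3 && hi == 3) ok = tmm;
              else ok = false;   // protein-membrane, fiber-membrane
              if (!ok) continue;
            }
            // chain adjacency: hinged neighbours (and their gap-filling end
            // circles) do not see each other
            if (chain[a] > 0 && chain[a] == chain[b]) {
              int d = std::abs(subidx[a] - subidx[b]);
              int cid = chain[a] - 1;
              if (cid >= 0 && cid < chain_len.size() && chain_closed[cid])
                d = std::min(d, chain_len[cid] - d);
              if (d <= 1) continue;
            }
            // exact narrow phase from current poses
            Geo A, B;
            for (int which = 0; which < 2; ++which) {
              const Fixture& f = which == 0 ? fa : fb;
              Geo& G = which == 0 ? A : B;
              int bi = f.body;
              double c = std::cos(ang[bi]), s = std::sin(ang[bi]);
              Vec2 pos(x[bi], y[bi]);
              if (f.kind == 0) {
                G.isCircle = true;
                G.c = pos + rot(Vec2(f.ox, f.oy), c, s);
                G.r = f.p1;
              } else if (f.kind == 1) {
                G.isCircle = false;
                double ca = std::cos(ang[bi] + f.lang), sa = std::sin(ang[bi] + f.lang);
                Vec2 cen = pos + rot(Vec2(f.ox, f.oy), c, s);
                Vec2 ex(ca * f.p1, sa * f.p1), ey(-sa * f.p2, ca * f.p2);
                G.v.push_back(cen - ex - ey);
                G.v.push_back(cen + ex - ey);
                G.v.push_back(cen + ex + ey);
                G.v.push_back(cen - ex + ey);
                G.c = cen;
              } else {
                G.isCircle = false;
                Vec2 cen;
                for (size_t k = 0; k < f.poly.size(); ++k) {
                  G.v.push_back(pos + rot(f.poly[k], c, s));
                  cen = cen + G.v.back();
                }
                G.c = cen * (1.0 / G.v.size());
              }
            }
            Vec2 axis; double depth;
            if (!mtvPair(A, B, axis, depth)) continue;
            double wsum = invm[a] + invm[b];
            if (wsum <= 0) continue;
            double sa = depth * invm[a] / wsum, sb = depth * invm[b] / wsum;
            x[a] -= axis.x * sa; y[a] -= axis.y * sa;
            x[b] += axis.x * sb; y[b] += axis.y * sb;
            double corr = std::max(sa, sb);
            if (corr > maxCorr) maxCorr = corr;
          }
        }
      }
      // ---- (b) constraint projection ----
      // hinges: coincident anchor points, anchored-point response
      for (int h = 0; h < hinges.nrow(); ++h) {
        int a = (int)hinges(h, 0), b = (int)hinges(h, 1);
        double ca = std::cos(ang[a]), sa = std::sin(ang[a]);
        double cb = std::cos(ang[b]), sb = std::sin(ang[b]);
        Vec2 ra = rot(Vec2(hinges(h, 2), hinges(h, 3)), ca, sa);
        Vec2 rb = rot(Vec2(hinges(h, 4), hinges(h, 5)), cb, sb);
        Vec2 pa = Vec2(x[a], y[a]) + ra;
        Vec2 pb = Vec2(x[b], y[b]) + rb;
        Vec2 d = pb - pa;
        double len = d.len();
        if (len < 1e-12) continue;
        Vec2 n = d * (1.0 / len);
        double wa = invm[a] + ra.cross(n) * ra.cross(n) * invI[a];
        double wb = invm[b] + rb.cross(n) * rb.cross(n) * invI[b];
        if (wa + wb <= 0) continue;
        double lambda = len / (wa + wb);
        Vec2 p = n * lambda;
        x[a] += p.x * invm[a]; y[a] += p.y * invm[a];
        ang[a] += invI[a] * ra.cross(p);
        x[b] -= p.x * invm[b]; y[b] -= p.y * invm[b];
        ang[b] -= invI[b] * rb.cross(p);
        double corr = lambda * std::max(invm[a], invm[b]);
        if (corr > maxCorr) maxCorr = corr;
      }
      // springs: center-to-center distance driven toward rest length
      for (int s = 0; s < springs.nrow(); ++s) {
        int a = (int)springs(s, 0), b = (int)springs(s, 1);
        double rest = springs(s, 2), stiff = springs(s, 3);
        Vec2 d(x[b] - x[a], y[b] - y[a]);
        double len = d.len();
        if (len < 1e-12) continue;
        double C = (len - rest) * stiff;
        double wsum = invm[a] + invm[b];
        if (wsum <= 0) continue;
        Vec2 n = d * (1.0 / len);
        double fa = C * invm[a] / wsum, fb = C * invm[b] / wsum;
        x[a] += n.x * fa; y[a] += n.y * fa;
        x[b] -= n.x * fb; y[b] -= n.y * fb;
        double corr = std::max(std::abs(fa), std::abs(fb));
        if (corr > maxCorr) maxCorr = corr;
      }
      // pin-to: anchored distance constraint, isotropic
      for (int t = 0; t < pintos.nrow(); ++t) {
        int a = (int)pintos(t, 0), b = (int)pintos(t, 3);
        double ca = std::cos(ang[a]), sa = std::sin(ang[a]);
        double cb = std::cos(ang[b]), sb = std::sin(ang[b]);
        Vec2 ra = rot(Vec2(pintos(t, 1), pintos(t, 2)), ca, sa);
        Vec2 rb = rot(Vec2(pintos(t, 4), pintos(t, 5)), cb, sb);
        Vec2 pa = Vec2(x[a], y[a]) + ra;
        Vec2 pb = Vec2(x[b], y[b]) + rb;
        Vec2 d = pb - pa;
        double len = d.len();
        if (len < 1e-12) continue;
        double C = len - pintos(t, 6);
        Vec2 n = d * (1.0 / len);
        double wa = invm[a] + ra.cross(n) * ra.cross(n) * invI[a];
        double wb = invm[b] + rb.cross(n) * rb.cross(n) * invI[b];
        if (wa + wb <= 0) continue;
        double lambda = C / (wa + wb);
        Vec2 p = n * lambda;
        x[a] += p.x * invm[a]; y[a] += p.y * invm[a];
        ang[a] += invI[a] * ra.cross(p);
        x[b] -= p.x * invm[b]; y[b] -= p.y * invm[b];
        ang[b] -= invI[b] * rb.cross(p);
        double corr = std::abs(lambda) * std::max(invm[a], invm[b]);
        if (corr > maxCorr) maxCorr = corr;
      }
      // rails: project membrane-bound proteins onto their membrane chain
      for (int r = 0; r < rails.size(); ++r) {
        List rl = rails[r];
        int pbody = as<int>(rl["body"]);
        if (invm[pbody] <= 0) continue;
        IntegerVector cb = rl["chain_bodies"];
        bool closed = as<bool>(rl["closed"]);
        double offset = as<double>(rl["offset"]);
        double rrot = as<double>(rl["rotation"]);
        int m = cb.size();
        if (m < 2) continue;
        Vec2 p(x[pbody], y[pbody]);
        double bestD = R_PosInf;
        Vec2 bestFoot, bestTan;
        int nseg = closed ? m : m - 1;
        for (int si = 0; si < nseg; ++si) {
          int i1 = cb[si], i2 = cb[(si + 1) % m];
          Vec2 a(x[i1], y[i1]), bpt(x[i2], y[i2]);
          Vec2 e = bpt - a;
          double el2 = e.dot(e);
          if (el2 < 1e-12) continue;
          double tpar = (p - a).dot(e) / el2;
          if (tpar < 0) tpar = 0; if (tpar > 1) tpar = 1;
          Vec2 foot = a + e * tpar;
          double dd = (p - foot).len();
          if (dd < bestD) {
            bestD = dd; bestFoot = foot;
            bestTan = e * (1.0 / std::sqrt(el2));
          }
        }
        if (!R_finite(bestD)) continue;
        Vec2 nrm(-bestTan.y, bestTan.x);    // left normal: exterior of a
        Vec2 target = bestFoot + nrm * offset; // clockwise vesicle
        double corr = (target - p).len();
        x[pbody] = target.x;
        y[pbody] = target.y;
        ang[pbody] = std::atan2(-nrm.x, nrm.y) + rrot; // local +Y -> normal
        if (corr > maxCorr) maxCorr = corr;
      }
    }
    for (int i = 0; i < nb; ++i) {
      if (!R_finite(x[i]) || !R_finite(y[i]) || !R_finite(ang[i]))
        stop("simulation diverged: body %d has a non-finite pose", i + 1);
    }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["angle"] = NumericVector(ang.begin(), ang.end()),
                      _["max_corr"] = maxCorr);
}
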