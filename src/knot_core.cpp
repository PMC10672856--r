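// Computational core: KMT chain reduction, planar crossing diagrams and
// Alexander-invariant evaluation for closed polygonal curves.
//
// Knot labels are resolved from |Delta(-1)| (one modular determinant per
// closure) and, when that value is ambiguous, from the full Alexander
// polynomial obtained by evaluation/interpolation of the crossing-matrix
// minor modulo the Mersenne prime 2^31-1.  The minor determinant equals
// +/- t^s Delta(t); stripping the trailing power of t and fixing the sign
// with Delta(1) = +/-1 recovers the polynomial exactly as long as its
// coefficients stay below p/2 (true by orders of magnitude for every knot
// in the lookup table, including 12-fold trefoil sums).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

typedef std::array<double, 3> P3;

static inline P3 sub3(const P3 &a, const P3 &b) {
  return P3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline P3 cross3(const P3 &a, const P3 &b) {
  return P3{a[1] * b[2] - a[2] * b[1],
            a[2] * b[0] - a[0] * b[2],
            a[0] * b[1] - a[1] * b[0]};
}
static inline double dot3(const P3 &a, const P3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const P3 &a) { return std::sqrt(dot3(a, a)); }

static double bbox_diag(const std::vector<P3> &p) {
  if (p.empty()) return 0.0;
  P3 lo = p[0], hi = p[0];
  for (const P3 &q : p)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], q[k]);
      hi[k] = std::max(hi[k], q[k]);
    }
  return norm3(sub3(hi, lo));
}

// ---------------------------------------------------------------------------
// segment / triangle intersection (the KMT elementary test)
// ---------------------------------------------------------------------------

// 2D helpers for the coplanar branch
static inline double cr2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}
static bool seg2_hit(double ax, double ay, double bx, double by,
                     double cx, double cy, double dx, double dy) {
  double r1 = cr2(bx - ax, by - ay, cx - ax, cy - ay);
  double r2 = cr2(bx - ax, by - ay, dx - ax, dy - ay);
  double r3 = cr2(dx - cx, dy - cy, ax - cx, ay - cy);
  double r4 = cr2(dx - cx, dy - cy, bx - cx, by - cy);
  return (r1 * r2 < 0.0) && (r3 * r4 < 0.0);
}
static inline bool pt_in_tri2(double px, double py, double ax, double ay,
                              double bx, double by, double cx, double cy) {
  double d1 = cr2(bx - ax, by - ay, px - ax, py - ay);
  double d2 = cr2(cx - bx, cy - by, px - bx, py - by);
  double d3 = cr2(ax - cx, ay - cy, px - cx, py - cy);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}

// Does segment (a,b) cross triangle (t0,t1,t2)?  Hits within `ctol` of the
// corners t0/t2 are ignored: chain segments adjacent to the triangle share
// those vertices and merely graze them.
static bool seg_tri_cross(const P3 &a, const P3 &b, const P3 &t0,
                          const P3 &t1, const P3 &t2, double ctol) {
  P3 dir = sub3(b, a), e1 = sub3(t1, t0), e2 = sub3(t2, t0);
  P3 n = cross3(e1, e2);
  double nn = norm3(n);
  if (nn < 1e-14) return false;  // degenerate triangle: zero area
  double dl = norm3(dir);
  if (dl < 1e-14) return false;
  P3 h = cross3(dir, e2);
  double det = dot3(e1, h);  // = det[e1, dir, e2]; zero iff dir in-plane
  if (std::fabs(det) < 1e-12 * dl * nn) {
    // segment (nearly) parallel to the triangle plane
    double da = dot3(sub3(a, t0), n) / nn, db = dot3(sub3(b, t0), n) / nn;
    double thick = std::max(ctol, 1e-9 * (norm3(e1) + norm3(e2)));
    if (std::fabs(da) > thick && std::fabs(db) > thick) return false;
    // coplanar: test in 2D on an in-plane basis
    P3 u = e1;
    double ul = norm3(u);
    for (int k = 0; k < 3; ++k) u[k] /= ul;
    P3 v = cross3(n, u);
    double vl = norm3(v);
    for (int k = 0; k < 3; ++k) v[k] /= vl;
    double axp = dot3(sub3(a, t0), u), ayp = dot3(sub3(a, t0), v);
    double bxp = dot3(sub3(b, t0), u), byp = dot3(sub3(b, t0), v);
    double x0 = 0, y0 = 0;
    double x1 = dot3(e1, u), y1 = dot3(e1, v);
    double x2 = dot3(e2, u), y2 = dot3(e2, v);
    auto near_corner2 = [&](double px, double py) {
      double d0 = std::hypot(px - x0, py - y0);
      double d2c = std::hypot(px - x2, py - y2);
      return d0 < ctol || d2c < ctol;
    };
    if (pt_in_tri2(axp, ayp, x0, y0, x1, y1, x2, y2) && !near_corner2(axp, ayp))
      return true;
    if (pt_in_tri2(bxp, byp, x0, y0, x1, y1, x2, y2) && !near_corner2(bxp, byp))
      return true;
    if (seg2_hit(axp, ayp, bxp, byp, x0, y0, x1, y1)) return true;
    if (seg2_hit(axp, ayp, bxp, byp, x1, y1, x2, y2)) return true;
    // edge t0-t2 is the new chord the deletion would create; a hit there that
    // is not at a corner still blocks deletion
    if (seg2_hit(axp, ayp, bxp, byp, x0, y0, x2, y2)) return true;
    return false;
  }
  double inv = 1.0 / det;
  P3 s = sub3(a, t0);
  double uu = dot3(s, h) * inv;
  if (uu < -1e-9 || uu > 1.0 + 1e-9) return false;
  P3 q = cross3(s, e1);
  double vv = dot3(dir, q) * inv;
  if (vv < -1e-9 || uu + vv > 1.0 + 1e-9) return false;
  double tt = dot3(e2, q) * inv;  // parameter along the segment
  if (tt < 1e-9 || tt > 1.0 - 1e-9) return false;
  P3 pt{a[0] + tt * dir[0], a[1] + tt * dir[1], a[2] + tt * dir[2]};
  if (norm3(sub3(pt, t0)) < ctol || norm3(sub3(pt, t2)) < ctol) return false;
  return true;
}

// ---------------------------------------------------------------------------
// KMT reduction
// ---------------------------------------------------------------------------

static void kmt_run(const std::vector<P3> &pts, bool closed,
                    std::vector<int> &alive) {
  int n = (int)pts.size();
  alive.resize(n);
  for (int i = 0; i < n; ++i) alive[i] = i;
  if (n <= 3) return;  // 3-point chains are already minimal
  double ctol = std::max(1e-9, 1e-9 * bbox_diag(pts));
  bool changed = true;
  while (changed) {
    changed = false;
    int m = (int)alive.size();
    int pos = closed ? 0 : 1;
    while (true) {
      m = (int)alive.size();
      if (m <= 3) break;
      int last = closed ? m : m - 1;
      if (pos >= (closed ? m : m - 1)) break;
      int ip = closed ? (pos - 1 + m) % m : pos - 1;
      int in_ = closed ? (pos + 1) % m : pos + 1;
      const P3 &u = pts[alive[ip]], &v = pts[alive[pos]], &w = pts[alive[in_]];
      // zero-area triangle: the vertex is collinear and always removable
      P3 ar = cross3(sub3(v, u), sub3(w, u));
      bool crossed = false;
      if (norm3(ar) > 1e-18) {
        // bounding box of the triangle (+ tolerance): most segments of a
        // long chain are far from a local triangle and reject cheaply
        double blo[3], bhi[3];
        for (int c = 0; c < 3; ++c) {
          blo[c] = std::min(u[c], std::min(v[c], w[c])) - ctol;
          bhi[c] = std::max(u[c], std::max(v[c], w[c])) + ctol;
        }
        int nseg = closed ? m : m - 1;
        for (int k = 0; k < nseg; ++k) {
          if (k == pos || k == ip) continue;  // segments incident to v
          int k2 = closed ? (k + 1) % m : k + 1;
          const P3 &a = pts[alive[k]], &b = pts[alive[k2]];
          if ((a[0] < blo[0] && b[0] < blo[0]) ||
              (a[0] > bhi[0] && b[0] > bhi[0]) ||
              (a[1] < blo[1] && b[1] < blo[1]) ||
              (a[1] > bhi[1] && b[1] > bhi[1]) ||
              (a[2] < blo[2] && b[2] < blo[2]) ||
              (a[2] > bhi[2] && b[2] > bhi[2]))
            continue;
          if (seg_tri_cross(a, b, u, v, w, ctol)) {
            crossed = true;
            break;
          }
        }
      }
      if (!crossed) {
        alive.erase(alive.begin() + pos);
        changed = true;
        if (closed && pos >= (int)alive.size()) pos = 0;
        // do not advance: the next vertex slid into `pos`
      } else {
        ++pos;
      }
      (void)last;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_kmt(NumericMatrix pts, bool closed) {
  int n = pts.nrow();
  std::vector<P3> p(n);
  for (int i = 0; i < n; ++i) p[i] = P3{pts(i, 0), pts(i, 1), pts(i, 2)};
  std::vector<int> alive;
  kmt_run(p, closed, alive);
  NumericMatrix out((int)alive.size(), 3);
  IntegerVector kept((int)alive.size());
  for (int i = 0; i < (int)alive.size(); ++i) {
    out(i, 0) = p[alive[i]][0];
    out(i, 1) = p[alive[i]][1];
    out(i, 2) = p[alive[i]][2];
    kept[i] = alive[i] + 1;
  }
  out.attr("kept") = kept;
  return out;
}

// ---------------------------------------------------------------------------
// modular arithmetic (p = 2^31 - 1)
// ---------------------------------------------------------------------------

static const int64_t MODP = 2147483647LL;

static inline int64_t mmod(int64_t a) {
  a %= MODP;
  if (a < 0) a += MODP;
  return a;
}
static int64_t powmod(int64_t b, int64_t e) {
  int64_t r = 1;
  b = mmod(b);
  while (e > 0) {
    if (e & 1) r = (r * b) % MODP;
    b = (b * b) % MODP;
    e >>= 1;
  }
  return r;
}
static inline int64_t invmod(int64_t a) { return powmod(a, MODP - 2); }

// determinant mod p; M is n x n row-major, destroyed
static int64_t det_modp(std::vector<int64_t> &M, int n) {
  if (n <= 0) return 1;
  int64_t det = 1;
  for (int c = 0; c < n; ++c) {
    int piv = -1;
    for (int r = c; r < n; ++r)
      if (M[(size_t)r * n + c] != 0) { piv = r; break; }
    if (piv < 0) return 0;
    if (piv != c) {
      for (int k = c; k < n; ++k)
        std::swap(M[(size_t)piv * n + k], M[(size_t)c * n + k]);
      det = MODP - det;
      if (det == MODP) det = 0;
    }
    int64_t pv = M[(size_t)c * n + c];
    det = (det * pv) % MODP;
    int64_t ipv = invmod(pv);
    for (int r = c + 1; r < n; ++r) {
      int64_t f = M[(size_t)r * n + c];
      if (f == 0) continue;
      f = (f * ipv) % MODP;
      for (int k = c; k < n; ++k) {
        M[(size_t)r * n + k] =
            mmod(M[(size_t)r * n + k] - f * M[(size_t)c * n + k] % MODP);
      }
    }
  }
  return det % MODP;
}

// ---------------------------------------------------------------------------
// crossing diagram
// ---------------------------------------------------------------------------

struct Crossing {
  double pos_over, pos_under;  // position along the loop: segment index + param
  int seg_over, seg_under;
  int sign;  // +1 / -1
};

// Build the crossing diagram of closed `loop` projected along `dir`.
// Returns 0 on success, -1 if the projection is degenerate (retry with a new
// direction), -2 if the diagram is absurdly large.
static int build_diagram(const std::vector<P3> &loop, const P3 &dir,
                         std::vector<Crossing> &cr) {
  cr.clear();
  int n = (int)loop.size();
  // orthonormal basis perpendicular to dir
  P3 aux{1, 0, 0};
  if (std::fabs(dir[0]) > 0.9) aux = P3{0, 1, 0};
  P3 e1 = cross3(dir, aux);
  double l1 = norm3(e1);
  if (l1 < 1e-12) return -1;
  for (int k = 0; k < 3; ++k) e1[k] /= l1;
  P3 e2 = cross3(dir, e1);
  double l2 = norm3(e2);
  for (int k = 0; k < 3; ++k) e2[k] /= l2;

  std::vector<double> x(n), y(n), z(n);
  double zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < n; ++i) {
    x[i] = dot3(loop[i], e1);
    y[i] = dot3(loop[i], e2);
    z[i] = dot3(loop[i], dir);
    zmin = std::min(zmin, z[i]);
    zmax = std::max(zmax, z[i]);
  }
  double zscale = std::max(zmax - zmin, 1e-9);
  double xyscale = 0;
  for (int i = 0; i < n; ++i)
    xyscale = std::max(xyscale, std::fabs(x[i]) + std::fabs(y[i]));
  xyscale = std::max(xyscale, 1e-9);

  const double ptol = 1e-9;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double rx = x[i2] - x[i], ry = y[i2] - y[i];
    double rn = std::hypot(rx, ry);
    if (rn < 1e-12 * xyscale) return -1;  // segment along projection axis
    double ilx = std::min(x[i], x[i2]), ihx = std::max(x[i], x[i2]);
    double ily = std::min(y[i], y[i2]), ihy = std::max(y[i], y[i2]);
    for (int j = i + 1; j < n; ++j) {
      if (j == i || j == (i + 1) % n) continue;
      if (i == 0 && j == n - 1) continue;
      if (j == i + 1) continue;
      int j2 = (j + 1) % n;
      if ((x[j] < ilx && x[j2] < ilx) || (x[j] > ihx && x[j2] > ihx) ||
          (y[j] < ily && y[j2] < ily) || (y[j] > ihy && y[j2] > ihy))
        continue;
      double qx = x[j2] - x[j], qy = y[j2] - y[j];
      double qn = std::hypot(qx, qy);
      if (qn < 1e-12 * xyscale) return -1;
      double den = cr2(rx, ry, qx, qy);
      double wx = x[j] - x[i], wy = y[j] - y[i];
      if (std::fabs(den) < 1e-13 * rn * qn) {
        // near-parallel: degenerate only if the segments come close
        double dist = std::fabs(cr2(rx, ry, wx, wy)) / rn;
        if (dist < 1e-7 * xyscale) {
          // check 1D overlap along r
          double t0 = (wx * rx + wy * ry) / (rn * rn);
          double t1 = t0 + (qx * rx + qy * ry) / (rn * rn);
          if (std::max(std::min(t0, t1), 0.0) <=
              std::min(std::max(t0, t1), 1.0) + 1e-9)
            return -1;
        }
        continue;
      }
      double s = cr2(wx, wy, qx, qy) / den;
      double u = cr2(wx, wy, rx, ry) / den;
      bool inside = s > ptol && s < 1 - ptol && u > ptol && u < 1 - ptol;
      bool nearby = s > -ptol && s < 1 + ptol && u > -ptol && u < 1 + ptol;
      if (!inside) {
        if (nearby) return -1;  // crossing at/near a vertex: retry
        continue;
      }
      double z1 = z[i] + s * (z[i2] - z[i]);
      double z2 = z[j] + u * (z[j2] - z[j]);
      if (std::fabs(z1 - z2) < 1e-7 * zscale) return -1;
      Crossing c;
      double sgn = cr2(rx, ry, qx, qy);  // sign of (d_i x d_j)
      if (z1 > z2) {
        c.seg_over = i; c.seg_under = j;
        c.pos_over = i + s; c.pos_under = j + u;
        c.sign = sgn > 0 ? 1 : -1;
      } else {
        c.seg_over = j; c.seg_under = i;
        c.pos_over = j + u; c.pos_under = i + s;
        // d_over x d_under = -(d_i x d_j) ... cross is antisymmetric
        c.sign = sgn > 0 ? -1 : 1;
      }
      cr.push_back(c);
      if ((int)cr.size() > 400) return -2;
    }
  }
  // distinct positions along the loop (spec: coincidence within 1e-9 of
  // projected arc position forces a new projection)
  std::vector<double> posns;
  posns.reserve(cr.size() * 2);
  for (const Crossing &c : cr) {
    posns.push_back(c.pos_over);
    posns.push_back(c.pos_under);
  }
  std::sort(posns.begin(), posns.end());
  for (size_t i = 1; i < posns.size(); ++i)
    if (posns[i] - posns[i - 1] < 1e-9) return -1;
  return 0;
}

// Alexander matrix (entries A + B t) from a diagram; m = #crossings
static void alex_matrix(const std::vector<Crossing> &cr,
                        std::vector<int64_t> &A, std::vector<int64_t> &B,
                        int &m) {
  m = (int)cr.size();
  A.assign((size_t)m * m, 0);
  B.assign((size_t)m * m, 0);
  // arcs are delimited by under-events ordered along the loop
  std::vector<double> u_sorted;
  u_sorted.reserve(m);
  for (const Crossing &c : cr) u_sorted.push_back(c.pos_under);
  std::sort(u_sorted.begin(), u_sorted.end());
  auto arc_of = [&](double pos) {
    // arc k spans (u_sorted[k], u_sorted[k+1]) cyclically
    int k = (int)(std::upper_bound(u_sorted.begin(), u_sorted.end(), pos) -
                  u_sorted.begin()) - 1;
    if (k < 0) k = m - 1;
    return k;
  };
  for (int r = 0; r < m; ++r) {
    const Crossing &c = cr[r];
    int out = arc_of(c.pos_under + 0.0);  // arc starting at this under event
    // arc_of at exactly pos_under returns the arc starting here (upper_bound)
    int in = (out - 1 + m) % m;
    int ov = arc_of(c.pos_over);
    if (c.sign > 0) {
      // incoming under: t, outgoing under: -1, over: 1 - t
      B[(size_t)r * m + in] += 1;
      A[(size_t)r * m + out] += -1;
      A[(size_t)r * m + ov] += 1;
      B[(size_t)r * m + ov] += -1;
    } else {
      // incoming under: 1, outgoing under: -t, over: t - 1
      A[(size_t)r * m + in] += 1;
      B[(size_t)r * m + out] += -1;
      A[(size_t)r * m + ov] += -1;
      B[(size_t)r * m + ov] += 1;
    }
  }
}

// |Delta(-1)| from one modular determinant of the (m-1) minor
static int64_t diagram_d1(const std::vector<int64_t> &A,
                          const std::vector<int64_t> &B, int m) {
  if (m <= 1) return 1;
  int n = m - 1;
  std::vector<int64_t> M((size_t)n * n);
  int64_t t = MODP - 1;  // -1 mod p
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c)
      M[(size_t)r * n + c] = mmod(A[(size_t)r * m + c] + t * mmod(B[(size_t)r * m + c]) % MODP);
  int64_t d = det_modp(M, n);
  if (d > MODP / 2) d = MODP - d;  // centered lift, absolute value
  return d;
}

// Full Alexander polynomial (centered integer coefficients, trailing t-power
// stripped, sign such that Delta(1) = 1).  Returns empty vector on failure.
static std::vector<int64_t> diagram_poly(const std::vector<int64_t> &A,
                                         const std::vector<int64_t> &B,
                                         int m) {
  if (m <= 1) return std::vector<int64_t>{1};
  int n = m - 1;
  int npts = n + 1;  // det degree <= n
  std::vector<int64_t> ys(npts);
  std::vector<int64_t> M((size_t)n * n);
  for (int k = 0; k < npts; ++k) {
    int64_t t = k;
    for (int r = 0; r < n; ++r)
      for (int c = 0; c < n; ++c)
        M[(size_t)r * n + c] =
            mmod(A[(size_t)r * m + c] + t * mmod(B[(size_t)r * m + c]) % MODP);
    ys[k] = det_modp(M, n);
  }
  // Newton interpolation at nodes 0..npts-1
  std::vector<int64_t> dd = ys;
  for (int j = 1; j < npts; ++j) {
    int64_t inv = invmod(j);  // x_i - x_{i-j} = j
    for (int i = npts - 1; i >= j; --i)
      dd[i] = mmod(dd[i] - dd[i - 1]) * inv % MODP;
  }
  // expand to monomial coefficients: poly = dd[n]*(t-x_{n-1})*...+...
  std::vector<int64_t> coef(npts, 0);
  for (int i = npts - 1; i >= 0; --i) {
    // poly <- poly*(t - i) + dd[i]
    for (int k = npts - 1; k >= 1; --k)
      coef[k] = mmod(coef[k - 1] + mmod(MODP - (int64_t)i) * coef[k] % MODP);
    coef[0] = mmod(mmod(MODP - (int64_t)i) * coef[0] % MODP + dd[i]);
    // note: when i == npts-1 the shift uses zeros; correct
  }
  // centered lift
  std::vector<int64_t> cc(npts);
  for (int k = 0; k < npts; ++k) {
    int64_t v = coef[k];
    if (v > MODP / 2) v -= MODP;
    cc[k] = v;
  }
  // strip trailing power of t
  int s = 0;
  while (s < npts && cc[s] == 0) ++s;
  if (s == npts) return std::vector<int64_t>();  // det == 0: degenerate
  int deg = npts - 1;
  while (deg > s && cc[deg] == 0) --deg;
  std::vector<int64_t> out(cc.begin() + s, cc.begin() + deg + 1);
  int64_t at1 = 0;
  for (int64_t v : out) at1 += v;
  if (at1 == -1)
    for (int64_t &v : out) v = -v;
  else if (at1 != 1)
    return std::vector<int64_t>();  // not a valid Alexander minor: degenerate
  return out;
}

// ---------------------------------------------------------------------------
// per-closure classification driver
// ---------------------------------------------------------------------------

struct DirPool {
  const NumericMatrix &dirs;
  int cursor;
  explicit DirPool(const NumericMatrix &d) : dirs(d), cursor(0) {}
  P3 next() {
    if (cursor >= dirs.nrow())
      stop("projection direction pool exhausted (degenerate geometry?)");
    P3 d{dirs(cursor, 0), dirs(cursor, 1), dirs(cursor, 2)};
    ++cursor;
    return d;
  }
};

// classify one closed loop; fills d1 (and coefs if wanted); true on success
static bool loop_invariants(const std::vector<P3> &loop, DirPool &pool,
                            int max_try, bool want_poly, int64_t &d1,
                            std::vector<int64_t> &coefs, int &ncross) {
  std::vector<int> alive;
  kmt_run(loop, true, alive);
  std::vector<P3> red(alive.size());
  for (size_t i = 0; i < alive.size(); ++i) red[i] = loop[alive[i]];
  ncross = 0;
  if (red.size() <= 3) {
    d1 = 1;
    coefs.assign(1, 1);
    return true;
  }
  std::vector<Crossing> cr;
  // Exact incidences in 3D (a vertex lying on another segment, as straight
  // interpolated linkers can produce) defeat every projection; after
  // repeated degenerate projections the loop is nudged by a deterministic
  // jitter far below any topological clearance.
  double jscale = 1e-6 * std::max(bbox_diag(red), 1.0);
  uint64_t rng_state = 0x9E3779B97F4A7C15ULL;
  auto jitter = [&]() {
    for (P3 &p : red)
      for (int c = 0; c < 3; ++c) {
        rng_state ^= rng_state << 13;
        rng_state ^= rng_state >> 7;
        rng_state ^= rng_state << 17;
        p[c] += jscale * (2.0 * ((rng_state >> 11) * (1.0 / 9007199254740992.0)) - 1.0);
      }
  };
  for (int att = 0; att < max_try; ++att) {
    if (att > 0 && att % 16 == 0) jitter();
    P3 dir = pool.next();
    int rc = build_diagram(red, dir, cr);
    if (rc == -1) continue;
    if (rc == -2) return false;  // too complex; caller records NA
    int m;
    std::vector<int64_t> A, B;
    alex_matrix(cr, A, B, m);
    ncross = m;
    if (m <= 1) {
      d1 = 1;
      coefs.assign(1, 1);
      return true;
    }
    if (want_poly) {
      coefs = diagram_poly(A, B, m);
      if (coefs.empty()) continue;  // degenerate diagram, retry direction
      int64_t v = 0, tp = 1;
      for (int64_t c0 : coefs) { v += c0 * tp; tp *= -1; }
      d1 = std::llabs(v);
    } else {
      coefs.clear();
      d1 = diagram_d1(A, B, m);
    }
    return true;
  }
  stop("no valid projection found after %d attempts", max_try);
  return false;
}

// Classify an open chain over a set of closures.
//  pts       open chain (n x 3)
//  closures  far closure points (m x 3); ignored when direct = true
//  dirs      pool of unit projection directions (shared, consumed in order)
//  ambig     sorted |Delta(-1)| values that require the full polynomial
//  early_window  stop once this many closures agree unanimously (0 = never)
//  max_reps  polynomials kept per distinct ambiguous d1 value
// [[Rcpp::export]]
List cpp_classify_open(NumericMatrix pts, NumericMatrix closures,
                       NumericMatrix dirs, bool direct,
                       IntegerVector ambig, int early_window, int max_reps) {
  int n = pts.nrow();
  std::vector<P3> p(n);
  for (int i = 0; i < n; ++i) p[i] = P3{pts(i, 0), pts(i, 1), pts(i, 2)};
  std::vector<int> alive;
  kmt_run(p, false, alive);
  std::vector<P3> red(alive.size());
  for (size_t i = 0; i < alive.size(); ++i) red[i] = p[alive[i]];

  int m = direct ? 1 : closures.nrow();
  std::vector<double> d1s;
  d1s.reserve(m);
  std::vector<double> rep_d1;
  List polys;
  std::vector<int64_t> ambig_set(ambig.begin(), ambig.end());
  std::sort(ambig_set.begin(), ambig_set.end());
  std::vector<std::pair<int64_t, int>> rep_count;

  DirPool pool(dirs);
  bool unanimous = true;

  if (red.size() <= 4) {
    // closing a reduced chain of <= 4 points gives a polygon of <= 5
    // vertices, below the trefoil's stick number: always unknotted
    for (int k = 0; k < m; ++k) d1s.push_back(1);
    return List::create(_["d1"] = NumericVector(d1s.begin(), d1s.end()),
                        _["rep_d1"] = NumericVector(0), _["polys"] = List(0),
                        _["n_evaluated"] = m,
                        _["reduced_n"] = (int)red.size());
  }

  for (int k = 0; k < m; ++k) {
    std::vector<P3> loop = red;
    if (!direct) loop.push_back(P3{closures(k, 0), closures(k, 1), closures(k, 2)});
    int64_t d1 = -1;
    std::vector<int64_t> coefs;
    int ncross = 0;
    bool ok = loop_invariants(loop, pool, 64, false, d1, coefs, ncross);
    if (!ok) {
      d1s.push_back(NA_REAL);
      continue;
    }
    bool is_ambig = std::binary_search(ambig_set.begin(), ambig_set.end(), d1);
    if (is_ambig) {
      int have = 0;
      for (auto &rc : rep_count)
        if (rc.first == d1) { have = rc.second; break; }
      if (have < max_reps) {
        // recompute with the polynomial on a fresh projection
        int64_t d1b;
        std::vector<int64_t> cf;
        int nc;
        if (loop_invariants(loop, pool, 64, true, d1b, cf, nc) && !cf.empty()) {
          IntegerVector iv((int)cf.size());
          for (int q = 0; q < (int)cf.size(); ++q) iv[q] = (int)cf[q];
          polys.push_back(iv);
          rep_d1.push_back((double)d1b);
          bool found = false;
          for (auto &rc : rep_count)
            if (rc.first == d1b) { rc.second++; found = true; break; }
          if (!found) rep_count.push_back({d1b, 1});
          d1 = d1b;  // the polynomial value is authoritative for this closure
        }
      }
    }
    d1s.push_back((double)d1);
    if (d1s.size() > 1 && d1s.back() != d1s.front()) unanimous = false;
    if (early_window > 0 && (int)d1s.size() >= early_window && unanimous) break;
  }
  return List::create(_["d1"] = NumericVector(d1s.begin(), d1s.end()),
                      _["rep_d1"] = NumericVector(rep_d1.begin(), rep_d1.end()),
                      _["polys"] = polys,
                      _["n_evaluated"] = (int)d1s.size(),
                      _["reduced_n"] = (int)red.size());
}

// Alexander polynomial of an explicit closed loop (used by alexander_value
// and by the invariant tests).
// [[Rcpp::export]]
List cpp_loop_poly(NumericMatrix loop, NumericMatrix dirs) {
  int n = loop.nrow();
  std::vector<P3> p(n);
  for (int i = 0; i < n; ++i) p[i] = P3{loop(i, 0), loop(i, 1), loop(i, 2)};
  DirPool pool(dirs);
  int64_t d1;
  std::vector<int64_t> coefs;
  int ncross = 0;
  bool ok = loop_invariants(p, pool, dirs.nrow(), true, d1, coefs, ncross);
  if (!ok || coefs.empty()) stop("could not compute a valid diagram for the loop");
  IntegerVector iv((int)coefs.size());
  for (int q = 0; q < (int)coefs.size(); ++q) iv[q] = (int)coefs[q];
  return List::create(_["coef"] = iv, _["ncross"] = ncross);
}
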