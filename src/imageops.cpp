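#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// 8-connected component labelling by BFS flood fill.
// mask: integer/logical matrix (non-zero = foreground). Returns integer
// label matrix, labels 1..K in scan order of the component seed pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push(c * nr + r);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int cr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) && !lab(rr, c2)) {
              lab(rr, c2) = next;
              q.push(c2 * nr + rr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing (8-connected outer contour, clockwise in
// raster coordinates) with Jacob's stopping criterion.
// Returns an n x 2 matrix of (x = col, y = row), 1-based.
// [[Rcpp::export(name = ".trace_boundary")]]
NumericMatrix trace_boundary(const IntegerMatrix& lab, int label) {
  int nr = lab.nrow(), nc = lab.ncol();
  // Moore neighbourhood in clockwise order starting from W
  const int dr[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
  const int dc[8] = {-1, -1,  0,  1,  1,  1, 0, -1};
  int sr = -1, sc = -1;
  for (int c = 0; c < nc && sr < 0; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) return NumericMatrix(0, 2);
  std::vector<double> xs, ys;
  int br = sr, bc = sc;       // current boundary pixel
  int back = 0;               // index of backtrack direction (came from W)
  xs.push_back(bc + 1); ys.push_back(br + 1);
  for (int guard = 0; guard < 8 * nr * nc; ++guard) {
    bool found = false;
    int k = (back + 1) % 8;
    for (int s = 0; s < 8; ++s) {
      int d = (k + s) % 8;
      int rr = br + dr[d], cc = bc + dc[d];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab(rr, cc) == label) {
        br = rr; bc = cc;
        back = (d + 4) % 8; // came from opposite direction
        found = true;
        break;
      }
    }
    if (!found) break; // isolated pixel
    if (br == sr && bc == sc && (int)xs.size() > 1) break;
    xs.push_back(bc + 1); ys.push_back(br + 1);
    if ((int)xs.size() > 4 * (nr + nc) * 4) break; // safety
  }
  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Draw a tapered capsule along a polyline into img (modified in place).
// pts: n x 2 (x = col, y = row, 1-based, double); halfw, intens: per point.
// Darker-wins for dark-on-light (take = -1), lighter-wins for inverted (+1).
// [[Rcpp::export(name = ".render_polyline")]]
void render_polyline(NumericMatrix img, const NumericMatrix& pts,
                     const NumericVector& halfw, const NumericVector& intens,
                     int take) {
  int nr = img.nrow(), nc = img.ncol();
  int n = pts.nrow();
  if (n < 2) return;
  double wmax = 0;
  for (int i = 0; i < n; ++i) wmax = std::max(wmax, halfw[i]);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  int c0 = std::max(0, (int)std::floor(xmin - wmax - 2) - 1);
  int c1 = std::min(nc - 1, (int)std::ceil(xmax + wmax + 1));
  int r0 = std::max(0, (int)std::floor(ymin - wmax - 2) - 1);
  int r1 = std::min(nr - 1, (int)std::ceil(ymax + wmax + 1));
  for (int c = c0; c <= c1; ++c) {
    double px = c + 1;
    for (int r = r0; r <= r1; ++r) {
      double py = r + 1;
      double best = R_PosInf; double bint = NA_REAL;
      for (int i = 0; i + 1 < n; ++i) {
        double ax = pts(i, 0), ay = pts(i, 1);
        double bx = pts(i + 1, 0), by = pts(i + 1, 1);
        double vx = bx - ax, vy = by - ay;
        double L2 = vx * vx + vy * vy;
        double t = L2 > 0 ? ((px - ax) * vx + (py - ay) * vy) / L2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
        double d = std::sqrt(dx * dx + dy * dy);
        double w = halfw[i] + t * (halfw[i + 1] - halfw[i]);
        double rel = d - w;
        if (rel < best) {
          best = rel;
          bint = intens[i] + t * (intens[i + 1] - intens[i]);
        }
      }
      if (best <= 0) {
        double cur = img(r, c);
        if ((take < 0 && bint < cur) || (take > 0 && bint > cur))
          img(r, c) = bint;
      }
    }
  }
}

// Which of the query points lie inside the tapered capsule along pts?
// [[Rcpp::export(name = ".points_in_capsule")]]
LogicalVector points_in_capsule(const NumericMatrix& q, const NumericMatrix& pts,
                                const NumericVector& halfw) {
  int m = q.nrow(), n = pts.nrow();
  LogicalVector out(m);
  for (int j = 0; j < m; ++j) {
    double px = q(j, 0), py = q(j, 1);
    bool in = false;
    for (int i = 0; i + 1 < n && !in; ++i) {
      double ax = pts(i, 0), ay = pts(i, 1);
      double vx = pts(i + 1, 0) - ax, vy = pts(i + 1, 1) - ay;
      double L2 = vx * vx + vy * vy;
      double t = L2 > 0 ? ((px - ax) * vx + (py - ay) * vy) / L2 : 0.0;
      t = std::min(1.0, std::max(0.0, t));
      double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
      double w = halfw[i] + t * (halfw[i + 1] - halfw[i]);
      if (dx * dx + dy * dy <= w * w) in = true;
    }
    out[j] = in;
  }
  return out;
}

static inline void build_chain(double ax, double ay, double orient,
                               const double* joints, double seglen,
                               double* X, double* Y) {
  X[0] = ax; Y[0] = ay;
  double th = orient;
  for (int i = 0; i < 5; ++i) {
    if (i > 0) th += joints[i - 1];
    X[i + 1] = X[i] + seglen * std::cos(th);
    Y[i + 1] = Y[i] + seglen * std::sin(th);
  }
}

// Brute-force grid search of the 5-link larva shape model against residual
// contour pixels. State = orientation + 4 joint angles (radians); the model
// is a chain of 5 equal segments of length seglen anchored at (ax, ay).
// Score = number of residual pixels within halfwidth of the chain.
// Grids are absolute offsets to add to the current state.
// [[Rcpp::export(name = ".shape_fit_search")]]
List shape_fit_search(const NumericVector& resx, const NumericVector& resy,
                      double ax, double ay, double orient0,
                      const NumericVector& joints0, double seglen,
                      double halfwidth, const NumericVector& dOrient,
                      const NumericVector& dJoint) {
  int m = resx.size();
  int nO = dOrient.size(), nJ = dJoint.size();
  double bestScore = -1, bO = orient0, bJ[4] = {joints0[0], joints0[1], joints0[2], joints0[3]};
  double X[6], Y[6];
  double w2 = halfwidth * halfwidth;
  double reach = 5 * seglen + halfwidth + 1;
  for (int io = 0; io < nO; ++io) {
    double orient = orient0 + dOrient[io];
    for (int j1 = 0; j1 < nJ; ++j1) {
      double a1 = joints0[0] + dJoint[j1];
      if (std::fabs(a1) > M_PI / 2) continue;
      for (int j2 = 0; j2 < nJ; ++j2) {
        double a2 = joints0[1] + dJoint[j2];
        if (std::fabs(a2) > M_PI / 2) continue;
        for (int j3 = 0; j3 < nJ; ++j3) {
          double a3 = joints0[2] + dJoint[j3];
          if (std::fabs(a3) > M_PI / 2) continue;
          for (int j4 = 0; j4 < nJ; ++j4) {
            double a4 = joints0[3] + dJoint[j4];
            if (std::fabs(a4) > M_PI / 2) continue;
            double joints[4] = {a1, a2, a3, a4};
            build_chain(ax, ay, orient, joints, seglen, X, Y);
            int score = 0;
            for (int p = 0; p < m; ++p) {
              double px = resx[p], py = resy[p];
              double dax = px - ax, day = py - ay;
              if (dax * dax + day * day > reach * reach) continue;
              for (int s = 0; s < 5; ++s) {
                double vx = X[s + 1] - X[s], vy = Y[s + 1] - Y[s];
                double L2 = vx * vx + vy * vy;
                double t = ((px - X[s]) * vx + (py - Y[s]) * vy) / L2;
                t = std::min(1.0, std::max(0.0, t));
                double dx = px - (X[s] + t * vx), dy = py - (Y[s] + t * vy);
                if (dx * dx + dy * dy <= w2) { ++score; break; }
              }
            }
            if (score > bestScore) {
              bestScore = score; bO = orient;
              bJ[0] = a1; bJ[1] = a2; bJ[2] = a3; bJ[3] = a4;
            }
          }
        }
      }
    }
  }
  double joints[4] = {bJ[0], bJ[1], bJ[2], bJ[3]};
  build_chain(ax, ay, bO, joints, seglen, X, Y);
  NumericMatrix chain(6, 2);
  for (int i = 0; i < 6; ++i) { chain(i, 0) = X[i]; chain(i, 1) = Y[i]; }
  return List::create(_["orientation"] = bO,
                      _["joints"] = NumericVector::create(bJ[0], bJ[1], bJ[2], bJ[3]),
                      _["score"] = bestScore,
                      _["chain"] = chain);
}

// Pairwise pixel-overlap counts between blobs of two frames.
// Each blob is a sorted integer vector of linear pixel indices.
// [[Rcpp::export(name = ".overlap_counts")]]
IntegerMatrix overlap_counts(const List& prev, const List& curr) {
  int np = prev.size(), nc = curr.size();
  IntegerMatrix out(np, nc);
  for (int i = 0; i < np; ++i) {
    IntegerVector a = prev[i];
    for (int j = 0; j < nc; ++j) {
      IntegerVector b = curr[j];
      int ia = 0, ib = 0, cnt = 0;
      while (ia < a.size() && ib < b.size()) {
        if (a[ia] < b[ib]) ++ia;
        else if (a[ia] > b[ib]) ++ib;
        else { ++cnt; ++ia; ++ib; }
      }
      out(i, j) = cnt;
    }
  }
  return out;
}
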