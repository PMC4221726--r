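#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Band-filter kinds. Offset tables (dr, dc, uy, ux) are precomputed in R
// (ray_offsets) so the rounding convention lives in exactly one place; uy/ux
// are the unit vectors from each rounded sample offset back toward the
// filter center.
enum FilterKind { KIND_CI = 0, KIND_SBF = 1, KIND_TSBF = 2 };

// Response of one filter at one (0-based) center pixel.
// Conventions (shared with the R brute-force oracle used in tests):
//  - per-sample score: SBF/CI cos(angle(gradient, toward-center)), 0 where
//    the gradient magnitude is 0; TSBF omega * |g . u| = omega * |cos| * |g|
//  - samples at radius < 1 or outside the image are dropped; a band mean is
//    renormalized by its surviving sample count
//  - a line whose bands are all empty contributes 0 but still counts in the
//    outer mean over n_lines
static double pixel_response(int cy, int cx,
                             const NumericMatrix &gx, const NumericMatrix &gy,
                             const IntegerMatrix &dr, const IntegerMatrix &dc,
                             const NumericMatrix &uy, const NumericMatrix &ux,
                             const LogicalVector &rad_ok,
                             int rad_lo, int rmin, int rmax, int bw,
                             double omega, int kind,
                             std::vector<double> &s, std::vector<char> &ok,
                             std::vector<double> &ps, std::vector<int> &pc) {
  const int L = dr.nrow(), K = dr.ncol();
  const int H = gx.nrow(), W = gx.ncol();
  double acc = 0.0, ci_sum = 0.0;
  long ci_cnt = 0;
  for (int l = 0; l < L; ++l) {
    for (int j = 0; j < K; ++j) {
      ok[j] = 0;
      s[j] = 0.0;
      if (!rad_ok[j]) continue;
      const int py = cy + dr(l, j), px = cx + dc(l, j);
      if (py < 0 || py >= H || px < 0 || px >= W) continue;
      const double g2 = gx(py, px), g1 = gy(py, px);
      const double dot = g1 * uy(l, j) + g2 * ux(l, j);
      if (kind == KIND_TSBF) {
        s[j] = omega * std::fabs(dot);
      } else {
        const double m = std::sqrt(g1 * g1 + g2 * g2);
        s[j] = (m > 0.0) ? dot / m : 0.0;
      }
      ok[j] = 1;
    }
    if (kind == KIND_CI) {
      // fixed annular support r in [rmin, rmax], no sliding band
      for (int j = 0; j < K; ++j) {
        const int radv = rad_lo + j;
        if (radv >= rmin && radv <= rmax && ok[j]) { ci_sum += s[j]; ++ci_cnt; }
      }
      continue;
    }
    // prefix sums over (score, valid count) make every band O(1)
    ps[0] = 0.0; pc[0] = 0;
    for (int j = 0; j < K; ++j) {
      ps[j + 1] = ps[j] + s[j];
      pc[j + 1] = pc[j] + (ok[j] ? 1 : 0);
    }
    double best = 0.0;
    bool any = false;
    for (int r = rmin; r <= rmax; ++r) {
      int j0 = r - bw / 2 - rad_lo;  // band samples r - floor(bw/2) .. r + ceil(bw/2) - 1
      int j1 = j0 + bw;              // exclusive
      if (j0 < 0) j0 = 0;
      if (j1 > K) j1 = K;
      if (j0 >= j1) continue;
      const int cnt = pc[j1] - pc[j0];
      if (cnt > 0) {
        const double b = (ps[j1] - ps[j0]) / cnt;
        if (!any || b > best) { best = b; any = true; }
      }
    }
    acc += any ? best : 0.0;
  }
  if (kind == KIND_CI) return ci_cnt > 0 ? ci_sum / ci_cnt : 0.0;
  return acc / L;
}

// [[Rcpp::export]]
NumericVector point_response_cpp(NumericMatrix gx, NumericMatrix gy,
                                 IntegerMatrix dr, IntegerMatrix dc,
                                 NumericMatrix uy, NumericMatrix ux,
                                 LogicalVector rad_ok, int rad_lo,
                                 int rmin, int rmax, int bw,
                                 double omega, int kind,
                                 IntegerVector cy, IntegerVector cx) {
  const int n = cy.size();
  NumericVector out(n);
  std::vector<double> s(dr.ncol());
  std::vector<char> ok(dr.ncol());
  std::vector<double> ps(dr.ncol() + 1);
  std::vector<int> pc(dr.ncol() + 1);
  for (int i = 0; i < n; ++i)
    out[i] = pixel_response(cy[i], cx[i], gx, gy, dr, dc, uy, ux, rad_ok,
                            rad_lo, rmin, rmax, bw, omega, kind, s, ok, ps, pc);
  return out;
}

// [[Rcpp::export]]
NumericMatrix response_map_cpp(NumericMatrix gx, NumericMatrix gy,
                               IntegerMatrix dr, IntegerMatrix dc,
                               NumericMatrix uy, NumericMatrix ux,
                               LogicalVector rad_ok, int rad_lo,
                               int rmin, int rmax, int bw,
                               double omega, int kind) {
  const int H = gx.nrow(), W = gx.ncol();
  NumericMatrix out(H, W);
  std::vector<double> s(dr.ncol());
  std::vector<char> ok(dr.ncol());
  std::vector<double> ps(dr.ncol() + 1);
  std::vector<int> pc(dr.ncol() + 1);
  for (int c = 0; c < W; ++c) {
    Rcpp::checkUserInterrupt();
    for (int r = 0; r < H; ++r)
      out(r, c) = pixel_response(r, c, gx, gy, dr, dc, uy, ux, rad_ok,
                                 rad_lo, rmin, rmax, bw, omega, kind, s, ok, ps, pc);
  }
  return out;
}

// Local maxima of v over (2*half+1)^2 windows, strictly above thr.
// A pixel is kept iff no window neighbour is larger and no equal-valued
// window neighbour precedes it in (row, col) lexicographic order, which
// keeps exactly one representative per tied plateau.
// [[Rcpp::export]]
List nms_cpp(NumericMatrix v, int half, double thr) {
  const int H = v.nrow(), W = v.ncol();
  std::vector<int> rows, cols;
  std::vector<double> scores;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const double x = v(r, c);
      if (!(x > thr)) continue;
      bool keep = true;
      const int r0 = std::max(0, r - half), r1 = std::min(H - 1, r + half);
      const int c0 = std::max(0, c - half), c1 = std::min(W - 1, c + half);
      for (int rr = r0; rr <= r1 && keep; ++rr)
        for (int cc = c0; cc <= c1; ++cc) {
          if (rr == r && cc == c) continue;
          const double y = v(rr, cc);
          if (y > x || (y == x && (rr < r || (rr == r && cc < c)))) {
            keep = false;
            break;
          }
        }
      if (keep) { rows.push_back(r); cols.push_back(c); scores.push_back(x); }
    }
  }
  return List::create(_["row"] = wrap(rows), _["col"] = wrap(cols),
                      _["score"] = wrap(scores));
}
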