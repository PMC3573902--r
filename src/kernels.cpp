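// Low-level numerical kernels: separable correlation, per-pixel 3x3
// symmetric eigen-solve for the structure-tensor flow, bilinear sampling,
// morphological thinning and geodesic distances on binary masks.
#include <RcppArmadillo.h>
#include <queue>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Separable 2-D correlation with replicate borders. kx runs along x
// (columns), ky along y (rows); both must have odd length.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv2(const NumericMatrix& img,
                           const NumericVector& kx,
                           const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // pass along x (columns)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int k = -rx; k <= rx; ++k) {
        int jj = j + k;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        s += img(i, jj) * kx[k + rx];
      }
      tmp(i, j) = s;
    }
  }
  // pass along y (rows)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        s += tmp(ii, j) * ky[k + ry];
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Total-least-squares flow from the 3x3 spatiotemporal structure tensor.
// The eigenvector e of the smallest eigenvalue is parallel to (u, v, 1)
// where the brightness-constancy constraint g_x u + g_y v + g_t = 0 is
// solvable; pixels where the two smallest eigenvalues are not separated
// (aperture problem) or where e_t ~ 0 are flagged invalid. Confidence is
// the coherence (l2 - l3) / (l2 + l3 + eps) with l1 >= l2 >= l3.
// [[Rcpp::export]]
List cpp_flow_solve(const NumericMatrix& Jxx, const NumericMatrix& Jxy,
                    const NumericMatrix& Jxt, const NumericMatrix& Jyy,
                    const NumericMatrix& Jyt, const NumericMatrix& Jtt,
                    double eps, double sep_rel_tol) {
  const int nr = Jxx.nrow(), nc = Jxx.ncol();
  NumericMatrix u(nr, nc), v(nr, nc), conf(nr, nc);
  LogicalMatrix valid(nr, nc);
  arma::mat33 J;
  arma::vec3 eval;
  arma::mat33 evec;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      J(0, 0) = Jxx(i, j); J(0, 1) = Jxy(i, j); J(0, 2) = Jxt(i, j);
      J(1, 0) = Jxy(i, j); J(1, 1) = Jyy(i, j); J(1, 2) = Jyt(i, j);
      J(2, 0) = Jxt(i, j); J(2, 1) = Jyt(i, j); J(2, 2) = Jtt(i, j);
      u(i, j) = 0.0; v(i, j) = 0.0; conf(i, j) = 0.0; valid(i, j) = false;
      double tr = J(0, 0) + J(1, 1) + J(2, 2);
      if (!std::isfinite(tr) || tr <= eps) continue;  // no structure at all
      if (!arma::eig_sym(eval, evec, J)) continue;    // ascending eigenvalues
      double l3 = std::max(eval(0), 0.0);
      double l2 = std::max(eval(1), 0.0);
      double l1 = std::max(eval(2), 0.0);
      double c = (l2 - l3) / (l2 + l3 + eps);
      conf(i, j) = (c < 0.0) ? 0.0 : (c > 1.0 ? 1.0 : c);
      if (l1 <= eps) continue;
      if ((l2 - l3) < sep_rel_tol * l1) continue;     // aperture / degenerate
      double ex = evec(0, 0), ey = evec(1, 0), et = evec(2, 0);
      if (std::fabs(et) < 1e-6) continue;             // motion unresolvable
      u(i, j) = ex * et / (et * et + eps);
      v(i, j) = ey * et / (et * et + eps);
      valid(i, j) = true;
    }
  }
  return List::create(_["u"] = u, _["v"] = v,
                      _["confidence"] = conf, _["valid"] = valid);
}

// Bilinear sampling of img at 0-based (x = column, y = row) positions.
// Positions outside the grid return NA.
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img,
                           const NumericVector& x,
                           const NumericVector& y) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double xv = x[k], yv = y[k];
    if (!std::isfinite(xv) || !std::isfinite(yv) ||
        xv < 0.0 || yv < 0.0 || xv > nc - 1.0 || yv > nr - 1.0) {
      out[k] = NA_REAL;
      continue;
    }
    int j0 = (int)std::floor(xv), i0 = (int)std::floor(yv);
    if (j0 >= nc - 1) j0 = nc - 2;
    if (i0 >= nr - 1) i0 = nr - 2;
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    double fx = xv - j0, fy = yv - i0;
    out[k] = img(i0, j0) * (1 - fx) * (1 - fy) +
             img(i0, j0 + 1) * fx * (1 - fy) +
             img(i0 + 1, j0) * (1 - fx) * fy +
             img(i0 + 1, j0 + 1) * fx * fy;
  }
  return out;
}

// Backward warp: out(i, j) = img(y = i + dy(i,j), x = j + dx(i,j)),
// bilinear; out-of-bounds samples yield NA.
// [[Rcpp::export]]
NumericMatrix cpp_warp(const NumericMatrix& img,
                       const NumericMatrix& dx,
                       const NumericMatrix& dy) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double xv = j + dx(i, j), yv = i + dy(i, j);
      if (!std::isfinite(xv) || !std::isfinite(yv) ||
          xv < 0.0 || yv < 0.0 || xv > nc - 1.0 || yv > nr - 1.0) {
        out(i, j) = NA_REAL;
        continue;
      }
      int j0 = (int)std::floor(xv), i0 = (int)std::floor(yv);
      if (j0 >= nc - 1) j0 = nc - 2;
      if (i0 >= nr - 1) i0 = nr - 2;
      double fx = xv - j0, fy = yv - i0;
      out(i, j) = img(i0, j0) * (1 - fx) * (1 - fy) +
                  img(i0, j0 + 1) * fx * (1 - fy) +
                  img(i0 + 1, j0) * (1 - fx) * fy +
                  img(i0 + 1, j0 + 1) * fx * fy;
    }
  }
  return out;
}

// Fill entries where valid is FALSE with the value of the nearest valid
// pixel (multi-source BFS over the 8-neighbourhood). Used to extend flow
// fields across low-confidence holes before interpolation.
// [[Rcpp::export]]
NumericMatrix cpp_fill_nearest(const NumericMatrix& img,
                               const LogicalMatrix& valid) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  IntegerMatrix state(nr, nc);  // 0 unset, 1 set
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (valid(i, j)) {
        out(i, j) = img(i, j);
        state(i, j) = 1;
        q.push(std::make_pair(i, j));
      } else out(i, j) = NA_REAL;
    }
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 8; ++k) {
      int ii = p.first + di[k], jj = p.second + dj[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      if (state(ii, jj)) continue;
      out(ii, jj) = out(p.first, p.second);
      state(ii, jj) = 1;
      q.push(std::make_pair(ii, jj));
    }
  }
  return out;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning of a binary mask to a 1-px-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours p2..p9 clockwise from north
          int p2 = nb(m, i - 1, j),     p3 = nb(m, i - 1, j + 1);
          int p4 = nb(m, i, j + 1),     p5 = nb(m, i + 1, j + 1);
          int p6 = nb(m, i + 1, j),     p7 = nb(m, i + 1, j - 1);
          int p8 = nb(m, i, j - 1),     p9 = nb(m, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        m(kill[k].first, kill[k].second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

// Geodesic (along-mask) distances from a start pixel by Dijkstra over the
// 8-neighbourhood with Euclidean step weights. Returns the distance grid
// (NA off the mask or unreachable) and predecessor indices for path
// extraction (0-based, -1 at the source / unreached).
// [[Rcpp::export]]
List cpp_geodesic(const LogicalMatrix& mask, int start_i, int start_j) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dist(nr, nc);
  IntegerMatrix pred_i(nr, nc), pred_j(nr, nc);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  std::fill(pred_i.begin(), pred_i.end(), -1);
  std::fill(pred_j.begin(), pred_j.end(), -1);
  if (start_i < 0 || start_j < 0 || start_i >= nr || start_j >= nc ||
      !mask(start_i, start_j))
    stop("geodesic start pixel is not on the mask");
  typedef std::pair<double, int> QE;  // (distance, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  std::vector<double> d(nr * nc, R_PosInf);
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double w[8] = {M_SQRT2, 1, M_SQRT2, 1, 1, M_SQRT2, 1, M_SQRT2};
  int s = start_i + start_j * nr;
  d[s] = 0.0;
  pq.push(std::make_pair(0.0, s));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int idx = top.second;
    if (top.first > d[idx]) continue;
    int i = idx % nr, j = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      if (!mask(ii, jj)) continue;
      double nd = d[idx] + w[k];
      int nidx = ii + jj * nr;
      if (nd < d[nidx]) {
        d[nidx] = nd;
        pred_i(ii, jj) = i;
        pred_j(ii, jj) = j;
        pq.push(std::make_pair(nd, nidx));
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) && std::isfinite(d[i + j * nr]))
        dist(i, j) = d[i + j * nr];
  return List::create(_["dist"] = dist,
                      _["pred_i"] = pred_i, _["pred_j"] = pred_j);
}
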