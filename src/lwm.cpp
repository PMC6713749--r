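#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tricubic weight kernel W(R) = 1 - 3R^2 + 2R^3 on [0,1], 0 beyond.
static inline double wkernel(double R) {
  if (R >= 1.0) return 0.0;
  return 1.0 - 3.0 * R * R + 2.0 * R * R * R;
}

// Ten-term second-order monomial basis, centred offsets (dx, dy, dz).
static inline void basis10(double dx, double dy, double dz, double* b) {
  b[0] = 1.0; b[1] = dx; b[2] = dy; b[3] = dz;
  b[4] = dx * dx; b[5] = dy * dy; b[6] = dz * dz;
  b[7] = dx * dy; b[8] = dx * dz; b[9] = dy * dz;
}

// Uniform-grid bucket index over a point cloud, for neighbour queries.
struct BucketGrid {
  arma::mat pts;             // N x 3
  double x0, y0, z0, h;
  int ncx, ncy, ncz;
  std::vector<std::vector<int>> cells;

  BucketGrid(const arma::mat& p, double target_per_cell) : pts(p) {
    const int n = p.n_rows;
    arma::rowvec mn = arma::min(p, 0), mx = arma::max(p, 0);
    x0 = mn[0]; y0 = mn[1]; z0 = mn[2];
    double vol = std::max(1e-9, (mx[0] - mn[0]) * (mx[1] - mn[1]) *
                                 (mx[2] - mn[2]));
    h = std::cbrt(vol * target_per_cell / std::max(1, n));
    if (!(h > 1e-9)) h = 1.0;
    ncx = std::max(1, (int)std::floor((mx[0] - x0) / h) + 1);
    ncy = std::max(1, (int)std::floor((mx[1] - y0) / h) + 1);
    ncz = std::max(1, (int)std::floor((mx[2] - z0) / h) + 1);
    cells.resize((size_t)ncx * ncy * ncz);
    for (int i = 0; i < n; ++i) cells[cell_of(i)].push_back(i);
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline size_t cidx(int cx, int cy, int cz) const {
    return (size_t)cx + (size_t)ncx * (cy + (size_t)ncy * cz);
  }
  inline size_t cell_of(int i) const {
    int cx = clampi((int)std::floor((pts(i, 0) - x0) / h), ncx);
    int cy = clampi((int)std::floor((pts(i, 1) - y0) / h), ncy);
    int cz = clampi((int)std::floor((pts(i, 2) - z0) / h), ncz);
    return cidx(cx, cy, cz);
  }
  // Indices of all points within `radius` of q (conservative cell sweep).
  void within(const double* q, double radius, std::vector<int>& out) const {
    out.clear();
    int cx0 = clampi((int)std::floor((q[0] - radius - x0) / h), ncx);
    int cx1 = clampi((int)std::floor((q[0] + radius - x0) / h), ncx);
    int cy0 = clampi((int)std::floor((q[1] - radius - y0) / h), ncy);
    int cy1 = clampi((int)std::floor((q[1] + radius - y0) / h), ncy);
    int cz0 = clampi((int)std::floor((q[2] - radius - z0) / h), ncz);
    int cz1 = clampi((int)std::floor((q[2] + radius - z0) / h), ncz);
    for (int cz = cz0; cz <= cz1; ++cz)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cx = cx0; cx <= cx1; ++cx) {
          const std::vector<int>& c = cells[cidx(cx, cy, cz)];
          out.insert(out.end(), c.begin(), c.end());
        }
  }
};

// k nearest neighbours (self included) for every row of `pts`.
// Returns 1-based index matrix (N x k) ordered by increasing distance,
// and the distance to the k-th member (the neighbourhood radius).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix pts_, int k) {
  arma::mat pts(pts_.begin(), pts_.nrow(), pts_.ncol(), false);
  const int n = pts.n_rows;
  if (k > n) stop("k exceeds the number of points");
  BucketGrid grid(pts, (double)k);
  IntegerMatrix idx(n, k);
  NumericVector radius(n);
  std::vector<int> cand;
  std::vector<std::pair<double, int>> best;
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double r = grid.h;  // expand until k points are certainly covered
    for (;;) {
      grid.within(q, r, cand);
      if ((int)cand.size() >= k) {
        best.clear();
        best.reserve(cand.size());
        for (int j : cand) {
          double dx = pts(j, 0) - q[0], dy = pts(j, 1) - q[1],
                 dz = pts(j, 2) - q[2];
          best.push_back({std::sqrt(dx * dx + dy * dy + dz * dz), j});
        }
        std::nth_element(best.begin(), best.begin() + (k - 1), best.end());
        double kth = best[k - 1].first;
        if (kth <= r || (int)cand.size() == n) {
          std::partial_sort(best.begin(), best.begin() + k, best.end());
          for (int m = 0; m < k; ++m) idx(i, m) = best[m].second + 1;
          radius[i] = kth;
          break;
        }
      }
      r *= 2.0;
      if (r > 1e12) stop("knn search failed to converge");
    }
  }
  return List::create(_["idx"] = idx, _["radius"] = radius);
}

// Local least-squares quadratic fits: for each control point, fit the three
// mapped coordinates over its k-point neighbourhood with the 10-term basis
// centred on the control point. Returns an N x 30 coefficient matrix
// (columns 1-10 -> X, 11-20 -> Y, 21-30 -> Z).
// [[Rcpp::export]]
NumericMatrix cpp_lwm_fit(NumericMatrix src_, NumericMatrix dst_,
                          IntegerMatrix nn) {
  arma::mat src(src_.begin(), src_.nrow(), 3, false);
  arma::mat dst(dst_.begin(), dst_.nrow(), 3, false);
  const int n = src.n_rows, k = nn.ncol();
  if (k < 10) stop("neighbourhood smaller than the 10-term basis");
  NumericMatrix coef(n, 30);
  arma::mat D(k, 10), rhs(k, 3);
  double b[10];
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < k; ++m) {
      const int j = nn(i, m) - 1;
      basis10(src(j, 0) - src(i, 0), src(j, 1) - src(i, 1),
              src(j, 2) - src(i, 2), b);
      for (int c = 0; c < 10; ++c) D(m, c) = b[c];
      rhs(m, 0) = dst(j, 0); rhs(m, 1) = dst(j, 1); rhs(m, 2) = dst(j, 2);
    }
    arma::mat Q, R;
    if (!arma::qr_econ(Q, R, D)) stop("QR failed at control point %d", i + 1);
    const double tol = 10 * arma::datum::eps * arma::abs(R.diag()).max();
    if (arma::sum(arma::abs(R.diag()) > tol) < 10)
      stop("rank-deficient neighbourhood at control point %d", i + 1);
    arma::mat sol = arma::solve(arma::trimatu(R), Q.t() * rhs);
    for (int c = 0; c < 10; ++c) {
      coef(i, c) = sol(c, 0);
      coef(i, 10 + c) = sol(c, 1);
      coef(i, 20 + c) = sol(c, 2);
    }
  }
  return coef;
}

static inline void eval_poly(const NumericMatrix& coef, int i,
                             const double* b, double* out) {
  double X = 0, Y = 0, Z = 0;
  for (int c = 0; c < 10; ++c) {
    X += coef(i, c) * b[c];
    Y += coef(i, 10 + c) * b[c];
    Z += coef(i, 20 + c) * b[c];
  }
  out[0] = X; out[1] = Y; out[2] = Z;
}

// Weighted-mean evaluation of the LWM transform at query points.
// mode 0: normalised distance uses each control point's own radius;
// mode 1: uses the query point's distance to its (n-1)-th nearest control
// point (the alternative reading; `nloc` supplies n).
// Queries beyond every influence radius fall back to the polynomial of the
// nearest control point.
// [[Rcpp::export]]
NumericMatrix cpp_lwm_eval(NumericMatrix src_, NumericMatrix coef,
                           NumericVector radii, NumericMatrix queries,
                           int mode, int nloc) {
  arma::mat src(src_.begin(), src_.nrow(), 3, false);
  const int n = src.n_rows, m = queries.nrow();
  NumericMatrix out(m, 3);
  BucketGrid grid(src, 8.0);
  const double rmax = Rcpp::max(radii);
  std::vector<int> cand;
  std::vector<double> dist_all;
  double b[10], val[3];
  for (int q = 0; q < m; ++q) {
    double p[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    double rq = 1.0;
    if (mode == 1) {
      // distance from the query to its (nloc-1)-th nearest control point
      dist_all.resize(n);
      for (int i = 0; i < n; ++i) {
        double dx = src(i, 0) - p[0], dy = src(i, 1) - p[1],
               dz = src(i, 2) - p[2];
        dist_all[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      std::vector<double> tmp(dist_all);
      int kk = std::min(n - 1, std::max(1, nloc - 1));
      std::nth_element(tmp.begin(), tmp.begin() + kk, tmp.end());
      rq = std::max(tmp[kk], 1e-12);
    }
    double num[3] = {0, 0, 0}, den = 0.0;
    double dmin = std::numeric_limits<double>::infinity();
    int imin = -1;
    if (mode == 0) {
      grid.within(p, rmax, cand);
    } else {
      cand.resize(n);
      for (int i = 0; i < n; ++i) cand[i] = i;
    }
    for (int i : cand) {
      const double dx = p[0] - src(i, 0), dy = p[1] - src(i, 1),
                   dz = p[2] - src(i, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < dmin) { dmin = d; imin = i; }
      const double R = d / (mode == 0 ? std::max(radii[i], 1e-12) : rq);
      const double w = wkernel(R);
      if (w > 0.0) {
        basis10(dx, dy, dz, b);
        eval_poly(coef, i, b, val);
        num[0] += w * val[0]; num[1] += w * val[1]; num[2] += w * val[2];
        den += w;
      }
    }
    if (den <= 0.0) {
      // the bucket sweep may have missed the true nearest control point
      dmin = std::numeric_limits<double>::infinity();
      imin = -1;
      for (int i = 0; i < n; ++i) {
        double dx = p[0] - src(i, 0), dy = p[1] - src(i, 1),
               dz = p[2] - src(i, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < dmin) { dmin = d; imin = i; }
      }
      basis10(p[0] - src(imin, 0), p[1] - src(imin, 1), p[2] - src(imin, 2),
              b);
      eval_poly(coef, imin, b, val);
      out(q, 0) = val[0]; out(q, 1) = val[1]; out(q, 2) = val[2];
    } else {
      out(q, 0) = num[0] / den;
      out(q, 1) = num[1] / den;
      out(q, 2) = num[2] / den;
    }
  }
  return out;
}
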