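#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major 3D view over an R array.
struct Arr3 {
  const double* p;
  int nx, ny, nz;
  Arr3(const NumericVector& v, const IntegerVector& d)
    : p(REAL(v)), nx(d[0]), ny(d[1]), nz(d[2]) {}
  inline double at(int x, int y, int z) const {
    return p[x + (long long)nx * (y + (long long)ny * z)];
  }
};

// Normalized cross-correlation between a moving-image block and the
// reference patch of the same size. Two-pass (explicitly centred) sums so
// the result tracks the definitional triple-sum to machine precision.
// Zero variance on either side yields 0 by convention.
static double ncc_pair(const Arr3& mv, int bx, int by, int bz,
                       const Arr3& rf, int px, int py, int pz,
                       int sx, int sy, int sz,
                       bool* block_zerovar = nullptr) {
  const double n = (double)sx * sy * sz;
  double sb = 0.0, sf = 0.0;
  for (int z = 0; z < sz; ++z)
    for (int y = 0; y < sy; ++y)
      for (int x = 0; x < sx; ++x) {
        sb += mv.at(bx + x, by + y, bz + z);
        sf += rf.at(px + x, py + y, pz + z);
      }
  const double mb = sb / n, mf = sf / n;
  double vb = 0.0, vf = 0.0, cov = 0.0;
  for (int z = 0; z < sz; ++z)
    for (int y = 0; y < sy; ++y)
      for (int x = 0; x < sx; ++x) {
        const double db = mv.at(bx + x, by + y, bz + z) - mb;
        const double df = rf.at(px + x, py + y, pz + z) - mf;
        vb += db * db;
        vf += df * df;
        cov += db * df;
      }
  if (block_zerovar) *block_zerovar = (vb <= 1e-12);
  if (vb <= 1e-12 || vf <= 1e-12) return 0.0;
  double lam = cov / std::sqrt(vb * vf);
  if (lam > 1.0) lam = 1.0;
  if (lam < -1.0) lam = -1.0;
  return lam;
}

// [[Rcpp::export]]
double cpp_ncc(NumericVector block, IntegerVector bdim,
               NumericVector region, IntegerVector rdim,
               IntegerVector lag) {
  Arr3 b(block, bdim), f(region, rdim);
  return ncc_pair(b, 0, 0, 0, f, lag[0], lag[1], lag[2],
                  bdim[0], bdim[1], bdim[2]);
}

// Exhaustive search of the reference for the best-matching placement of one
// moving-image block. Candidate origins span [lo, hi] inclusive on each
// axis. Ties on the correlation (within 1e-12) are broken by smallest
// Euclidean displacement from `tie_origin`, then lexicographic (z, y, x).
// [[Rcpp::export]]
List cpp_match_block(NumericVector moving, IntegerVector mdim,
                     NumericVector reference, IntegerVector rdim,
                     IntegerVector borig, IntegerVector bsize,
                     IntegerVector lo, IntegerVector hi,
                     IntegerVector tie_origin) {
  Arr3 mv(moving, mdim), rf(reference, rdim);
  const int sx = bsize[0], sy = bsize[1], sz = bsize[2];
  const int bx = borig[0], by = borig[1], bz = borig[2];

  // Block variance check (degenerate rule: textureless block cannot match).
  bool zerovar = false;
  ncc_pair(mv, bx, by, bz, mv, bx, by, bz, sx, sy, sz, &zerovar);
  if (zerovar) {
    return List::create(_["origin"] = tie_origin, _["cc"] = 0.0,
                        _["zerovar"] = true);
  }

  const double eps = 1e-12;
  double best = -2.0;
  long long best_d2 = -1;
  int ox = tie_origin[0], oy = tie_origin[1], oz = tie_origin[2];
  bool found = false;

  for (int pz = lo[2]; pz <= hi[2]; ++pz)
    for (int py = lo[1]; py <= hi[1]; ++py)
      for (int px = lo[0]; px <= hi[0]; ++px) {
        const double lam = ncc_pair(mv, bx, by, bz, rf, px, py, pz,
                                    sx, sy, sz);
        const long long dx = px - tie_origin[0];
        const long long dy = py - tie_origin[1];
        const long long dz = pz - tie_origin[2];
        const long long d2 = dx * dx + dy * dy + dz * dz;
        bool take = false;
        if (!found || lam > best + eps) {
          take = true;
        } else if (lam >= best - eps) {
          if (d2 < best_d2) {
            take = true;
          } else if (d2 == best_d2) {
            // lexicographic (z, y, x); loop order already visits in that
            // order so an equal candidate never displaces the incumbent
            take = false;
          }
        }
        if (take) {
          best = lam; best_d2 = d2; ox = px; oy = py; oz = pz;
          found = true;
        }
      }

  if (!found) stop("empty search region");
  return List::create(
    _["origin"] = IntegerVector::create(ox, oy, oz),
    _["cc"] = best, _["zerovar"] = false);
}

// Trilinear interpolation of a 3D volume at arbitrary (possibly fractional)
// voxel coordinates; samples outside the grid take `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector vdim,
                            NumericMatrix pts, double fill) {
  Arr3 v(vol, vdim);
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 ||
        x > v.nx - 1 || y > v.ny - 1 || z > v.nz - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == v.nx - 1) --x0;
    if (y0 == v.ny - 1) --y0;
    if (z0 == v.nz - 1) --z0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                           (dz ? fz : 1 - fz);
          acc += w * v.at(x0 + dx, y0 + dy, z0 + dz);
        }
    out[i] = acc;
  }
  return out;
}
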