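#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Even-odd (parity) point-in-polygon test over all polygons of one slice.
// Crossing test uses strict "<" so that voxel centres exactly on a vertical
// edge resolve deterministically.
// [[Rcpp::export(name = ".cpp_slice_parity")]]
LogicalVector cpp_slice_parity(NumericVector px, NumericVector py, List polys) {
  const int n = px.size();
  std::vector<int> cross(n, 0);
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix poly = polys[p];
    const int m = poly.nrow();
    for (int e = 0; e < m; ++e) {
      const double x1 = poly(e, 0), y1 = poly(e, 1);
      const int f = (e + 1 == m) ? 0 : e + 1;
      const double x2 = poly(f, 0), y2 = poly(f, 1);
      if (y1 == y2) continue;
      const double inv = (x2 - x1) / (y2 - y1);
      for (int i = 0; i < n; ++i) {
        if ((y1 > py[i]) != (y2 > py[i])) {
          const double xint = x1 + (py[i] - y1) * inv;
          if (px[i] < xint) ++cross[i];
        }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (cross[i] & 1);
  return out;
}

static inline double trilinear(const double *v, const int n1, const int n2,
                               const int n3, const double fx, const double fy,
                               const double fz) {
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
      k0 = (int)std::floor(fz);
  if (i0 > n1 - 2) i0 = n1 - 2;
  if (j0 > n2 - 2) j0 = n2 - 2;
  if (k0 > n3 - 2) k0 = n3 - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  const double ax = fx - i0, ay = fy - j0, az = fz - k0;
  const long s1 = 1, s2 = n1, s3 = (long)n1 * n2;
  const double *b = v + i0 * s1 + j0 * s2 + k0 * s3;
  const double c00 = b[0] * (1 - ax) + b[s1] * ax;
  const double c10 = b[s2] * (1 - ax) + b[s2 + s1] * ax;
  const double c01 = b[s3] * (1 - ax) + b[s3 + s1] * ax;
  const double c11 = b[s3 + s2] * (1 - ax) + b[s3 + s2 + s1] * ax;
  return (c00 * (1 - ay) + c10 * ay) * (1 - az) +
         (c01 * (1 - ay) + c11 * ay) * az;
}

// Local-normalisation gamma map. Candidate points lie on a regular lattice of
// pitch `step` inside a ball of radius `max_radius` around each reference
// voxel; candidates are visited in order of increasing distance and the
// search stops once the pure distance term exceeds the running minimum
// (valid because the dose term is non-negative). Candidates outside the
// evaluated grid's support are skipped. Voxels below threshold_frac *
// max(reference) get NA; a voxel with no valid candidate gets Inf.
// [[Rcpp::export(name = ".cpp_gamma_map")]]
NumericVector cpp_gamma_map(NumericVector refv, NumericVector ref_origin,
                            NumericVector ref_spacing, IntegerVector ref_dims,
                            NumericVector evalv, NumericVector eval_origin,
                            NumericVector eval_spacing, IntegerVector eval_dims,
                            double dose_tol_frac, double dta,
                            double threshold_frac, double step,
                            double max_radius) {
  const int rn1 = ref_dims[0], rn2 = ref_dims[1], rn3 = ref_dims[2];
  const int en1 = eval_dims[0], en2 = eval_dims[1], en3 = eval_dims[2];
  const double *ev = evalv.begin();

  // candidate offset lattice, sorted by distance
  const int ns = (int)std::floor(max_radius / step + 1e-9);
  std::vector<double> ox, oy, oz, d2v;
  for (int a = -ns; a <= ns; ++a)
    for (int b = -ns; b <= ns; ++b)
      for (int c = -ns; c <= ns; ++c) {
        const double x = a * step, y = b * step, z = c * step;
        const double d2 = x * x + y * y + z * z;
        if (d2 <= max_radius * max_radius + 1e-9) {
          ox.push_back(x); oy.push_back(y); oz.push_back(z); d2v.push_back(d2);
        }
      }
  std::vector<size_t> ord(ox.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return d2v[a] < d2v[b]; });

  double refmax = 0;
  for (int i = 0; i < refv.size(); ++i)
    if (refv[i] > refmax) refmax = refv[i];
  if (refmax <= 0) stop("reference distribution has zero maximum dose");
  const double cutoff = threshold_frac * refmax;
  const double dta2 = dta * dta;

  NumericVector out(refv.size(), NA_REAL);
  long idx = 0;
  for (int k = 0; k < rn3; ++k) {
    const double rz = ref_origin[2] + k * ref_spacing[2];
    for (int j = 0; j < rn2; ++j) {
      const double ry = ref_origin[1] + j * ref_spacing[1];
      for (int i = 0; i < rn1; ++i, ++idx) {
        const double dr = refv[idx];
        if (dr < cutoff) continue;
        const double rx = ref_origin[0] + i * ref_spacing[0];
        const double denom = dose_tol_frac * dr;
        double best = R_PosInf;
        for (size_t q = 0; q < ord.size(); ++q) {
          const size_t o = ord[q];
          const double dterm = d2v[o] / dta2;
          if (dterm >= best) break;  // sorted: no later candidate can win
          const double cx = rx + ox[o], cy = ry + oy[o], cz = rz + oz[o];
          const double fx = (cx - eval_origin[0]) / eval_spacing[0];
          const double fy = (cy - eval_origin[1]) / eval_spacing[1];
          const double fz = (cz - eval_origin[2]) / eval_spacing[2];
          if (fx < 0 || fx > en1 - 1 || fy < 0 || fy > en2 - 1 || fz < 0 ||
              fz > en3 - 1)
            continue;
          const double de = trilinear(ev, en1, en2, en3, fx, fy, fz);
          const double dd = (de - dr) / denom;
          const double g2 = dterm + dd * dd;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
    }
  }
  return out;
}

// Trilinear sampling of a grid at arbitrary points; out-of-support points
// return 0 and are flagged.
// [[Rcpp::export(name = ".cpp_sample_grid")]]
List cpp_sample_grid(NumericVector v, NumericVector origin,
                     NumericVector spacing, IntegerVector dims,
                     NumericMatrix pts) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector outside(n);
  const double *vv = v.begin();
  for (int i = 0; i < n; ++i) {
    const double fx = (pts(i, 0) - origin[0]) / spacing[0];
    const double fy = (pts(i, 1) - origin[1]) / spacing[1];
    const double fz = (pts(i, 2) - origin[2]) / spacing[2];
    if (fx < 0 || fx > n1 - 1 || fy < 0 || fy > n2 - 1 || fz < 0 ||
        fz > n3 - 1) {
      out[i] = 0.0;
      outside[i] = true;
    } else {
      out[i] = trilinear(vv, n1, n2, n3, fx, fy, fz);
      outside[i] = false;
    }
  }
  return List::create(_["dose"] = out, _["outside"] = outside);
}
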