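#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shape diameter function by interior ray casting (Moller-Trumbore
// intersection against every triangle; mesh sizes in this package are a few
// hundred to a few thousand faces, so brute force beats building a BVH).
// Rays leave each face centroid opposite to the face normal, spread over a
// deterministic Fibonacci spiral inside a cone; per-ray chord lengths are
// aggregated robustly in R.

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export(name = ".sdf_rays_cpp")]]
NumericMatrix sdf_rays_cpp(NumericMatrix V, IntegerMatrix F,
                           NumericMatrix centroids, NumericMatrix normals,
                           int n_rays, double cone_half_deg) {
  const int nf = F.nrow();
  const double eps = 1e-9;
  NumericMatrix hits(nf, n_rays); // chord length per ray; NA when no hit
  std::fill(hits.begin(), hits.end(), NA_REAL);

  // precompute triangle vertex arrays
  std::vector<double> A(3 * nf), E1(3 * nf), E2(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    for (int c = 0; c < 3; ++c) {
      A[3 * f + c] = V(i0, c);
      E1[3 * f + c] = V(i1, c) - V(i0, c);
      E2[3 * f + c] = V(i2, c) - V(i0, c);
    }
  }

  const double half = cone_half_deg * M_PI / 180.0;
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  // cone directions in local frame (z = axis): Fibonacci spiral over the
  // spherical cap, first ray straight down the axis
  std::vector<double> dirs(3 * n_rays);
  for (int r = 0; r < n_rays; ++r) {
    double u = (n_rays == 1) ? 0.0 : (double)r / (double)(n_rays - 1);
    double cosang = 1.0 - u * (1.0 - std::cos(half));
    double sinang = std::sqrt(std::max(0.0, 1.0 - cosang * cosang));
    double phi = golden * r;
    dirs[3 * r + 0] = sinang * std::cos(phi);
    dirs[3 * r + 1] = sinang * std::sin(phi);
    dirs[3 * r + 2] = cosang;
  }

  for (int f = 0; f < nf; ++f) {
    double axis[3] = {-normals(f, 0), -normals(f, 1), -normals(f, 2)};
    // orthonormal frame around axis
    double ref[3] = {1.0, 0.0, 0.0};
    if (std::fabs(axis[0]) > 0.9) { ref[0] = 0.0; ref[1] = 1.0; }
    double t1[3], t2[3];
    cross3(axis, ref, t1);
    double n1 = std::sqrt(dot3(t1, t1));
    for (int c = 0; c < 3; ++c) t1[c] /= n1;
    cross3(axis, t1, t2);
    double orig[3] = {centroids(f, 0), centroids(f, 1), centroids(f, 2)};

    for (int r = 0; r < n_rays; ++r) {
      double d[3];
      for (int c = 0; c < 3; ++c)
        d[c] = dirs[3 * r + 0] * t1[c] + dirs[3 * r + 1] * t2[c] +
               dirs[3 * r + 2] * axis[c];
      double best = R_PosInf;
      for (int g = 0; g < nf; ++g) {
        if (g == f) continue;
        const double* a = &A[3 * g];
        const double* e1 = &E1[3 * g];
        const double* e2 = &E2[3 * g];
        double p[3];
        cross3(d, e2, p);
        double det = dot3(e1, p);
        if (std::fabs(det) < 1e-14) continue;
        double inv = 1.0 / det;
        double tv[3] = {orig[0] - a[0], orig[1] - a[1], orig[2] - a[2]};
        double u = dot3(tv, p) * inv;
        if (u < -1e-9 || u > 1.0 + 1e-9) continue;
        double q[3];
        cross3(tv, e1, q);
        double v = dot3(d, q) * inv;
        if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
        double t = dot3(e2, q) * inv;
        if (t > eps && t < best) best = t;
      }
      // normalize the chord by the ray's tilt from the inward normal: on a
      // sphere every normalized chord equals the diameter exactly
      if (R_finite(best)) hits(f, r) = best / dirs[3 * r + 2];
    }
  }
  return hits;
}
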