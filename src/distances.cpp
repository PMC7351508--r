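#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Squared distance helper
static inline double sq(double x) { return x * x; }

// Closest point on triangle (a,b,c) to point p (Ericson, Real-Time
// Collision Detection, ch. 5). Writes the closest point into out[3].
static void closest_point_triangle(const double *p, const double *a,
                                   const double *b, const double *c,
                                   double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }

  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }

  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

// Unsigned distance from each point to the nearest point on the
// triangulated surface (exhaustive over triangles).
// points: n x 3, verts: nv x 3, faces: nf x 3 (1-based indices).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix points,
                                      NumericMatrix verts,
                                      IntegerMatrix faces) {
  int n = points.nrow(), nf = faces.nrow();
  NumericVector out(n);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int k = 0; k < 3; ++k) V[3*i + k] = verts(i, k);

  for (int i = 0; i < n; ++i) {
    double p[3] = { points(i,0), points(i,1), points(i,2) };
    double best = R_PosInf;
    double cp[3];
    for (int f = 0; f < nf; ++f) {
      const double *a = &V[3*(faces(f,0) - 1)];
      const double *b = &V[3*(faces(f,1) - 1)];
      const double *c = &V[3*(faces(f,2) - 1)];
      closest_point_triangle(p, a, b, c, cp);
      double d2 = sq(cp[0]-p[0]) + sq(cp[1]-p[1]) + sq(cp[2]-p[2]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Generalized winding number of a closed mesh at each query point,
// via the van Oosterom-Strackee solid-angle formula summed over
// triangles.  ~1 inside, ~0 outside.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix points,
                                 NumericMatrix verts,
                                 IntegerMatrix faces) {
  int n = points.nrow(), nf = faces.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = points(i,0), py = points(i,1), pz = points(i,2);
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
      double ax = verts(faces(f,0)-1, 0) - px;
      double ay = verts(faces(f,0)-1, 1) - py;
      double az = verts(faces(f,0)-1, 2) - pz;
      double bx = verts(faces(f,1)-1, 0) - px;
      double by = verts(faces(f,1)-1, 1) - py;
      double bz = verts(faces(f,1)-1, 2) - pz;
      double cx = verts(faces(f,2)-1, 0) - px;
      double cy = verts(faces(f,2)-1, 1) - py;
      double cz = verts(faces(f,2)-1, 2) - pz;
      double la = std::sqrt(ax*ax + ay*ay + az*az);
      double lb = std::sqrt(bx*bx + by*by + bz*bz);
      double lc = std::sqrt(cx*cx + cy*cy + cz*cz);
      double det = ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx);
      double denom = la*lb*lc + (ax*bx + ay*by + az*bz)*lc +
                     (ax*cx + ay*cy + az*cz)*lb + (bx*cx + by*cy + bz*cz)*la;
      total += 2.0 * std::atan2(det, denom);
    }
    out[i] = total / (4.0 * M_PI);
  }
  return out;
}

// Brute-force k-nearest neighbours of each query row among ref rows.
// Returns list(index: n x k 1-based, dist: n x k).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  int n = query.nrow(), m = ref.nrow();
  if (k > m) k = m;
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<std::pair<double,int> > cand(m);
  for (int i = 0; i < n; ++i) {
    double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    for (int j = 0; j < m; ++j) {
      double d2 = sq(ref(j,0)-qx) + sq(ref(j,1)-qy) + sq(ref(j,2)-qz);
      cand[j] = std::make_pair(d2, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = cand[j].second + 1;
      dst(i, j) = std::sqrt(cand[j].first);
    }
  }
  return List::create(Named("index") = idx, Named("dist") = dst);
}
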