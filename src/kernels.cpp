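#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quaternion convention throughout: q = (w, x, y, z), Hamilton product,
// q maps sensor-frame vectors into the earth frame: v_e = q (0,v_s) q*.

static inline void quat_mult(const double *a, const double *b, double *out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void quat_normalize(double *q) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  if (n > 0) { q[0] /= n; q[1] /= n; q[2] /= n; q[3] /= n; }
}

// Gradient-descent (Madgwick-class) attitude filter, IMU variant.
// accel: n x 3 (any consistent unit, only the direction is used),
// gyro: n x 3 in rad/s, q0: initial quaternion, beta: filter gain.
// Returns n x 4 quaternion trajectory (sensor -> earth).
// [[Rcpp::export]]
NumericMatrix madgwick_filter(NumericMatrix accel, NumericMatrix gyro,
                              double dt, double beta, NumericVector q0) {
  int n = accel.nrow();
  NumericMatrix out(n, 4);
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  quat_normalize(q);
  for (int i = 0; i < n; i++) {
    double w[4] = {0.0, gyro(i, 0), gyro(i, 1), gyro(i, 2)};
    double qdot[4];
    quat_mult(q, w, qdot);
    for (int j = 0; j < 4; j++) qdot[j] *= 0.5;

    double ax = accel(i, 0), ay = accel(i, 1), az = accel(i, 2);
    double an = std::sqrt(ax*ax + ay*ay + az*az);
    if (an > 0) {
      ax /= an; ay /= an; az /= an;
      // objective: estimated gravity direction in the sensor frame,
      // R(q)^T (0,0,1), minus the normalised accelerometer reading
      double f1 = 2.0*(q[1]*q[3] - q[0]*q[2]) - ax;
      double f2 = 2.0*(q[2]*q[3] + q[0]*q[1]) - ay;
      double f3 = q[0]*q[0] - q[1]*q[1] - q[2]*q[2] + q[3]*q[3] - az;
      double s[4];
      s[0] = -2.0*q[2]*f1 + 2.0*q[1]*f2 + 2.0*q[0]*f3;
      s[1] =  2.0*q[3]*f1 + 2.0*q[0]*f2 - 2.0*q[1]*f3;
      s[2] = -2.0*q[0]*f1 + 2.0*q[3]*f2 - 2.0*q[2]*f3;
      s[3] =  2.0*q[1]*f1 + 2.0*q[2]*f2 + 2.0*q[3]*f3;
      double sn = std::sqrt(s[0]*s[0] + s[1]*s[1] + s[2]*s[2] + s[3]*s[3]);
      if (sn > 0) for (int j = 0; j < 4; j++) qdot[j] -= beta * s[j] / sn;
    }
    for (int j = 0; j < 4; j++) q[j] += qdot[j] * dt;
    quat_normalize(q);
    for (int j = 0; j < 4; j++) out(i, j) = q[j];
  }
  return out;
}

// Rotate row vectors v (n x 3, sensor frame) into the earth frame using
// the per-sample quaternions q (n x 4).
// [[Rcpp::export]]
NumericMatrix quat_rotate(NumericMatrix q, NumericMatrix v) {
  int n = v.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double w = q(i,0), x = q(i,1), y = q(i,2), z = q(i,3);
    double vx = v(i,0), vy = v(i,1), vz = v(i,2);
    // v_e = R(q) v_s, R from unit quaternion
    out(i,0) = (1 - 2*(y*y + z*z))*vx + 2*(x*y - w*z)*vy + 2*(x*z + w*y)*vz;
    out(i,1) = 2*(x*y + w*z)*vx + (1 - 2*(x*x + z*z))*vy + 2*(y*z - w*x)*vz;
    out(i,2) = 2*(x*z - w*y)*vx + 2*(y*z + w*x)*vy + (1 - 2*(x*x + y*y))*vz;
  }
  return out;
}

//' Sample entropy of a series
//'
//' Chebyshev distance, template length \code{m}, tolerance \code{r};
//' self-matches excluded. Returns \code{-log(A/B)}, or \code{NA} when no
//' template pair matches.
//'
//' @param x numeric series.
//' @param m template length.
//' @param r matching tolerance, in the units of \code{x}.
//' @return sample entropy (nat).
//' @export
// [[Rcpp::export]]
double sample_entropy(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  long long B = 0, A = 0;
  for (int i = 0; i < n - m; i++) {
    for (int j = i + 1; j < n - m; j++) {
      double d = 0.0;
      for (int k = 0; k < m; k++) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        B++;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (dd > d) d = dd;
        if (d <= r) A++;
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

//' Approximate entropy of a series
//'
//' Pincus' statistic \code{phi(m) - phi(m+1)} with self-matches included,
//' Chebyshev distance.
//'
//' @inheritParams sample_entropy
//' @return approximate entropy (nat).
//' @export
// [[Rcpp::export]]
double approx_entropy(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  double phi[2];
  for (int p = 0; p < 2; p++) {
    int mm = m + p;
    int nm = n - mm + 1;
    double s = 0.0;
    for (int i = 0; i < nm; i++) {
      int cnt = 0;
      for (int j = 0; j < nm; j++) {
        double d = 0.0;
        for (int k = 0; k < mm; k++) {
          double dd = std::fabs(x[i + k] - x[j + k]);
          if (dd > d) d = dd;
        }
        if (d <= r) cnt++;
      }
      s += std::log((double)cnt / (double)nm);
    }
    phi[p] = s / nm;
  }
  return phi[0] - phi[1];
}

// Rosenstein nearest-neighbour divergence curve for the largest Lyapunov
// exponent. x is delay-embedded with dimension dim and delay tau; for each
// reference point the nearest neighbour with temporal separation > min_sep
// is found, and the mean log Euclidean distance is tracked over k = 0..K.
// Returns the mean log-divergence curve (length K+1); the caller fits the
// slope. Pairs that run off the end of the series are dropped per step.
// [[Rcpp::export]]
NumericVector lyap_divergence(NumericVector x, int dim, int tau,
                              int min_sep, int K) {
  int n = x.size();
  int ne = n - (dim - 1) * tau;   // number of embedded points
  if (ne <= min_sep + 1) return NumericVector(0);
  std::vector<int> nn(ne, -1);
  for (int i = 0; i < ne; i++) {
    double best = R_PosInf;
    for (int j = 0; j < ne; j++) {
      if (std::abs(i - j) <= min_sep) continue;
      double d = 0.0;
      for (int k = 0; k < dim; k++) {
        double dd = x[i + k * tau] - x[j + k * tau];
        d += dd * dd;
        if (d >= best) break;
      }
      if (d < best) { best = d; nn[i] = j; }
    }
  }
  NumericVector curve(K + 1, NA_REAL);
  for (int k = 0; k <= K; k++) {
    double s = 0.0; int cnt = 0;
    for (int i = 0; i < ne; i++) {
      int j = nn[i];
      if (j < 0 || i + k >= ne || j + k >= ne) continue;
      double d = 0.0;
      for (int m2 = 0; m2 < dim; m2++) {
        double dd = x[i + k + m2 * tau] - x[j + k + m2 * tau];
        d += dd * dd;
      }
      if (d > 0) { s += 0.5 * std::log(d); cnt++; }
    }
    if (cnt > 0) curve[k] = s / cnt;
  }
  return curve;
}
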