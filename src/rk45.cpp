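// Adaptive Dormand-Prince 5(4) integrator for the ten consumer-resource
// model variants.  The variant code and 12-slot parameter vector are fixed
// by pack_params()/variant_code() on the R side:
//   code: 0 LV, 1 LVV, 2 RM, 3 RMS, 4 LVV_LV, 5 RM_LV, 6 RM_LVV,
//         7 RMS_LV, 8 RMS_LVV, 9 RMS_RM
//   par:  r K g a l e m F z r_lin g_lin F_lin
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void deriv(int v, const double* p, double A, double Z,
                         double& dA, double& dZ) {
  const double r = p[0], K = p[1], g = p[2], a = p[3], l = p[4], e = p[5],
               m = p[6], F = p[7], z = p[8], rl = p[9], gl = p[10],
               Fl = p[11];
  switch (v) {
  case 0:  // LV
    dA = r * A - g * Z * A - l * A;
    dZ = e * g * Z * A - m * Z; break;
  case 1:  // LVV
    dA = r * A * (1.0 - A / K) - g * Z * A - l * A;
    dZ = e * g * Z * A - m * Z; break;
  case 2:  // RM
    dA = r * A * (1.0 - A / K) - g * Z * A / (A + a) - l * A;
    dZ = e * g * Z * A / (A + a) - m * Z; break;
  case 3:  // RMS
    dA = r * A * (1.0 - A / K) - g * Z * A / (A + a) - l * A + l * K;
    dZ = e * g * Z * A / (A + a) - m * Z - F * Z * Z / (Z * Z + z * z);
    break;
  case 4:  // LVV_LV
    dA = rl * A - g * Z * A - l * A;
    dZ = e * g * Z * A - m * Z; break;
  case 5:  // RM_LV
    dA = rl * A - gl * Z * A - l * A;
    dZ = e * gl * Z * A - m * Z; break;
  case 6:  // RM_LVV
    dA = r * A * (1.0 - A / K) - gl * Z * A - l * A;
    dZ = e * gl * Z * A - m * Z; break;
  case 7:  // RMS_LV
    dA = rl * A - gl * Z * A - l * A + l * K;
    dZ = e * gl * Z * A - m * Z - Fl * Z; break;
  case 8:  // RMS_LVV
    dA = r * A * (1.0 - A / K) - gl * Z * A - l * A + l * K;
    dZ = e * gl * Z * A - m * Z - Fl * Z; break;
  case 9:  // RMS_RM
    dA = r * A * (1.0 - A / K) - g * Z * A / (A + a) - l * A + l * K;
    dZ = e * g * Z * A / (A + a) - m * Z - Fl * Z; break;
  default:
    stop("unknown variant code");
  }
}

// Dormand-Prince coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export]]
NumericMatrix integrate_cr_cpp(int variant, NumericVector par,
                               NumericVector y0, NumericVector times,
                               double rtol = 1e-8, double atol = 1e-10,
                               double hmax = 1.0) {
  const int nout = times.size();
  if (y0.size() != 2) stop("y0 must have length 2");
  if (par.size() != 12) stop("par must have length 12");
  NumericMatrix out(nout, 2);
  double p[12];
  for (int i = 0; i < 12; ++i) p[i] = par[i];

  double t = times[0];
  double A = y0[0], Z = y0[1];
  out(0, 0) = A; out(0, 1) = Z;
  double k1A, k1Z;
  deriv(variant, p, A, Z, k1A, k1Z);
  double h = 1e-4;

  for (int i = 1; i < nout; ++i) {
    const double tend = times[i];
    int iter = 0;
    while (t < tend) {
      if (++iter > 100000000) stop("step-count limit exceeded");
      if (h > hmax) h = hmax;
      if (t + h > tend) h = tend - t;
      // stages (FSAL: k1 carried over)
      double k2A, k2Z, k3A, k3Z, k4A, k4Z, k5A, k5Z, k6A, k6Z, k7A, k7Z;
      deriv(variant, p, A + h * a21 * k1A, Z + h * a21 * k1Z, k2A, k2Z);
      deriv(variant, p, A + h * (a31 * k1A + a32 * k2A),
                        Z + h * (a31 * k1Z + a32 * k2Z), k3A, k3Z);
      deriv(variant, p, A + h * (a41 * k1A + a42 * k2A + a43 * k3A),
                        Z + h * (a41 * k1Z + a42 * k2Z + a43 * k3Z),
            k4A, k4Z);
      deriv(variant, p,
            A + h * (a51 * k1A + a52 * k2A + a53 * k3A + a54 * k4A),
            Z + h * (a51 * k1Z + a52 * k2Z + a53 * k3Z + a54 * k4Z),
            k5A, k5Z);
      deriv(variant, p,
            A + h * (a61 * k1A + a62 * k2A + a63 * k3A + a64 * k4A +
                     a65 * k5A),
            Z + h * (a61 * k1Z + a62 * k2Z + a63 * k3Z + a64 * k4Z +
                     a65 * k5Z),
            k6A, k6Z);
      const double yA = A + h * (b1 * k1A + b3 * k3A + b4 * k4A + b5 * k5A +
                                 b6 * k6A);
      const double yZ = Z + h * (b1 * k1Z + b3 * k3Z + b4 * k4Z + b5 * k5Z +
                                 b6 * k6Z);
      deriv(variant, p, yA, yZ, k7A, k7Z);
      const double errA = h * (e1 * k1A + e3 * k3A + e4 * k4A + e5 * k5A +
                               e6 * k6A + e7 * k7A);
      const double errZ = h * (e1 * k1Z + e3 * k3Z + e4 * k4Z + e5 * k5Z +
                               e6 * k6Z + e7 * k7Z);
      const double scA = atol + rtol * std::max(std::fabs(A), std::fabs(yA));
      const double scZ = atol + rtol * std::max(std::fabs(Z), std::fabs(yZ));
      const double err = std::sqrt(0.5 * ((errA / scA) * (errA / scA) +
                                          (errZ / scZ) * (errZ / scZ)));
      if (err <= 1.0) {
        t += h;
        A = yA; Z = yZ;
        k1A = k7A; k1Z = k7Z;  // first-same-as-last
        double fac = (err == 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
        if (fac > 5.0) fac = 5.0;
        h *= fac;
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        if (fac < 0.1) fac = 0.1;
        h *= fac;
        if (h < 1e-14) stop("step size underflow (stiff point?)");
      }
      if (!std::isfinite(A) || !std::isfinite(Z))
        stop("non-finite state during integration");
    }
    out(i, 0) = A; out(i, 1) = Z;
  }
  return out;
}
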