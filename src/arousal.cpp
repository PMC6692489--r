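#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Solve z = z_pred + v * (s - sigmoid(alpha + z)) for z.
// The map is monotone (g(z) = z - z_pred - v*(s - p(z)) has g' >= 1), so the
// root is unique; Newton from z_pred with a bracketed bisection fallback.
static double solve_update(double z_pred, double v, double alpha, double s,
                           bool &ok) {
  ok = true;
  if (v == 0.0) return z_pred;
  double z = z_pred;
  for (int it = 0; it < 50; ++it) {
    double p = sigmoid(alpha + z);
    double g = z - z_pred - v * (s - p);
    double gp = 1.0 + v * p * (1.0 - p);
    double dz = g / gp;
    z -= dz;
    if (std::fabs(dz) < 1e-10) return z;
  }
  // bisection fallback on the monotone g
  double b = v * std::fabs(s - sigmoid(alpha + z_pred)) + 1.0;
  double lo = z_pred - b, hi = z_pred + b;
  double glo = lo - z_pred - v * (s - sigmoid(alpha + lo));
  double ghi = hi - z_pred - v * (s - sigmoid(alpha + hi));
  if (glo > 0 || ghi < 0) { ok = false; return z; }
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double gm = mid - z_pred - v * (s - sigmoid(alpha + mid));
    if (gm <= 0) lo = mid; else hi = mid;
    if (hi - lo < 1e-12) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List cpp_forward_filter(IntegerVector s, double alpha, double sigma_eps2,
                        double z0, double var0) {
  int J = s.size();
  NumericVector z_pred(J), var_pred(J), z_filt(J), var_filt(J);
  double zp = z0, vp = var0;
  for (int j = 0; j < J; ++j) {
    double zpr = zp;
    double vpr = vp + sigma_eps2;
    bool ok = true;
    double z = solve_update(zpr, vpr, alpha, (double)s[j], ok);
    if (!ok) stop("filter update failed to converge at bin %d", j + 1);
    double p = sigmoid(alpha + z);
    double v = (vpr == 0.0) ? 0.0 : 1.0 / (1.0 / vpr + p * (1.0 - p));
    z_pred[j] = zpr; var_pred[j] = vpr; z_filt[j] = z; var_filt[j] = v;
    zp = z; vp = v;
  }
  return List::create(_["z_pred"] = z_pred, _["var_pred"] = var_pred,
                      _["z_filt"] = z_filt, _["var_filt"] = var_filt);
}

// [[Rcpp::export]]
List cpp_backward_smooth(NumericVector z_pred, NumericVector var_pred,
                         NumericVector z_filt, NumericVector var_filt) {
  int J = z_filt.size();
  NumericVector z_s(J), v_s(J), gain(J);
  z_s[J - 1] = z_filt[J - 1];
  v_s[J - 1] = var_filt[J - 1];
  gain[J - 1] = NA_REAL;
  for (int j = J - 2; j >= 0; --j) {
    double A = (var_pred[j + 1] == 0.0) ? 0.0 : var_filt[j] / var_pred[j + 1];
    gain[j] = A;
    z_s[j] = z_filt[j] + A * (z_s[j + 1] - z_pred[j + 1]);
    v_s[j] = var_filt[j] + A * A * (v_s[j + 1] - var_pred[j + 1]);
  }
  return List::create(_["z_smooth"] = z_s, _["var_smooth"] = v_s,
                      _["gain"] = gain);
}
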