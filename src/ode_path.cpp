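#include <Rcpp.h>
using namespace Rcpp;

// Closed-form propagation of the linear reporter system
//   dM/dt = tau(t) - dM * M,   dP/dt = alpha * M - dP * P
// where tau(t) is piecewise constant on the intervals defined by
// switch_times (strictly increasing, within [0, t_end]).  On a segment
// with constant tau the solution is
//   M(t)  = tau/dM + B e^{-dM d},                    B = M0 - tau/dM
//   P(t)  = Pss + A e^{-dM d} + C e^{-dP d},         dM != dP
//   P(t)  = Pss + alpha B d e^{-dM d} + C e^{-dM d}, dM == dP
// with Pss = alpha tau/(dM dP), A = alpha B/(dP - dM), d = t - t_seg.
// Evaluation times must be sorted ascending and lie within [0, t_end].

// [[Rcpp::export]]
NumericVector protein_path_cpp(NumericVector switch_times, int initial_on,
                               double rate_off, double rate_on,
                               double alpha, double dM, double dP,
                               double M0, double P0,
                               NumericVector times, double t_end) {
  const int k = switch_times.size(), n = times.size();
  NumericVector out(n);
  double t0 = 0.0, M = M0, P = P0;
  int state = initial_on;
  int ti = 0;
  const double eps = 1e-12;
  const bool deg = std::fabs(dM - dP) < 1e-8;
  for (int seg = 0; seg <= k; ++seg) {
    const double t1 = (seg < k) ? switch_times[seg] : t_end;
    const double tau = state ? rate_on : rate_off;
    const double Ms = tau / dM;
    const double B = M - Ms;
    const double Pss = alpha * tau / (dM * dP);
    const double A = deg ? 0.0 : alpha * B / (dP - dM);
    const double C = deg ? (P - Pss) : (P - Pss - A);
    while (ti < n && times[ti] <= t1 + eps) {
      double d = times[ti] - t0;
      if (d < 0) d = 0;
      const double eM = std::exp(-dM * d);
      if (deg) {
        out[ti] = Pss + alpha * B * d * eM + C * eM;
      } else {
        const double eP = std::exp(-dP * d);
        out[ti] = Pss + A * eM + C * eP;
      }
      ++ti;
    }
    if (ti >= n && seg == k) break;
    const double d = t1 - t0;
    const double eM = std::exp(-dM * d);
    const double eP = std::exp(-dP * d);
    const double Mnew = Ms + B * eM;
    const double Pnew = deg ? (Pss + alpha * B * d * eM + C * eM)
                            : (Pss + A * eM + C * eP);
    M = Mnew;
    P = Pnew;
    t0 = t1;
    state = 1 - state;
  }
  return out;
}

// mRNA profile along the same piecewise-constant transcription path.

// [[Rcpp::export]]
NumericVector mrna_path_cpp(NumericVector switch_times, int initial_on,
                            double rate_off, double rate_on,
                            double dM, double M0,
                            NumericVector times, double t_end) {
  const int k = switch_times.size(), n = times.size();
  NumericVector out(n);
  double t0 = 0.0, M = M0;
  int state = initial_on;
  int ti = 0;
  const double eps = 1e-12;
  for (int seg = 0; seg <= k; ++seg) {
    const double t1 = (seg < k) ? switch_times[seg] : t_end;
    const double tau = state ? rate_on : rate_off;
    const double Ms = tau / dM;
    const double B = M - Ms;
    while (ti < n && times[ti] <= t1 + eps) {
      double d = times[ti] - t0;
      if (d < 0) d = 0;
      out[ti] = Ms + B * std::exp(-dM * d);
      ++ti;
    }
    if (ti >= n && seg == k) break;
    M = Ms + B * std::exp(-dM * (t1 - t0));
    t0 = t1;
    state = 1 - state;
  }
  return out;
}

// Gaussian log-likelihood of observations y at times `times` under the
// deterministic protein path; avoids allocating in the R-level MCMC loop.

// [[Rcpp::export]]
double switch_loglik_cpp(NumericVector y, NumericVector times,
                         NumericVector switch_times, int initial_on,
                         double rate_off, double rate_on,
                         double alpha, double dM, double dP,
                         double M0, double P0, double sigma, double t_end) {
  NumericVector mu = protein_path_cpp(switch_times, initial_on, rate_off,
                                      rate_on, alpha, dM, dP, M0, P0,
                                      times, t_end);
  const int n = y.size();
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    const double r = y[i] - mu[i];
    ss += r * r;
  }
  return -0.5 * n * std::log(2.0 * M_PI) - n * std::log(sigma) -
         0.5 * ss / (sigma * sigma);
}
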