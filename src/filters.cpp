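#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase filtering of each column of X by a cascade of biquad sections.
// sos is K x 6 (b0 b1 b2 a0 a1 a2).  Each section is run forward then
// backward with zero initial conditions; callers are expected to zero-pad
// the series so that start-up transients die out inside the padding.
// [[Rcpp::export]]
NumericMatrix sos_filtfilt_cols(NumericMatrix sos, NumericMatrix X) {
  int K = sos.nrow(), T = X.nrow(), n = X.ncol();
  NumericMatrix Y(clone(X));
  double *yp = REAL(Y);
  for (int j = 0; j < n; ++j) {
    double *col = yp + (R_xlen_t)j * T;
    for (int k = 0; k < K; ++k) {
      const double a0 = sos(k, 3);
      const double b0 = sos(k, 0) / a0, b1 = sos(k, 1) / a0,
                   b2 = sos(k, 2) / a0;
      const double a1 = sos(k, 4) / a0, a2 = sos(k, 5) / a0;
      double z1 = 0.0, z2 = 0.0;
      for (int t = 0; t < T; ++t) {           // forward pass
        const double x = col[t];
        const double y = b0 * x + z1;
        z1 = b1 * x - a1 * y + z2;
        z2 = b2 * x - a2 * y;
        col[t] = y;
      }
      z1 = z2 = 0.0;
      for (int t = T - 1; t >= 0; --t) {      // backward pass
        const double x = col[t];
        const double y = b0 * x + z1;
        z1 = b1 * x - a1 * y + z2;
        z2 = b2 * x - a2 * y;
        col[t] = y;
      }
    }
  }
  return Y;
}

// First-order leaky integrator, exponential-Euler update, applied to each
// column of X (columns are neurons, rows are samples): y[t] = e*y[t-1] +
// (1-e)*x[t] with e = exp(-dt/tau) and y[0] built from y_init = 0.
// [[Rcpp::export]]
NumericMatrix leaky_integrate_cols(NumericMatrix X, double decay) {
  int T = X.nrow(), n = X.ncol();
  double gain = 1.0 - decay;
  NumericMatrix Y(T, n);
  for (int j = 0; j < n; ++j) {
    double y = 0.0;
    for (int t = 0; t < T; ++t) {
      y = decay * y + gain * X(t, j);
      Y(t, j) = y;
    }
  }
  return Y;
}
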