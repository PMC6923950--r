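#include <Rcpp.h>
#include <cmath>

// Three-state metabolic growth model of the diauxic shift.
//
// State order:      y = (m_g, g, m_e, e, m_q)
// Parameter order:  p = (mu1, mu2, beta1, K, beta2, beta3, gamma1, gamma2, gamma3)
//
// The glucose->ethanol switching term is beta1 * m_g / (g + K): negligible
// while glucose is abundant, ramping up to rate beta1/K once g is depleted.

static inline void microenv_deriv(const double *y, const double *p, double *dy) {
  const double mg = y[0], g = y[1], me = y[2], e = y[3];
  const double mu1 = p[0], mu2 = p[1], beta1 = p[2], K = p[3];
  const double beta2 = p[4], beta3 = p[5];
  const double g1 = p[6], g2 = p[7], g3 = p[8];

  const double grow_g = mu1 * mg * g;        // growth on glucose
  const double sw = beta1 * mg / (g + K);    // switch to ethanol state
  const double grow_e = mu2 * me * e;        // growth on ethanol

  dy[0] = grow_g - sw - beta2 * mg;          // d m_g
  dy[1] = -grow_g / g1;                      // d g
  dy[2] = grow_e + sw - beta3 * me;          // d m_e
  dy[3] = grow_g / g2 - grow_e / g3;         // d e
  dy[4] = beta2 * mg + beta3 * me;           // d m_q
}

// Dormand-Prince 5(4) adaptive step integrator with FSAL.  Steps never
// straddle requested output times, so no dense-output interpolation is
// needed.  Returns status 0 on success; on failure the rows from the last
// valid output time onward are left NA and t_fail reports where it stopped.

// [[Rcpp::export]]
Rcpp::List microenv_solve_cpp(Rcpp::NumericVector y0,
                              Rcpp::NumericVector times,
                              Rcpp::NumericVector pars,
                              double rtol = 1e-8,
                              double atol = 1e-10,
                              int max_steps = 2000000,
                              double neg_tol = 1e-9) {
  const int d = 5;
  if (y0.size() != d) Rcpp::stop("y0 must have length 5");
  if (pars.size() != 9) Rcpp::stop("pars must have length 9");
  const int nt = times.size();
  Rcpp::NumericMatrix out(nt, d);
  std::fill(out.begin(), out.end(), NA_REAL);

  double y[d], ynew[d], yerr[d], k1[d], kw[6][d], ytmp[d];
  for (int i = 0; i < d; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }

  // abort threshold for negative undershoots, relative to initial content
  double content0 = 0.0;
  for (int i = 0; i < d; ++i) content0 += std::fabs(y0[i]);
  const double neg_abort = neg_tol * std::max(1.0, content0);

  // Butcher tableau (Dormand-Prince)
  const double a21 = 1.0/5;
  const double a31 = 3.0/40, a32 = 9.0/40;
  const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
  const double a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
               a54 = -212.0/729;
  const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
               a64 = 49.0/176, a65 = -5103.0/18656;
  const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
               b5 = -2187.0/6784, b6 = 11.0/84;
  const double e1 = 35.0/384 - 5179.0/57600, e3 = 500.0/1113 - 7571.0/16695,
               e4 = 125.0/192 - 393.0/640, e5 = -2187.0/6784 + 92097.0/339200,
               e6 = 11.0/84 - 187.0/2100, e7 = -1.0/40;

  double t = times[0];
  double h = 1e-3;
  long steps = 0;
  int status = 0;
  double t_fail = t;
  bool have_k1 = false;

  for (int seg = 1; seg < nt && status == 0; ++seg) {
    const double t_end = times[seg];
    if (!(t_end > t)) { status = 2; t_fail = t; break; }
    while (t < t_end) {
      if (++steps > max_steps) { status = 1; t_fail = t; break; }
      if (h > t_end - t) h = t_end - t;
      if (h < 1e-12) { h = 1e-12; }
      if (!have_k1) { microenv_deriv(y, pars.begin(), k1); have_k1 = true; }

      for (int i = 0; i < d; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      microenv_deriv(ytmp, pars.begin(), kw[0]);
      for (int i = 0; i < d; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * kw[0][i]);
      microenv_deriv(ytmp, pars.begin(), kw[1]);
      for (int i = 0; i < d; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * kw[0][i] + a43 * kw[1][i]);
      microenv_deriv(ytmp, pars.begin(), kw[2]);
      for (int i = 0; i < d; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * kw[0][i] + a53 * kw[1][i] +
                              a54 * kw[2][i]);
      microenv_deriv(ytmp, pars.begin(), kw[3]);
      for (int i = 0; i < d; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * kw[0][i] + a63 * kw[1][i] +
                              a64 * kw[2][i] + a65 * kw[3][i]);
      microenv_deriv(ytmp, pars.begin(), kw[4]);
      for (int i = 0; i < d; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * kw[1][i] + b4 * kw[2][i] +
                              b5 * kw[3][i] + b6 * kw[4][i]);
      microenv_deriv(ynew, pars.begin(), kw[5]);

      double errnorm = 0.0;
      bool finite = true;
      for (int i = 0; i < d; ++i) {
        yerr[i] = h * (e1 * k1[i] + e3 * kw[1][i] + e4 * kw[2][i] +
                       e5 * kw[3][i] + e6 * kw[4][i] + e7 * kw[5][i]);
        if (!std::isfinite(ynew[i])) finite = false;
        const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        const double r = yerr[i] / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / d);

      if (!finite) { status = 3; t_fail = t; break; }

      if (errnorm <= 1.0) {
        t += h;
        bool neg_bad = false;
        for (int i = 0; i < d; ++i) {
          double v = ynew[i];
          if (v < 0.0) {
            if (v <= -neg_abort) { neg_bad = true; break; }
            v = 0.0;
          }
          y[i] = v;
        }
        if (neg_bad) { status = 4; t_fail = t; break; }
        // FSAL: reuse last stage unless a clamp modified the state
        for (int i = 0; i < d; ++i) k1[i] = kw[5][i];
        have_k1 = true;
      } else {
        have_k1 = true; // k1 still valid at unchanged y
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h < 1e-12) { status = 5; t_fail = t; break; }
    }
    if (status == 0)
      for (int i = 0; i < d; ++i) out(seg, i) = y[i];
  }

  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("status") = status,
                            Rcpp::Named("t_fail") = t_fail,
                            Rcpp::Named("n_steps") = (double)steps);
}
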