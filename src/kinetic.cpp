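#include <Rcpp.h>
using namespace Rcpp;

// Nonlocal conversion rates on the grid.  The stimulating integrals are
// right/left cumulative sums including half of the focal cell (midpoint
// rule); the inhibitory base N - S is clamped below at 1, the density
// counterpart of the microscopic convention that the focal individual is
// always counted in its own inhibitory pool.
static void nonlocal_rates_core(const std::vector<double>& A,
                                const std::vector<double>& I, double dx,
                                double Nmass, double mu_A, double mu_I,
                                double alpha_A, double beta_A, double gamma_A,
                                double alpha_I, double beta_I, double gamma_I,
                                std::vector<double>& KA,
                                std::vector<double>& KI) {
  const int nx = A.size();
  const bool linA = (beta_A == 1.0), noinhA = (gamma_A == 0.0);
  const bool linI = (beta_I == 1.0), noinhI = (gamma_I == 0.0);
  double tail = 0.0;
  for (int i = nx - 1; i >= 0; --i) {
    double S = dx * (0.5 * A[i] + tail);
    if (S < 0) S = 0;
    double stim = linA ? S : std::pow(S, beta_A);
    double inh = 1.0;
    if (!noinhA) inh = std::pow(std::max(Nmass - S, 1.0), -gamma_A);
    KA[i] = mu_A + alpha_A * stim * inh;
    tail += A[i];
  }
  double head = 0.0;
  for (int i = 0; i < nx; ++i) {
    double S = dx * (0.5 * I[i] + head);
    if (S < 0) S = 0;
    double stim = linI ? S : std::pow(S, beta_I);
    double inh = 1.0;
    if (!noinhI) inh = std::pow(std::max(Nmass - S, 1.0), -gamma_I);
    KI[i] = mu_I + alpha_I * stim * inh;
    head += I[i];
  }
}

//' @noRd
// [[Rcpp::export(name = ".nonlocal_rates_cpp")]]
List nonlocal_rates_cpp(NumericVector A, NumericVector I, double dx,
                        double Nmass, double mu_A, double mu_I,
                        double alpha_A, double beta_A, double gamma_A,
                        double alpha_I, double beta_I, double gamma_I) {
  std::vector<double> a(A.begin(), A.end()), ii(I.begin(), I.end());
  std::vector<double> KA(a.size()), KI(a.size());
  nonlocal_rates_core(a, ii, dx, Nmass, mu_A, mu_I, alpha_A, beta_A, gamma_A,
                      alpha_I, beta_I, gamma_I, KA, KI);
  return List::create(_["K_A"] = NumericVector(KA.begin(), KA.end()),
                      _["K_I"] = NumericVector(KI.begin(), KI.end()));
}

//' @noRd
// [[Rcpp::export(name = ".kinetic_run_cpp")]]
List kinetic_run_cpp(NumericVector A0, NumericVector I0, double dx, double dt,
                     int n_steps, int record_every, double v, double Nmass,
                     double mu_A, double mu_I, double alpha_A, double beta_A,
                     double gamma_A, double alpha_I, double beta_I,
                     double gamma_I) {
  const int nx = A0.size();
  if (v * dt > dx * (1.0 + 1e-12))
    stop("CFL condition violated: v*dt = %g exceeds dx = %g", v * dt, dx);

  std::vector<double> A(A0.begin(), A0.end()), I(I0.begin(), I0.end());
  std::vector<double> KA(nx), KI(nx), Anew(nx);

  const int nrec = n_steps / record_every + 1;
  NumericMatrix recA(nrec, nx), recI(nrec, nx);
  NumericVector rec_t(nrec);
  int irec = 0;
  for (int i = 0; i < nx; ++i) { recA(0, i) = A[i]; recI(0, i) = I[i]; }
  rec_t[0] = 0.0;
  irec = 1;

  const double c = v * dt / dx;

  for (int s = 1; s <= n_steps; ++s) {
    nonlocal_rates_core(A, I, dx, Nmass, mu_A, mu_I, alpha_A, beta_A,
                        gamma_A, alpha_I, beta_I, gamma_I, KA, KI);
    // conservative first-order upwind transport of A towards positive x,
    // zero flux through both domain ends
    for (int i = 0; i < nx; ++i) {
      double f_in = (i > 0) ? c * A[i - 1] : 0.0;
      double f_out = (i < nx - 1) ? c * A[i] : 0.0;
      Anew[i] = A[i] - f_out + f_in;
    }
    // reaction exchange, conserving A + I per node
    for (int i = 0; i < nx; ++i) {
      double ex = dt * (KA[i] * I[i] - KI[i] * A[i]);
      Anew[i] += ex;
      I[i] -= ex;
    }
    for (int i = 0; i < nx; ++i) {
      A[i] = Anew[i];
      if (!std::isfinite(A[i]) || !std::isfinite(I[i]))
        stop("non-finite density at step %d, node %d", s, i + 1);
    }
    if (s % record_every == 0 && irec < nrec) {
      for (int i = 0; i < nx; ++i) { recA(irec, i) = A[i]; recI(irec, i) = I[i]; }
      rec_t[irec] = s * dt;
      ++irec;
    }
  }

  return List::create(_["times"] = rec_t, _["A"] = recA, _["I"] = recI);
}
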