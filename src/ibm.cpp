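#include <Rcpp.h>
using namespace Rcpp;

// Double mimetic switching rates for one walker given its pooled counts.
// The inhibitory base counts the focal individual itself, so it is always
// >= 1 for a walker eligible to switch; the alternative convention
// (others only, floored at 1) is selectable.
static inline double stim_term(double count, double beta, double base,
                               double gamma) {
  // 0^0 == 1 in std::pow, which matches the convention needed for the
  // minimal model (gamma == 0 must disable inhibition even at base 0).
  return std::pow(count, beta) * std::pow(base, -gamma);
}

static inline double rate_activation(int a_plus, int N, double mu_A,
                                     double alpha_A, double beta_A,
                                     double gamma_A, bool focal_in_base) {
  double base = focal_in_base ? double(N - a_plus)
                              : std::max(1.0, double(N - 1 - a_plus));
  if (a_plus == 0 && beta_A > 0) return mu_A;
  return mu_A + alpha_A * stim_term(double(a_plus), beta_A, base, gamma_A);
}

static inline double rate_inactivation(int i_minus, int N, double mu_I,
                                       double alpha_I, double beta_I,
                                       double gamma_I, bool focal_in_base) {
  double base = focal_in_base ? double(N - i_minus)
                              : std::max(1.0, double(N - 1 - i_minus));
  if (i_minus == 0 && beta_I > 0) return mu_I;
  return mu_I + alpha_I * stim_term(double(i_minus), beta_I, base, gamma_I);
}

// "ahead" = strictly greater abscissa; exact ties broken by walker index
// (the lower index counts as behind).
static inline bool is_ahead(double xj, int j, double xf, int f) {
  if (xj > xf) return true;
  if (xj < xf) return false;
  return j > f;
}

static void all_rates(const std::vector<double>& x,
                      const std::vector<int>& mode, int N, double mu_A,
                      double mu_I, double alpha_A, double beta_A,
                      double gamma_A, double alpha_I, double beta_I,
                      double gamma_I, bool focal_in_base,
                      std::vector<double>& r) {
  for (int f = 0; f < N; ++f) {
    int a_plus = 0, i_minus = 0;
    for (int j = 0; j < N; ++j) {
      if (j == f) continue;
      bool ahead = is_ahead(x[j], j, x[f], f);
      if (mode[j] == 1 && ahead) ++a_plus;
      if (mode[j] == 0 && !ahead) ++i_minus;
    }
    r[f] = (mode[f] == 0)
               ? rate_activation(a_plus, N, mu_A, alpha_A, beta_A, gamma_A,
                                 focal_in_base)
               : rate_inactivation(i_minus, N, mu_I, alpha_I, beta_I,
                                   gamma_I, focal_in_base);
    if (!std::isfinite(r[f]) || r[f] < 0) {
      stop("non-finite or negative switching rate for walker %d "
           "(mode %d, position %g)", f + 1, mode[f], x[f]);
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".ibm_rates_cpp")]]
NumericVector ibm_rates_cpp(NumericVector x, IntegerVector mode, double mu_A,
                            double mu_I, double alpha_A, double beta_A,
                            double gamma_A, double alpha_I, double beta_I,
                            double gamma_I, bool focal_in_base) {
  int N = x.size();
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> ms(mode.begin(), mode.end());
  std::vector<double> r(N);
  all_rates(xs, ms, N, mu_A, mu_I, alpha_A, beta_A, gamma_A, alpha_I, beta_I,
            gamma_I, focal_in_base, r);
  return NumericVector(r.begin(), r.end());
}

//' @noRd
// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(NumericVector x0, IntegerVector mode0, double t_max,
                   double record_interval, double v, double mu_A, double mu_I,
                   double alpha_A, double beta_A, double gamma_A,
                   double alpha_I, double beta_I, double gamma_I,
                   bool focal_in_base) {
  const int N = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<int> mode(mode0.begin(), mode0.end());
  std::vector<double> r(N);

  const int nrec = int(std::floor(t_max / record_interval + 1e-9)) + 1;
  NumericVector times(nrec);
  NumericMatrix pos(nrec, N);
  IntegerMatrix mod(nrec, N);

  double t = 0.0;
  int irec = 0;
  // record initial state
  times[0] = 0.0;
  for (int j = 0; j < N; ++j) { pos(0, j) = x[j]; mod(0, j) = mode[j]; }
  irec = 1;

  long n_events = 0, n_cross = 0;

  while (t < t_max) {
    // a mover exactly at a stopped walker's abscissa (initial tie or an
    // overtaking instant just handled) is nudged strictly past it so the
    // behind/ahead partition is unambiguous on the open interval ahead
    if (v > 0) {
      for (int i = 0; i < N; ++i) {
        if (mode[i] != 1) continue;
        for (int j = 0; j < N; ++j) {
          if (mode[j] == 0 && std::abs(x[j] - x[i]) < 1e-12)
            x[i] = x[j] + 1e-9;
        }
      }
    }
    all_rates(x, mode, N, mu_A, mu_I, alpha_A, beta_A, gamma_A, alpha_I,
              beta_I, gamma_I, focal_in_base, r);
    double rtot = 0.0;
    for (int f = 0; f < N; ++f) rtot += r[f];

    double tau = (rtot > 0) ? exp_rand() / rtot : R_PosInf;

    // earliest overtaking instant: a mover reaching a stopped walker ahead
    double tc = R_PosInf;
    if (v > 0) {
      for (int i = 0; i < N; ++i) {
        if (mode[i] != 1) continue;
        for (int j = 0; j < N; ++j) {
          if (mode[j] != 0 || x[j] <= x[i]) continue;
          double dtc = (x[j] - x[i]) / v;
          if (dtc < tc) tc = dtc;
        }
      }
    }

    double dt_adv = std::min(tau, tc);
    double t_new = (std::isfinite(dt_adv)) ? t + dt_adv : t_max;
    bool truncated = false;
    if (t_new >= t_max) { t_new = t_max; truncated = true; }

    // record any sample instants passed while advancing
    while (irec < nrec && irec * record_interval <= t_new + 1e-12) {
      double ts = irec * record_interval;
      double dts = ts - t;
      times[irec] = ts;
      for (int j = 0; j < N; ++j) {
        pos(irec, j) = x[j] + (mode[j] == 1 ? v * dts : 0.0);
        mod(irec, j) = mode[j];
      }
      ++irec;
    }

    // advance movers
    double dts = t_new - t;
    for (int j = 0; j < N; ++j) if (mode[j] == 1) x[j] += v * dts;
    t = t_new;
    if (truncated) break;

    if (tc <= tau) {
      // overtaking instant: pools change, so rates are rebuilt and waiting
      // times redrawn on the next iteration (valid by memorylessness)
      ++n_cross;
    } else {
      // switching event: pick the walker in proportion to its rate
      double u = unif_rand() * rtot, acc = 0.0;
      int k = N - 1;
      for (int f = 0; f < N; ++f) {
        acc += r[f];
        if (u <= acc) { k = f; break; }
      }
      mode[k] = 1 - mode[k];
      ++n_events;
    }
  }

  return List::create(_["times"] = times, _["positions"] = pos,
                      _["modes"] = mod, _["n_switches"] = double(n_events),
                      _["n_crossings"] = double(n_cross));
}
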