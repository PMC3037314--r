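#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-deterministic simulation of the reduced dimensionless model:
//   dc/dt = m(t) + k_plus_eff - k_eff * c
// where m(t) is a telegraph process (0/1) switching 1->0 at rate alpha_t and
// 0->1 at rate beta_t (dimensionless time).  Between switches the flow is
// integrated in closed form, and the first two moments are accumulated as
// exact integrals of the exponential segments, so there is no ODE
// discretisation error anywhere.

// [[Rcpp::export(name = ".pdmp_core")]]
List pdmp_core(double alpha_t, double beta_t, double k_eff, double k_plus_eff,
               int m0, double c0, double t_burn, double t_end,
               double thin_dt) {
  int m = m0;
  double c = c0, t = 0.0;
  double Tacc = 0.0, int_c = 0.0, int_c2 = 0.0, occ = 0.0;
  double n_switch = 0.0;
  const bool do_thin = R_finite(thin_dt) && thin_dt > 0;
  std::vector<double> samp;
  double t_thin = t_burn;

  while (t < t_end) {
    double rate = m ? alpha_t : beta_t;
    double tau = (rate > 0) ? R::exp_rand() / rate : (t_end - t) + 1.0;
    bool final_seg = (t + tau >= t_end);
    double seg_end = final_seg ? t_end : t + tau;
    double cstar = (m + k_plus_eff) / k_eff;
    double dev = c - cstar;

    // stationary-window overlap [lo, hi] of this segment
    double lo = (t > t_burn) ? t : t_burn;
    if (seg_end > lo) {
      double u1 = lo - t, u2 = seg_end - t;
      double e1 = std::exp(-k_eff * u1), e2 = std::exp(-k_eff * u2);
      double w = u2 - u1;
      Tacc += w;
      occ += m * w;
      int_c += cstar * w + dev * (e1 - e2) / k_eff;
      int_c2 += cstar * cstar * w + 2.0 * cstar * dev * (e1 - e2) / k_eff +
                dev * dev * (e1 * e1 - e2 * e2) / (2.0 * k_eff);
    }
    if (do_thin) {
      while (t_thin < seg_end && t_thin <= t_end) {
        if (t_thin >= t)
          samp.push_back(cstar + dev * std::exp(-k_eff * (t_thin - t)));
        t_thin += thin_dt;
      }
    }

    c = cstar + dev * std::exp(-k_eff * (seg_end - t));
    if (!std::isfinite(c))
      stop("non-finite state at t=%g (m=%d, c*=%g)", seg_end, m, cstar);
    t = seg_end;
    if (final_seg) break;
    m = 1 - m;
    n_switch += 1.0;
    if (((long long)n_switch) % 4194304 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["T"] = Tacc, _["int_c"] = int_c, _["int_c2"] = int_c2,
                      _["occ"] = occ, _["samples"] = wrap(samp),
                      _["m_final"] = m, _["c_final"] = c,
                      _["n_switch"] = n_switch);
}
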