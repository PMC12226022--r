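#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Double-exponential kernel bookkeeping: value(t) = (a - b) / norm with
// a, b decaying with tau_decay, tau_rise; unit peak amplitude.
static inline double dexp_norm(double tau_rise, double tau_decay) {
  if (tau_decay <= tau_rise) stop("kernel decay must exceed rise");
  double tpk = std::log(tau_decay / tau_rise) * tau_rise * tau_decay /
               (tau_decay - tau_rise);
  return std::exp(-tpk / tau_decay) - std::exp(-tpk / tau_rise);
}

// Event-driven integrator for one synapse. Times in ms, voltages in mV,
// conductances in nS, calcium in uM, Ca* in uM*ms. Currents in pA
// (nS * mV); k_flux converts pA -> uM/ms (eta/(2FX) with unit bookkeeping
// done on the R side). rho integrated with forward Euler, the linear
// calcium equations with exponential Euler; Heaviside terms evaluated on
// the post-step Ca*.
// [[Rcpp::export]]
List cpp_simulate_synapse(NumericVector pre_ms, NumericVector post_ms,
                          double duration_ms, double dt, double report_dt_ms,
                          List par) {
  const double tau_rho_ms = as<double>(par["tau_rho_s"]) * 1000.0;
  const double rho_star = as<double>(par["rho_star"]);
  const double gamma_d = as<double>(par["gamma_d"]);
  const double gamma_p = as<double>(par["gamma_p"]);
  const double theta_d = as<double>(par["theta_d"]);
  const double theta_p = as<double>(par["theta_p"]);
  const bool plastic = (theta_d >= 0.0) && (theta_p >= 0.0);
  const double ca_rest = as<double>(par["ca_rest"]);
  const double tau_ca = as<double>(par["tau_ca"]);
  const double tau_star = as<double>(par["tau_star"]);
  const double k_flux = as<double>(par["k_flux"]);
  const double g_nmda_hat = as<double>(par["g_nmda_hat"]);
  const double nmda_rise = as<double>(par["nmda_rise"]);
  const double nmda_decay = as<double>(par["nmda_decay"]);
  const double e_nmda = as<double>(par["e_nmda"]);
  const double mg_ratio = as<double>(par["mg_out"]) / as<double>(par["mg_theta"]);
  const double mg_kappa = as<double>(par["mg_kappa"]);
  const double v_rest = as<double>(par["v_rest"]);
  const double epsp_amp = as<double>(par["epsp_amp"]);
  const double epsp_rise = as<double>(par["epsp_rise"]);
  const double epsp_decay = as<double>(par["epsp_decay"]);
  const double bap_amp = as<double>(par["bap_amp"]); // already attenuated
  const double bap_rise = as<double>(par["bap_rise"]);
  const double bap_decay = as<double>(par["bap_decay"]);
  const double vdcc_gain = as<double>(par["vdcc_gain"]); // already attenuated
  const double rho0 = as<double>(par["rho0"]);
  const double u_d = as<double>(par["u_d"]), u_p = as<double>(par["u_p"]);
  const double g_d = as<double>(par["g_d"]), g_p = as<double>(par["g_p"]);
  const double u0 = as<double>(par["u0"]), g0 = as<double>(par["g0"]);
  const double tau_change_ms = as<double>(par["tau_change_s"]) * 1000.0;

  if (dt <= 0) stop("dt must be positive");
  const int n_steps = (int)std::ceil(duration_ms / dt - 1e-9);
  const int rep_every = std::max(1, (int)std::lround(report_dt_ms / dt));
  const int n_rep = n_steps / rep_every;

  // decay multipliers per step
  const double d_nm_d = std::exp(-dt / nmda_decay), d_nm_r = std::exp(-dt / nmda_rise);
  const double d_ep_d = std::exp(-dt / epsp_decay), d_ep_r = std::exp(-dt / epsp_rise);
  const double d_bp_d = std::exp(-dt / bap_decay), d_bp_r = std::exp(-dt / bap_rise);
  const double d_ca = std::exp(-dt / tau_ca), d_star = std::exp(-dt / tau_star);
  const double d_uw = std::exp(-dt / tau_change_ms);
  const double nm_norm = dexp_norm(nmda_rise, nmda_decay);
  const double ep_norm = dexp_norm(epsp_rise, epsp_decay);
  const double bp_norm = dexp_norm(bap_rise, bap_decay);

  // event step indices (events applied at the start of their step)
  std::vector<int> pre_idx(pre_ms.size()), post_idx(post_ms.size());
  for (int i = 0; i < pre_ms.size(); ++i) {
    if (pre_ms[i] < 0 || pre_ms[i] > duration_ms + 1e-9)
      stop("presynaptic spike outside [0, duration]");
    pre_idx[i] = (int)std::lround(pre_ms[i] / dt);
  }
  for (int i = 0; i < post_ms.size(); ++i) {
    if (post_ms[i] < 0 || post_ms[i] > duration_ms + 1e-9)
      stop("postsynaptic spike outside [0, duration]");
    post_idx[i] = (int)std::lround(post_ms[i] / dt);
  }

  double nm_a = 0, nm_b = 0, ep_a = 0, ep_b = 0, bp_a = 0, bp_b = 0;
  double ca_exc = 0, ca_star = 0, rho = rho0, use = u0, gam = g0;
  double peak_ca_exc = 0, peak_ca_star = 0;
  size_t ip = 0, iq = 0;

  NumericVector rep_t(n_rep), rep_rho(n_rep), rep_use(n_rep), rep_g(n_rep);
  int ir = 0;
  for (int i = 0; i < n_steps; ++i) {
    while (ip < pre_idx.size() && pre_idx[ip] == i) {
      nm_a += 1.0 / nm_norm; nm_b += 1.0 / nm_norm;
      ep_a += 1.0 / ep_norm; ep_b += 1.0 / ep_norm;
      ++ip;
    }
    while (iq < post_idx.size() && post_idx[iq] == i) {
      bp_a += 1.0 / bp_norm; bp_b += 1.0 / bp_norm;
      ca_exc += vdcc_gain; // VDCC influx as an instantaneous impulse
      ++iq;
    }
    const double v = v_rest + epsp_amp * (ep_a - ep_b) + bap_amp * (bp_a - bp_b);
    const double m = 1.0 / (1.0 + mg_ratio * std::exp(-mg_kappa * v));
    const double g = g_nmda_hat * (nm_a - nm_b);
    double i_star = g * m * (e_nmda - v); // influx-positive convention
    if (i_star < 0) i_star = 0;           // no calcium extrusion above reversal
    const double flux = i_star * k_flux;  // uM/ms

    // exponential Euler for the two linear equations
    ca_exc = ca_exc * d_ca + flux * tau_ca * (1.0 - d_ca);
    ca_star = ca_star * d_star + ca_exc * tau_star * (1.0 - d_star);
    if (ca_exc > peak_ca_exc) peak_ca_exc = ca_exc;
    if (ca_star > peak_ca_star) peak_ca_star = ca_star;

    if (plastic) {
      const double hp = (ca_star >= theta_p) ? 1.0 : 0.0;
      const double hd = (ca_star >= theta_d) ? 1.0 : 0.0;
      double drho = -rho * (1.0 - rho) * (rho_star - rho) +
                    gamma_p * (1.0 - rho) * hp - gamma_d * rho * hd;
      rho += dt / tau_rho_ms * drho;
      if (rho < 0) rho = 0; else if (rho > 1) rho = 1;
    }
    const double u_bar = u_d + rho * (u_p - u_d);
    const double g_bar = g_d + rho * (g_p - g_d);
    use = u_bar + (use - u_bar) * d_uw;
    gam = g_bar + (gam - g_bar) * d_uw;

    // kernel decay for the next step
    nm_a *= d_nm_d; nm_b *= d_nm_r;
    ep_a *= d_ep_d; ep_b *= d_ep_r;
    bp_a *= d_bp_d; bp_b *= d_bp_r;

    if ((i + 1) % rep_every == 0) {
      rep_t[ir] = (i + 1) * dt;
      rep_rho[ir] = rho; rep_use[ir] = use; rep_g[ir] = gam;
      ++ir;
    }
  }
  return List::create(_["report_times_ms"] = rep_t, _["rho"] = rep_rho,
                      _["U_SE"] = rep_use, _["g_AMPA"] = rep_g,
                      _["peak_ca_exc"] = peak_ca_exc,
                      _["peak_ca_star"] = peak_ca_star,
                      _["final"] = NumericVector::create(
                          _["rho"] = rho, _["U_SE"] = use, _["g_AMPA"] = gam,
                          _["ca_exc"] = ca_exc, _["ca_star"] = ca_star));
}

// Bare efficacy dynamics with a held Ca* value (used for separatrix and
// convergence analyses where the calcium drive is clamped).
// [[Rcpp::export]]
NumericVector cpp_integrate_rho(double rho0, double dt_ms, double duration_ms,
                                double tau_s, double rho_star, double gamma_d,
                                double gamma_p, double theta_d, double theta_p,
                                double ca_star, int n_report) {
  const double tau_ms = tau_s * 1000.0;
  const int n_steps = (int)std::ceil(duration_ms / dt_ms - 1e-9);
  const int rep_every = std::max(1, n_steps / std::max(1, n_report));
  const bool plastic = (theta_d >= 0.0) && (theta_p >= 0.0);
  const double hp = (plastic && ca_star >= theta_p) ? 1.0 : 0.0;
  const double hd = (plastic && ca_star >= theta_d) ? 1.0 : 0.0;
  std::vector<double> out;
  double rho = rho0;
  for (int i = 0; i < n_steps; ++i) {
    if (plastic) {
      double drho = -rho * (1.0 - rho) * (rho_star - rho) +
                    gamma_p * (1.0 - rho) * hp - gamma_d * rho * hd;
      rho += dt_ms / tau_ms * drho;
      if (rho < 0) rho = 0; else if (rho > 1) rho = 1;
    }
    if ((i + 1) % rep_every == 0) out.push_back(rho);
  }
  if (out.empty() || (n_steps % rep_every) != 0) out.push_back(rho);
  return wrap(out);
}

// O(n^3) Hungarian algorithm (potentials / shortest augmenting paths) for a
// square cost matrix; returns the column assigned to each row (1-based).
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector match(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) match[p[j] - 1] = j;
  return match;
}
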