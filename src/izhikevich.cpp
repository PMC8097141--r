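#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parameter vector layout shared with the R side (see cell_params()):
// [0] C_m, [1] v_r, [2] v_t, [3] v_peak, [4] a, [5] b, [6] c, [7] d,
// [8] k_low, [9] k_high
static const int PAR_LEN = 10;

static void check_par(const double *p) {
  for (int i = 0; i < PAR_LEN; ++i)
    if (!std::isfinite(p[i])) stop("non-finite cell parameter at position %d", i + 1);
}

// Forward-Euler step of the two-regime Izhikevich model.
// k switches between k_low (V <= v_t) and k_high (V > v_t); the hybrid
// reset (V >= v_peak -> V <- c, u <- u + d) is applied at most once per step.
static inline bool euler_step(const double *p, double &V, double &u,
                              double I, double dt) {
  const double k = (V <= p[2]) ? p[8] : p[9];
  const double dV = (k * (V - p[1]) * (V - p[2]) - u + I) / p[0];
  const double du = p[4] * (p[5] * (V - p[1]) - u);
  V += dt * dV;
  u += dt * du;
  if (V >= p[3]) { V = p[6]; u += p[7]; return true; }
  return false;
}

//' @noRd
// [[Rcpp::export]]
List izh_integrate_cpp(NumericVector par, double V0, double u0,
                       NumericVector seg_dur, NumericVector seg_amp,
                       NumericVector noise, double dt,
                       bool store_trace, int max_spikes) {
  if (par.size() != PAR_LEN) stop("parameter vector must have length %d", PAR_LEN);
  check_par(par.begin());
  if (!std::isfinite(V0) || !std::isfinite(u0)) stop("non-finite initial state");
  if (!(dt > 0)) stop("dt must be positive");
  const int nseg = seg_dur.size();
  if (nseg == 0 || seg_amp.size() != nseg) stop("segment durations/amplitudes mismatch");
  double total = 0.0;
  for (int s = 0; s < nseg; ++s) {
    if (!(seg_dur[s] > 0)) stop("segment durations must be positive");
    total += seg_dur[s];
  }
  const int n = (int)std::llround(total / dt);
  const bool has_noise = noise.size() > 0;
  if (has_noise && noise.size() != n)
    stop("noise trace must have one value per integration step (%d)", n);

  std::vector<double> spikes;
  NumericVector Vtr, utr, ttr;
  if (store_trace) {
    Vtr = NumericVector(n + 1);
    utr = NumericVector(n + 1);
    ttr = NumericVector(n + 1);
    Vtr[0] = V0; utr[0] = u0; ttr[0] = 0.0;
  }
  double V = V0, u = u0;
  int seg = 0;
  double seg_end = seg_dur[0];
  for (int i = 0; i < n; ++i) {
    const double t = i * dt;
    while (seg < nseg - 1 && t >= seg_end - 1e-12) seg_end += seg_dur[++seg];
    double I = seg_amp[seg];
    if (has_noise) I += noise[i];
    const bool spiked = euler_step(par.begin(), V, u, I, dt);
    if (!std::isfinite(V) || !std::isfinite(u))
      stop("state became non-finite at t = %g ms", (i + 1) * dt);
    if (store_trace) {
      ttr[i + 1] = (i + 1) * dt;
      Vtr[i + 1] = V;
      utr[i + 1] = u;
    }
    if (spiked) {
      spikes.push_back((i + 1) * dt);
      if (max_spikes > 0 && (int)spikes.size() >= max_spikes) {
        if (store_trace) {
          // truncate trace at the stopping step
          ttr = NumericVector(ttr.begin(), ttr.begin() + i + 2);
          Vtr = NumericVector(Vtr.begin(), Vtr.begin() + i + 2);
          utr = NumericVector(utr.begin(), utr.begin() + i + 2);
        }
        break;
      }
    }
  }
  List out = List::create(
    _["spike_times"] = wrap(spikes),
    _["V_end"] = V, _["u_end"] = u,
    _["duration"] = total, _["dt"] = dt);
  if (store_trace) {
    out["times"] = ttr;
    out["V"] = Vtr;
    out["u"] = utr;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix cell_par, int n_pyr,
                          List adj_targets,
                          NumericVector syn_w, NumericVector syn_tau,
                          NumericVector syn_erev,
                          NumericVector drive_mean, NumericVector drive_sd,
                          double duration, double dt,
                          double noise_dt, bool ou_noise, double ou_tau) {
  const int n = cell_par.nrow();
  if (cell_par.ncol() != PAR_LEN) stop("cell parameter matrix must have %d columns", PAR_LEN);
  if (n_pyr < 0 || n_pyr > n) stop("invalid n_pyr");
  if (adj_targets.size() != n) stop("adjacency list must have one entry per cell");
  if (syn_w.size() != 4 || syn_tau.size() != 4 || syn_erev.size() != 4)
    stop("synapse parameter vectors must have length 4 (ee, ei, ie, ii)");
  if (!(dt > 0) || !(duration > 0)) stop("duration and dt must be positive");

  // projection order: 0 ee (PYR->PYR), 1 ei (PYR->PV), 2 ie (PV->PYR), 3 ii (PV->PV)
  const double dec_e_pyr = std::exp(-dt / syn_tau[0]);
  const double dec_e_pv  = std::exp(-dt / syn_tau[1]);
  const double dec_i_pyr = std::exp(-dt / syn_tau[2]);
  const double dec_i_pv  = std::exp(-dt / syn_tau[3]);

  std::vector<std::vector<int> > adj(n);
  for (int j = 0; j < n; ++j) {
    IntegerVector tg = adj_targets[j];
    adj[j].assign(tg.begin(), tg.end());
    for (size_t k = 0; k < adj[j].size(); ++k)
      if (adj[j][k] < 0 || adj[j][k] >= n) stop("adjacency target out of range");
  }

  std::vector<double> V(n), u(n, 0.0), g_exc(n, 0.0), g_inh(n, 0.0), I_noise(n);
  std::vector<const double *> pp(n);
  std::vector<double> par_copy(n * PAR_LEN);
  for (int j = 0; j < n; ++j) {
    for (int q = 0; q < PAR_LEN; ++q) par_copy[j * PAR_LEN + q] = cell_par(j, q);
    pp[j] = &par_copy[j * PAR_LEN];
    check_par(pp[j]);
    V[j] = pp[j][1]; // start every cell at its resting potential, u = 0
  }

  const int n_steps = (int)std::llround(duration / dt);
  int noise_every = std::max(1, (int)std::llround(noise_dt / dt));
  const double ou_rel = dt / ou_tau;
  const double ou_diff = std::sqrt(2.0 * dt / ou_tau);
  for (int j = 0; j < n; ++j) {
    const int pop = (j < n_pyr) ? 0 : 1;
    I_noise[j] = drive_mean[pop] + drive_sd[pop] * norm_rand();
  }

  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  std::vector<int> fired;
  fired.reserve(n);

  for (int i = 0; i < n_steps; ++i) {
    // refresh drive
    if (ou_noise) {
      for (int j = 0; j < n; ++j) {
        const int pop = (j < n_pyr) ? 0 : 1;
        I_noise[j] += ou_rel * (drive_mean[pop] - I_noise[j]) +
                      drive_sd[pop] * ou_diff * norm_rand();
      }
    } else if (i % noise_every == 0) {
      for (int j = 0; j < n; ++j) {
        const int pop = (j < n_pyr) ? 0 : 1;
        I_noise[j] = drive_mean[pop] + drive_sd[pop] * norm_rand();
      }
    }
    fired.clear();
    for (int j = 0; j < n; ++j) {
      const bool is_pyr = j < n_pyr;
      const double I = I_noise[j] +
        g_exc[j] * (syn_erev[is_pyr ? 0 : 1] - V[j]) +
        g_inh[j] * (syn_erev[is_pyr ? 2 : 3] - V[j]);
      if (euler_step(pp[j], V[j], u[j], I, dt)) fired.push_back(j);
      if (!std::isfinite(V[j]))
        stop("cell %d state became non-finite at t = %g ms", j + 1, (i + 1) * dt);
      g_exc[j] *= is_pyr ? dec_e_pyr : dec_e_pv;
      g_inh[j] *= is_pyr ? dec_i_pyr : dec_i_pv;
    }
    // deliver spikes with a one-step axonal delay
    const double t_sp = (i + 1) * dt;
    for (size_t f = 0; f < fired.size(); ++f) {
      const int p = fired[f];
      spike_cell.push_back(p);
      spike_time.push_back(t_sp);
      const bool pre_pyr = p < n_pyr;
      const std::vector<int> &tg = adj[p];
      for (size_t k = 0; k < tg.size(); ++k) {
        const int q = tg[k];
        const bool post_pyr = q < n_pyr;
        if (pre_pyr) g_exc[q] += syn_w[post_pyr ? 0 : 1];
        else         g_inh[q] += syn_w[post_pyr ? 2 : 3];
      }
    }
  }
  return List::create(
    _["spike_cell"] = wrap(spike_cell),
    _["spike_time"] = wrap(spike_time),
    _["n_steps"] = n_steps);
}
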