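#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Full time-stepped simulation of the two-compartment network:
// input-spike filtering (exact exponential propagators), dendritic and
// somatic dynamics, adaptive response functions, online MRIL weight
// updates (optionally noise-augmented), somatic Poisson spike sampling and
// event-driven inhibitory STDP on the lateral weights.
//
// Spikes are passed as (bin, neuron) pairs (1-based, sorted by bin).
// All randomness draws from R's RNG, so set.seed() upstream makes the run
// reproducible; the draw order per step is fixed: n_out normal deviates if
// the learning noise is enabled, then n_out uniform deviates if output
// spikes are sampled.
// [[Rcpp::export]]
List sim_run_cpp(IntegerVector spike_bin, IntegerVector spike_neuron,
                 int n_steps, List par, NumericMatrix w0, NumericMatrix G0,
                 List lp, List sp, bool learn, bool istdp_on,
                 bool sample_spikes, int record_every) {
  const int n_in = as<int>(par["n_in"]);
  const int n_out = as<int>(par["n_out"]);
  const double tau_mem = as<double>(par["tau_mem"]);
  const double g_D = as<double>(par["g_D"]);
  const double tau_syn = as<double>(par["tau_syn"]);
  const double e0 = as<double>(par["e0"]);
  const double phi0 = as<double>(par["phi0"]);
  const double beta0 = as<double>(par["beta0"]);
  const double theta0 = as<double>(par["theta0"]);
  const double t0 = as<double>(par["t0"]);
  const double dt = as<double>(par["dt"]);
  const double sigma_floor = as<double>(par["sigma_floor"]);

  const double eta = as<double>(lp["eta"]);
  const double gamma = as<double>(lp["gamma"]);
  const double g_noise = as<double>(lp["g_noise"]);
  const bool noise_on = as<bool>(lp["noise_enabled"]);

  const double Cp = as<double>(sp["Cp"]);
  const double Cd = as<double>(sp["Cd"]);
  const double tau_p = as<double>(sp["tau_p"]);
  const double tau_d = as<double>(sp["tau_d"]);
  const double Gmax = as<double>(sp["Gmax"]);
  const double stdp_sign = as<bool>(sp["conventional"]) ? -1.0 : 1.0;

  const double alpha = g_D / (g_D + 1.0 / tau_mem);
  const double inj = 1.0 / (tau_mem * tau_syn);
  const double Es = std::exp(-dt / tau_syn);
  const double Em = std::exp(-dt / tau_mem);
  const bool degenerate = std::fabs(1.0 / tau_mem - 1.0 / tau_syn) < 1e-12;
  const double Adenom = degenerate ? 1.0 : (1.0 / tau_mem - 1.0 / tau_syn);
  const double lam = dt / t0;
  const bool adapt = par.containsElementNamed("adapt") ? as<bool>(par["adapt"]) : true;

  NumericMatrix w = clone(w0);
  NumericMatrix G = clone(G0);

  // state (picked up from par if the caller is resuming a run)
  std::vector<double> u(n_out, 0.0), mu(n_out, 0.0), m2(n_out, 1.0),
      sigma(n_out, 1.0);
  std::vector<double> I(n_in, 0.0), e(n_in, 0.0);
  if (par.containsElementNamed("state0")) {
    List st = par["state0"];
    NumericVector su = st["u"], smu = st["mu"], sm2 = st["m2"],
        sI = st["I"], se = st["e"];
    for (int i = 0; i < n_out; ++i) {
      u[i] = su[i]; mu[i] = smu[i]; m2[i] = sm2[i];
      sigma[i] = std::sqrt(std::max(m2[i] - mu[i] * mu[i],
                                    sigma_floor * sigma_floor));
    }
    for (int j = 0; j < n_in; ++j) { I[j] = sI[j]; e[j] = se[j]; }
  }

  std::vector<double> v(n_out), vs(n_out), ps(n_out), pd(n_out), psif(n_out),
      inh(n_out);
  // iSTDP traces (one pair per neuron; exact for exponential kernels)
  std::vector<double> zp(n_out, 0.0), zd(n_out, 0.0);
  int trace_bin = 0;  // bin index at which zp/zd are current

  const int n_rec = (n_steps + record_every - 1) / record_every;
  NumericMatrix rec_u(n_out, n_rec), rec_vstar(n_out, n_rec),
      rec_phis(n_out, n_rec), rec_phid(n_out, n_rec), rec_mu(n_out, n_rec),
      rec_sigma(n_out, n_rec);
  NumericVector rec_time(n_rec);

  std::vector<int> out_neuron, out_bin;
  std::vector<int> spiked;
  spiked.reserve(n_out);

  int sp_ptr = 0;
  const int n_spk = spike_bin.size();
  int rec_idx = 0;

  for (int k = 1; k <= n_steps; ++k) {
    // 1. deliver input spikes of this bin
    while (sp_ptr < n_spk && spike_bin[sp_ptr] == k) {
      I[spike_neuron[sp_ptr] - 1] += inj;
      ++sp_ptr;
    }
    // 2. dendritic and attenuated potentials
    for (int i = 0; i < n_out; ++i) {
      double acc = 0.0;
      const double* wr = &w(i, 0);
      // column-major: stride n_out over j
      for (int j = 0; j < n_in; ++j) acc += wr[(size_t)j * n_out] * e[j];
      v[i] = acc;
      vs[i] = alpha * acc;
    }
    // 3. response functions
    for (int i = 0; i < n_out; ++i) {
      double s = std::max(sigma[i], sigma_floor);
      double uhat = (u[i] - mu[i]) / s;
      ps[i] = phi0 / (1.0 + std::exp(beta0 * (theta0 - uhat)));
      pd[i] = phi0 / (1.0 + std::exp(beta0 * (theta0 - vs[i])));
      psif[i] = beta0 * (1.0 - pd[i] / phi0);
    }
    // 4. lateral inhibition from rates
    for (int i = 0; i < n_out; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n_out; ++j) acc += G(i, j) * ps[j] / phi0;
      inh[i] = acc;
    }
    // 5. record (state at the start of the bin)
    if ((k - 1) % record_every == 0) {
      rec_time[rec_idx] = (k - 1) * dt;
      for (int i = 0; i < n_out; ++i) {
        rec_u(i, rec_idx) = u[i];
        rec_vstar(i, rec_idx) = vs[i];
        rec_phis(i, rec_idx) = ps[i];
        rec_phid(i, rec_idx) = pd[i];
        rec_mu(i, rec_idx) = mu[i];
        rec_sigma(i, rec_idx) = sigma[i];
      }
      ++rec_idx;
    }
    // 6. MRIL weight update
    if (learn) {
      const double decay = eta * dt * gamma;
      for (int i = 0; i < n_out; ++i) {
        double teach = ps[i];
        if (noise_on) {
          teach += phi0 * g_noise * norm_rand();
          if (teach < 0.0) teach = 0.0; else if (teach > phi0) teach = phi0;
        }
        double coef = eta * dt * psif[i] * (teach - pd[i]) / phi0;
        double* wr = &w(i, 0);
        for (int j = 0; j < n_in; ++j) {
          size_t idx = (size_t)j * n_out;
          wr[idx] += coef * e[j] - decay * wr[idx];
        }
      }
    }
    // 7. somatic Euler step
    for (int i = 0; i < n_out; ++i)
      u[i] += dt * (-u[i] / tau_mem + g_D * (v[i] - u[i]) - inh[i]);
    // 8. running moments (frozen when adaptation is disabled: the
    // response function then keeps the fixed parameters beta0, theta0)
    if (adapt) {
      for (int i = 0; i < n_out; ++i) {
        mu[i] += lam * (u[i] - mu[i]);
        m2[i] += lam * (u[i] * u[i] - m2[i]);
        sigma[i] = std::sqrt(std::max(m2[i] - mu[i] * mu[i],
                                      sigma_floor * sigma_floor));
      }
    }
    // 9. output spikes and event-driven iSTDP
    if (sample_spikes) {
      spiked.clear();
      for (int i = 0; i < n_out; ++i)
        if (unif_rand() < ps[i] * dt) spiked.push_back(i);
      if (!spiked.empty()) {
        if (istdp_on) {
          double gap = (k - trace_bin) * dt;
          if (gap > 0) {
            double dp = std::exp(-gap / tau_p), dd = std::exp(-gap / tau_d);
            for (int i = 0; i < n_out; ++i) { zp[i] *= dp; zd[i] *= dd; }
          }
          trace_bin = k;
          for (size_t s = 0; s < spiked.size(); ++s) {
            int i = spiked[s];
            for (int j = 0; j < n_out; ++j) {
              if (j == i) continue;
              double dg = stdp_sign * (Cp * zp[j] - Cd * zd[j]);
              double gij = G(i, j) + dg;
              double gji = G(j, i) + dg;
              if (gij < 0) gij = 0; else if (gij > Gmax) gij = Gmax;
              if (gji < 0) gji = 0; else if (gji > Gmax) gji = Gmax;
              G(i, j) = gij;
              G(j, i) = gji;
            }
            zp[i] += 1.0; zd[i] += 1.0;
          }
        }
        for (size_t s = 0; s < spiked.size(); ++s) {
          out_neuron.push_back(spiked[s] + 1);
          out_bin.push_back(k);
        }
      }
    }
    // 10. propagate synaptic traces (exact over one bin)
    if (degenerate) {
      for (int j = 0; j < n_in; ++j) {
        e[j] = (e[j] + e0 * I[j] * dt) * Em;
        I[j] *= Es;
      }
    } else {
      for (int j = 0; j < n_in; ++j) {
        double A = e0 * I[j] / Adenom;
        e[j] = (e[j] - A) * Em + A * Es;
        I[j] *= Es;
      }
    }
  }

  return List::create(
      _["w"] = w, _["G"] = G,
      _["u"] = NumericVector(u.begin(), u.end()),
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["m2"] = NumericVector(m2.begin(), m2.end()),
      _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
      _["I"] = NumericVector(I.begin(), I.end()),
      _["e"] = NumericVector(e.begin(), e.end()),
      _["rec_time"] = rec_time, _["rec_u"] = rec_u,
      _["rec_vstar"] = rec_vstar, _["rec_phi_som"] = rec_phis,
      _["rec_phi_dend"] = rec_phid, _["rec_mu"] = rec_mu,
      _["rec_sigma"] = rec_sigma,
      _["out_neuron"] = IntegerVector(out_neuron.begin(), out_neuron.end()),
      _["out_bin"] = IntegerVector(out_bin.begin(), out_bin.end()));
}
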