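#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Network integration loop: forward Euler on AdEx membranes with
// peak-normalized beta-function conductance synapses.
//
// Synaptic state uses the linear two-state recursion of the beta kernel:
// every event adds amp = W/eta to both a decay accumulator A (factor
// exp(-dt/tau_decay) per step) and a rise accumulator B (factor
// exp(-dt/tau_rise)); the summed conductance of a kinetics class is A - B,
// which samples the closed-form kernel exactly on the step grid. States are
// grouped per (neuron, kinetics class), so per-step cost is O(n_neurons *
// n_kinetics) plus O(spikes * out-degree) event pushes, independent of the
// synapse count.
//
// Per-step semantics (must mirror step_neuron() in R/adex.R):
//   1. deliver events whose delay elapses this step (contribute 0 now),
//   2. read conductances, 3. Euler update / refractory / reset bookkeeping
//   with per-step Gaussian bias noise from R's RNG, 4. decay the states.
//
// params columns: C gL EL DeltaT Vth tau_w a b Vreset t_ref Ee Ei Ibias

// [[Rcpp::export]]
List engine_run(NumericMatrix params, NumericVector noise_sd,
                IntegerVector syn_pre, IntegerVector syn_post,
                NumericVector syn_amp, IntegerVector syn_kin,
                IntegerVector syn_delay_steps,
                NumericVector kin_tau_rise, NumericVector kin_tau_decay,
                LogicalVector kin_inhibitory,
                int n_steps, double dt, double exp_arg_cap,
                IntegerVector record_vm) {
  const int n = params.nrow();
  const int K = kin_tau_rise.size();
  const int n_syn = syn_pre.size();
  if (n == 0) stop("empty network: no neurons to integrate");

  // unpack parameters into flat arrays
  std::vector<double> C(n), gL(n), EL(n), DeltaT(n), Vth(n), tau_w(n),
      a(n), b(n), Vreset(n), t_ref(n), Ee(n), Ei(n), Ibias(n);
  for (int i = 0; i < n; ++i) {
    C[i] = params(i, 0);  gL[i] = params(i, 1);  EL[i] = params(i, 2);
    DeltaT[i] = params(i, 3); Vth[i] = params(i, 4); tau_w[i] = params(i, 5);
    a[i] = params(i, 6);  b[i] = params(i, 7);  Vreset[i] = params(i, 8);
    t_ref[i] = params(i, 9); Ee[i] = params(i, 10); Ei[i] = params(i, 11);
    Ibias[i] = params(i, 12);
  }

  std::vector<double> fd(K), fr(K);
  for (int k = 0; k < K; ++k) {
    if (kin_tau_rise[k] <= 0 || kin_tau_decay[k] <= 0)
      stop("non-positive synaptic time constant");
    fd[k] = std::exp(-dt / kin_tau_decay[k]);
    fr[k] = std::exp(-dt / kin_tau_rise[k]);
  }

  // adjacency (CSR) over presynaptic neurons
  std::vector<int> out_deg(n, 0), offset(n + 1, 0);
  for (int s = 0; s < n_syn; ++s) out_deg[syn_pre[s]]++;
  for (int i = 0; i < n; ++i) offset[i + 1] = offset[i] + out_deg[i];
  std::vector<int> adj(n_syn);
  {
    std::vector<int> cur(offset.begin(), offset.end() - 1);
    for (int s = 0; s < n_syn; ++s) adj[cur[syn_pre[s]]++] = s;
  }

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s) {
    if (syn_delay_steps[s] < 1) stop("synaptic delay must be >= 1 step");
    if (syn_delay_steps[s] > max_delay) max_delay = syn_delay_steps[s];
  }
  const int ring_size = max_delay + 1;
  std::vector<std::vector<std::pair<int, double> > > ring(ring_size);

  // synaptic states, k-major layout: index = k*n + i
  std::vector<double> A(static_cast<size_t>(K) * n, 0.0),
      B(static_cast<size_t>(K) * n, 0.0);

  std::vector<double> Vm(n), w(n, 0.0), refrac(n, 0.0);
  for (int i = 0; i < n; ++i) Vm[i] = EL[i];

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  const int n_rec = record_vm.size();
  NumericMatrix vm_trace(n_rec > 0 ? n_steps : 0, n_rec);

  std::vector<double> ge(n), gi(n);
  RNGScope rng;

  for (int step = 1; step <= n_steps; ++step) {
    // 1. deliver due events (a just-arrived event contributes A - B = 0)
    std::vector<std::pair<int, double> >& due = ring[step % ring_size];
    for (size_t e = 0; e < due.size(); ++e) {
      A[due[e].first] += due[e].second;
      B[due[e].first] += due[e].second;
    }
    due.clear();

    // 2. summed conductances per neuron
    std::fill(ge.begin(), ge.end(), 0.0);
    std::fill(gi.begin(), gi.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double* Ak = &A[static_cast<size_t>(k) * n];
      const double* Bk = &B[static_cast<size_t>(k) * n];
      double* tgt = kin_inhibitory[k] ? &gi[0] : &ge[0];
      for (int i = 0; i < n; ++i) {
        double g = Ak[i] - Bk[i];
        if (g > 0) tgt[i] += g;
      }
    }

    // 3. membrane update
    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) {
        // clamped at Vreset; adaptation relaxes, timer counts down
        w[i] += dt * (a[i] * (Vm[i] - EL[i]) - w[i]) / tau_w[i];
        refrac[i] -= dt;
        if (refrac[i] < 0) refrac[i] = 0;
        continue;
      }
      double noise = 0.0;
      if (noise_sd[i] > 0) noise = norm_rand() * noise_sd[i];
      double arg = (Vm[i] - Vth[i]) / DeltaT[i];
      if (arg > exp_arg_cap) arg = exp_arg_cap;
      double dV = (-gL[i] * (Vm[i] - EL[i]) + gL[i] * DeltaT[i] * std::exp(arg)
                   - ge[i] * (Vm[i] - Ee[i]) - gi[i] * (Vm[i] - Ei[i])
                   - w[i] + Ibias[i] + noise) / C[i];
      double Vnew = Vm[i] + dt * dV;
      w[i] += dt * (a[i] * (Vm[i] - EL[i]) - w[i]) / tau_w[i];
      if (!std::isfinite(Vnew))
        stop("non-finite membrane potential for neuron %d at t = %.1f ms",
             i + 1, step * dt);
      if (Vnew > 0.0) {
        Vm[i] = Vreset[i];
        w[i] += b[i];
        refrac[i] = t_ref[i];
        spike_id.push_back(i + 1);
        spike_t.push_back(step * dt);
        // schedule one event per outgoing synapse
        for (int e = offset[i]; e < offset[i + 1]; ++e) {
          const int s = adj[e];
          const int slot = (step + syn_delay_steps[s]) % ring_size;
          ring[slot].push_back(std::make_pair(
              syn_kin[s] * n + syn_post[s], syn_amp[s]));
        }
      } else {
        Vm[i] = Vnew;
      }
    }

    // 4. decay synaptic states
    for (int k = 0; k < K; ++k) {
      double* Ak = &A[static_cast<size_t>(k) * n];
      double* Bk = &B[static_cast<size_t>(k) * n];
      const double dk = fd[k], rk = fr[k];
      for (int i = 0; i < n; ++i) {
        Ak[i] *= dk;
        Bk[i] *= rk;
      }
    }

    if (n_rec > 0)
      for (int r = 0; r < n_rec; ++r)
        vm_trace(step - 1, r) = Vm[record_vm[r] - 1];

    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["neuron_id"] = wrap(spike_id),
                      _["time_ms"] = wrap(spike_t),
                      _["vm"] = vm_trace);
}
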