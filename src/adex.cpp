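#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast deterministic RNG for the membrane noise: xoshiro256++ seeded via
// splitmix64, with Box-Muller normals.  The simulation draws one normal
// per neuron per step (hundreds of millions per run), which R's RNG is
// too slow for; determinism is preserved because the stream is a pure
// function of the run seed.
namespace {
struct FastNormal {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit FastNormal(uint64_t seed) {
    // splitmix64 expansion of the seed into the xoshiro state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next_u64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double next_unif() {  // in (0, 1]
    return ((next_u64() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  inline double next_normal() {
    if (has_spare) { has_spare = false; return spare; }
    const double r = std::sqrt(-2.0 * std::log(next_unif()));
    const double a = 2.0 * M_PI * next_unif();
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};
}  // namespace

// Two-population (RS excitatory / FS inhibitory) adaptive exponential
// integrate-and-fire network with conductance-based exponential synapses:
//
//   Cm dV/dt = Gl (El - V) + Gl DeltaV exp((V - Vthre)/DeltaV)
//              + ge (Ee - V) + gi (Ei - V) - w + sigma xi(t)
//   tau_w dw/dt = a (V - El) - w,        w <- w + b at each spike
//   dg/dt = -g / tau_syn,                g <- g + Q on presynaptic spikes
//
// Units: mV, ms, nS, pF, pA.  A spike is the time step at which V crosses
// Vthre upward; V is then reset to Vreset and clamped for Trefrac.
// With `literal_adaptation` the adaptation instead decays with Cm/Gl
// (the alternative printed form) while the spike increment is unchanged.
//
// Neurons 0..N_exc-1 are excitatory, N_exc..N-1 inhibitory. `targets`
// and `ptr` give the out-adjacency in CSR form.
// [[Rcpp::export]]
List adex_core(int N_exc, int N_inh,
               const IntegerVector& targets, const IntegerVector& ptr,
               const List& par_exc, const List& par_inh,
               double Q_exc, double Q_inh,
               double dt, int n_steps,
               const NumericVector& V0,
               const IntegerVector& record_idx, int record_every,
               bool literal_adaptation, int noise_seed) {
  const int N = N_exc + N_inh;
  if (V0.size() != N) stop("V0 length must equal N_exc + N_inh");
  if (dt <= 0 || dt > 0.5)
    stop("dt must be in (0, 0.5] ms; larger steps overflow the exponential term");

  auto getp = [](const List& p, const char* name) {
    return as<double>(p[name]);
  };
  // per-population parameter tables, index 0 = exc, 1 = inh
  double Gl[2], Cm[2], El[2], DeltaV[2], Vthre[2], Vreset[2], Trefrac[2],
      tau_w[2], a_[2], b_[2], sigma[2], Iext[2];
  const List* pars[2] = {&par_exc, &par_inh};
  for (int p = 0; p < 2; ++p) {
    Gl[p] = getp(*pars[p], "Gl");       Cm[p] = getp(*pars[p], "Cm");
    El[p] = getp(*pars[p], "El");       DeltaV[p] = getp(*pars[p], "Delta_V");
    Vthre[p] = getp(*pars[p], "V_thre"); Vreset[p] = getp(*pars[p], "V_reset");
    Trefrac[p] = getp(*pars[p], "T_refrac");
    tau_w[p] = getp(*pars[p], "tau_w");
    a_[p] = getp(*pars[p], "a");        b_[p] = getp(*pars[p], "b");
    sigma[p] = getp(*pars[p], "sigma"); Iext[p] = getp(*pars[p], "I_ext");
  }
  const double tau_syn = getp(par_exc, "tau_syn");
  const double Ee = getp(par_exc, "E_syn_exc");
  const double Ei = getp(par_exc, "E_syn_inh");
  const double gdecay = std::exp(-dt / tau_syn);
  const int refrac_steps[2] = {(int)std::round(Trefrac[0] / dt),
                               (int)std::round(Trefrac[1] / dt)};

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> w(N, 0.0), ge(N, 0.0), gi(N, 0.0);
  std::vector<int> refrac_until(N, 0);

  const int n_rec = record_idx.size();
  const int n_samp = n_steps / record_every;
  NumericMatrix vm_out(n_rec, n_samp), w_out(n_rec, n_samp);

  std::vector<int> spike_neuron, spike_step, spikers;
  spike_neuron.reserve(1 << 20);
  spike_step.reserve(1 << 20);

  FastNormal rng(0x5f3759dfULL * (uint64_t)(uint32_t)noise_seed + 0x9e3779b9ULL);
  const double noise_amp[2] = {sigma[0] * std::sqrt(dt) / Cm[0],
                               sigma[1] * std::sqrt(dt) / Cm[1]};
  int samp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      const int p = (i < N_exc) ? 0 : 1;
      const double Isyn = ge[i] * (Ee - V[i]) + gi[i] * (Ei - V[i]);
      // adaptation evolves also during the refractory clamp
      if (literal_adaptation)
        w[i] += dt * (-(Gl[p] / Cm[p]) * w[i] + a_[p] * (V[i] - El[p]));
      else
        w[i] += dt * (a_[p] * (V[i] - El[p]) - w[i]) / tau_w[p];
      if (step < refrac_until[i]) {
        V[i] = Vreset[p];
      } else {
        double ex = (V[i] - Vthre[p]) / DeltaV[p];
        if (ex > 30.0) ex = 30.0;  // overflow guard; spike fires this step anyway
        // below ~8 steepness units the exponential term is < 1e-3 pA
        const double spike_term =
            (ex > -8.0) ? Gl[p] * DeltaV[p] * std::exp(ex) : 0.0;
        double dV = Gl[p] * (El[p] - V[i]) + spike_term + Isyn - w[i] + Iext[p];
        V[i] += dt * dV / Cm[p];
        if (sigma[p] > 0.0)
          V[i] += noise_amp[p] * rng.next_normal();
        if (V[i] >= Vthre[p]) {
          spike_neuron.push_back(i);
          spike_step.push_back(step);
          spikers.push_back(i);
          V[i] = Vreset[p];
          refrac_until[i] = step + refrac_steps[p];
          w[i] += b_[p];
        }
      }
      ge[i] *= gdecay;
      gi[i] *= gdecay;
    }
    for (size_t k = 0; k < spikers.size(); ++k) {
      const int j = spikers[k];
      const bool exc = j < N_exc;
      for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
        const int t = targets[e];
        if (exc) ge[t] += Q_exc; else gi[t] += Q_inh;
      }
    }
    if (step % record_every == 0 && samp < n_samp) {
      for (int r = 0; r < n_rec; ++r) {
        vm_out(r, samp) = V[record_idx[r]];
        w_out(r, samp) = w[record_idx[r]];
      }
      ++samp;
    }
  }
  return List::create(_["spike_neuron"] = wrap(spike_neuron),
                      _["spike_step"] = wrap(spike_step),
                      _["vm"] = vm_out, _["w"] = w_out);
}
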