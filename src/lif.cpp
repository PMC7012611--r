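// Finite-size LIF network core: sparse Bernoulli connectivity, exponential
// synapses integrated exactly between spikes, RK2 for the membrane potential,
// threshold/reset without spike-time interpolation.
//
// The integrator keeps one aggregated synaptic trace per (postsynaptic
// neuron, presynaptic population) channel, stored population-block-wise so
// the per-step decay/accumulation passes are simple vectorizable loops.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// Draw the directed adjacency: every ordered pair (post i, pre j) is
// connected independently with probability K / N[pop(j)]; self-connections
// are excluded. Neurons are ordered by population. Returns CSR by
// presynaptic neuron (0-based indices).
// [[Rcpp::export]]
List build_connectivity_cpp(IntegerVector Npop, double K, int seed,
                            bool exclude_self) {
  const int P = Npop.size();
  long Ntot = 0;
  std::vector<long> off(P + 1, 0);
  for (int p = 0; p < P; ++p) {
    Ntot += Npop[p];
    off[p + 1] = Ntot;
  }
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> targets;
  targets.reserve(static_cast<size_t>(Ntot) * P);
  IntegerVector ptr(Ntot + 1);
  long pos = 0;
  for (int pb = 0; pb < P; ++pb) {
    const double p = K / (double)Npop[pb];
    for (long j = off[pb]; j < off[pb + 1]; ++j) {
      ptr[j] = (int)pos;
      if (p >= 1.0) {
        for (long i = 0; i < Ntot; ++i) {
          if (exclude_self && i == j) continue;
          targets.push_back((int)i);
          ++pos;
        }
      } else if (p > 0.0) {
        const double log1mp = std::log(1.0 - p);
        long i = -1;
        while (true) {
          double u = unif(rng);
          if (u <= 0.0) u = std::numeric_limits<double>::min();
          i += 1 + (long)std::floor(std::log(u) / log1mp);
          if (i >= Ntot) break;
          if (exclude_self && i == j) continue;
          targets.push_back((int)i);
          ++pos;
        }
      }
    }
  }
  ptr[Ntot] = (int)pos;
  return List::create(_["ptr"] = ptr,
                      _["targets"] = IntegerVector(targets.begin(), targets.end()));
}

// Integrate the network. pop: 0-based population index per neuron (sorted by
// population); js: signed couplings j_ab * polarity_b (uA.ms/cm^2, rows post);
// tau: synaptic time constants (ms, 0 where unused); lambda: constant drive
// per population (uA/cm^2, feedforward + optogenetic). Voltages in mV, time
// in ms. Spikes at or above threshold are recorded at the end-of-step time;
// only spikes at t >= warmup are returned/counted.
// [[Rcpp::export]]
List simulate_lif_cpp(IntegerVector pop, IntegerVector pop_offsets,
                      IntegerVector ptr, IntegerVector targets,
                      NumericMatrix js, NumericMatrix tau,
                      NumericVector lambda, NumericVector g_leak,
                      double C_M, double V_th, double V_R,
                      double dt, double duration, double warmup,
                      int seed, bool record_spikes,
                      bool randomize_V, double V_init) {
  const int P = js.nrow();
  const long N = pop.size();
  const long nsteps = (long)std::llround(duration / dt);
  const double invC = 1.0 / C_M;

  // per (post pop a, pre pop b): decay factor, coupling, coupling*decay, jump
  std::vector<double> dec(P * P), jsv(P * P), jsdec(P * P), jump(P * P);
  for (int a = 0; a < P; ++a) {
    for (int b = 0; b < P; ++b) {
      const double t = tau(a, b);
      jsv[a * P + b] = js(a, b);
      if (t > 0.0) {
        dec[a * P + b] = std::exp(-dt / t);
        jump[a * P + b] = 1.0 / t;
      } else {
        dec[a * P + b] = 0.0;
        jump[a * P + b] = 0.0;
      }
      jsdec[a * P + b] = jsv[a * P + b] * dec[a * P + b];
    }
  }

  // traces: G[b][i], one array of length N per presynaptic population
  std::vector<std::vector<double>> G(P, std::vector<double>(N, 0.0));
  std::vector<double> V(N), Inow(N), Inext(N);
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (long i = 0; i < N; ++i) {
    V[i] = randomize_V ? V_R + (V_th - V_R) * unif(rng) : V_init;
  }

  std::vector<int> counts(N, 0), spiked;
  spiked.reserve(1024);
  std::vector<int> sp_id;
  std::vector<double> sp_t;

  for (long step = 0; step < nsteps; ++step) {
    const double t_next = (step + 1) * dt;
    const bool after = t_next >= warmup;
    spiked.clear();

    // accumulate recurrent input at t and t+dt, decaying traces in place
    for (int a = 0; a < P; ++a) {
      const long i0 = pop_offsets[a], i1 = pop_offsets[a + 1];
      const double lam = lambda[a];
      for (long i = i0; i < i1; ++i) {
        Inow[i] = lam;
        Inext[i] = lam;
      }
      for (int b = 0; b < P; ++b) {
        const double j = jsv[a * P + b];
        const double jd = jsdec[a * P + b];
        const double d = dec[a * P + b];
        if (j == 0.0 && d == 0.0) continue;
        double *RESTRICT g = G[b].data();
        for (long i = i0; i < i1; ++i) {
          const double gb = g[i];
          Inow[i] += j * gb;
          Inext[i] += jd * gb;
          g[i] = gb * d;
        }
      }
    }

    // RK2 voltage update, threshold/reset
    for (int a = 0; a < P; ++a) {
      const long i0 = pop_offsets[a], i1 = pop_offsets[a + 1];
      const double gl = g_leak[a];
      for (long i = i0; i < i1; ++i) {
        double v = V[i];
        const double k1 = (-gl * (v - V_R) + Inow[i]) * invC;
        const double v1 = v + dt * k1;
        const double k2 = (-gl * (v1 - V_R) + Inext[i]) * invC;
        v += 0.5 * dt * (k1 + k2);
        if (v >= V_th) {
          v = V_R;
          spiked.push_back((int)i);
        } else if (v > 1000.0 || v < -1000.0) {
          stop("membrane potential diverged (|V| > 1000 mV) at t = %f ms, "
               "neuron %d", t_next, (int)i + 1);
        }
        V[i] = v;
      }
    }

    // propagate spikes: traces of the targets jump by 1/tau
    for (size_t k = 0; k < spiked.size(); ++k) {
      const int j = spiked[k];
      if (after) {
        ++counts[j];
        if (record_spikes) {
          sp_id.push_back(j + 1);
          sp_t.push_back(t_next);
        }
      }
      const int b = pop[j];
      const double *jmp = &jump[0];
      double *RESTRICT g = G[b].data();
      const int e0 = ptr[j], e1 = ptr[j + 1];
      for (int e = e0; e < e1; ++e) {
        const int i = targets[e];
        g[i] += jmp[pop[i] * P + b];
      }
    }
  }

  return List::create(
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["counts"] = IntegerVector(counts.begin(), counts.end()));
}
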