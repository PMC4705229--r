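#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven simulation of the three-layer classifier network.
//
// RN spikes are supplied as pre-built events (spike sources); PN, AN and
// (spikey preset) LN populations are leaky integrate-and-fire neurons with
// exponential current-based synapses, integrated by exponential Euler
// (exact for piecewise-constant input). All synaptic delays are one
// timestep. The PN->AN matrix may be plastic: symmetric nearest-neighbour
// STDP, positive update a_plus for any spike-pair order within win_steps,
// weights clipped to [0, w_max].

struct Pop {
  int n = 0;
  std::vector<double> v, ie, ii, pe, pi, bias;
  std::vector<int> refr;
  void init(int n_, double v_rest, const NumericVector& bias_) {
    n = n_;
    v.assign(n, v_rest);
    ie.assign(n, 0.0); ii.assign(n, 0.0);
    pe.assign(n, 0.0); pi.assign(n, 0.0);
    refr.assign(n, 0);
    bias.assign(n, 0.0);
    if (bias_.size() == n)
      for (int i = 0; i < n; ++i) bias[i] = bias_[i];
  }
};

// [[Rcpp::export]]
List cpp_simulate(int preset, int n_vr, int n_classes,
                  int rn_cluster, int pn_cluster, int an_cluster,
                  int ln_pn_cluster, int ln_an_cluster,
                  NumericVector np,   // tau_m, v_rest, v_thresh, v_reset, t_ref, r_m
                  double tau_exc, double tau_inh,
                  double w_rn_pn, double w_pn_inh, double w_an_inh,
                  double w_pn_ln, double w_ln_pn,
                  double w_an_ln, double w_ln_an,
                  NumericMatrix W_in,
                  int n_steps, double dt,
                  IntegerVector in_id, IntegerVector in_step,
                  IntegerVector teach_id, IntegerVector teach_step,
                  double teach_w,
                  bool plastic, double a_plus, int win_steps, double w_max,
                  NumericVector pn_bias, NumericVector an_bias,
                  bool record_pn, bool record_an, bool record_ln,
                  bool record_vm) {
  const double tau_m = np[0], v_rest = np[1], v_thresh = np[2],
               v_reset = np[3], t_ref = np[4], r_m = np[5];
  const int n_rn = n_vr * rn_cluster;
  const int n_pn = n_vr * pn_cluster;
  const int n_an = n_classes * an_cluster;
  const int n_lnp = (preset == 1) ? n_vr * ln_pn_cluster : 0;
  const int n_lna = (preset == 1) ? n_classes * ln_an_cluster : 0;
  if (W_in.nrow() != n_pn || W_in.ncol() != n_an)
    stop("weight matrix must be n_pn x n_an");

  const double e_m = std::exp(-dt / tau_m);
  const double de = std::exp(-dt / tau_exc);
  const double di = std::exp(-dt / tau_inh);
  const int ref_steps = (int)std::lround(t_ref / dt);

  Pop pn, an, lnp, lna;
  pn.init(n_pn, v_rest, pn_bias);
  an.init(n_an, v_rest, an_bias);
  if (preset == 1) {
    lnp.init(n_lnp, v_rest, NumericVector(0));
    lna.init(n_lna, v_rest, NumericVector(0));
  }

  // transposed plastic matrix: column j (presynaptic PN) contiguous
  std::vector<double> Wt((size_t)n_an * n_pn);
  for (int j = 0; j < n_pn; ++j)
    for (int a = 0; a < n_an; ++a)
      Wt[(size_t)j * n_an + a] = W_in(j, a);

  std::vector<int> last_pre(n_pn, -2 * win_steps - 10);
  std::vector<int> last_post(n_an, -2 * win_steps - 10);
  double w_lo_seen = R_PosInf, w_hi_seen = R_NegInf;
  {
    for (size_t k = 0; k < Wt.size(); ++k) {
      if (Wt[k] < w_lo_seen) w_lo_seen = Wt[k];
      if (Wt[k] > w_hi_seen) w_hi_seen = Wt[k];
    }
  }

  // charge bookkeeping per projection (sum of delivered synaptic weights)
  double q_rn_pn = 0, q_pn_inh = 0, q_pn_an = 0, q_an_inh = 0, q_teach = 0;
  double q_pn_ln = 0, q_ln_pn = 0, q_an_ln = 0, q_ln_an = 0;

  std::vector<int> rec_pn_id, rec_pn_step, rec_an_id, rec_an_step;
  std::vector<int> rec_ln_id, rec_ln_step;
  std::vector<double> vm_trace;  // first PN and first AN neuron, interleaved
  std::vector<int> pn_spikes, an_spikes, lnp_spikes, lna_spikes;

  int in_ptr = 0, teach_ptr = 0;
  const int n_in = in_id.size(), n_teach = teach_id.size();

  for (int s = 0; s < n_steps; ++s) {
    // 1. synaptic currents: decay then add impulses queued at step s-1
    auto currents = [&](Pop& p) {
      for (int i = 0; i < p.n; ++i) {
        p.ie[i] = p.ie[i] * de + p.pe[i]; p.pe[i] = 0.0;
        p.ii[i] = p.ii[i] * di + p.pi[i]; p.pi[i] = 0.0;
      }
    };
    currents(pn); currents(an);
    if (preset == 1) { currents(lnp); currents(lna); }

    // 2. membrane update, threshold, reset, refractory
    auto update = [&](Pop& p, std::vector<int>& spikes) {
      spikes.clear();
      for (int i = 0; i < p.n; ++i) {
        if (p.refr[i] > 0) { p.refr[i]--; p.v[i] = v_reset; continue; }
        const double E = v_rest + r_m * (p.ie[i] + p.ii[i] + p.bias[i]);
        p.v[i] = E + (p.v[i] - E) * e_m;
        if (p.v[i] >= v_thresh) {
          spikes.push_back(i);
          p.v[i] = v_reset;
          p.refr[i] = ref_steps;
        }
      }
    };
    update(pn, pn_spikes);
    update(an, an_spikes);
    if (preset == 1) { update(lnp, lnp_spikes); update(lna, lna_spikes); }

    if (record_vm) { vm_trace.push_back(pn.v[0]); vm_trace.push_back(an.v[0]); }

    // 3. external RN input events at step s -> PN at s+1
    while (in_ptr < n_in && in_step[in_ptr] == s) {
      const int r = in_id[in_ptr];
      if (preset == 0) {
        // one-to-one within the matching cluster (equal cluster sizes)
        pn.pe[r] += w_rn_pn;
        q_rn_pn += w_rn_pn;
      } else {
        // cluster-to-cluster all-to-all (cluster sizes differ)
        const int c = r / rn_cluster;
        for (int i = c * pn_cluster; i < (c + 1) * pn_cluster; ++i)
          pn.pe[i] += w_rn_pn;
        q_rn_pn += w_rn_pn * pn_cluster;
      }
      ++in_ptr;
    }
    // teaching events at step s -> AN at s+1 (excitatory, external)
    while (teach_ptr < n_teach && teach_step[teach_ptr] == s) {
      an.pe[teach_id[teach_ptr]] += teach_w;
      q_teach += teach_w;
      ++teach_ptr;
    }

    // 4. recurrent propagation of this step's spikes (delivered at s+1)
    // PN spikes: lateral inhibition + plastic drive to AN
    if (!pn_spikes.empty()) {
      if (preset == 0) {
        double tot = 0.0;
        std::vector<double> per_cl(n_vr, 0.0);
        for (int j : pn_spikes) {
          tot += w_pn_inh;
          per_cl[j / pn_cluster] += w_pn_inh;
          q_pn_inh += w_pn_inh * (n_pn - pn_cluster);
        }
        for (int i = 0; i < n_pn; ++i)
          pn.pi[i] += tot - per_cl[i / pn_cluster];
      } else {
        for (int j : pn_spikes) {
          const int c = j / pn_cluster;
          for (int i = c * ln_pn_cluster; i < (c + 1) * ln_pn_cluster; ++i)
            lnp.pe[i] += w_pn_ln;
          q_pn_ln += w_pn_ln * ln_pn_cluster;
        }
      }
      for (int j : pn_spikes) {
        const double* wcol = &Wt[(size_t)j * n_an];
        for (int a = 0; a < n_an; ++a) {
          an.pe[a] += wcol[a];
          q_pn_an += wcol[a];
        }
        if (record_pn) { rec_pn_id.push_back(j); rec_pn_step.push_back(s); }
      }
    }

    // AN spikes: winner-take-all inhibition
    if (!an_spikes.empty()) {
      if (preset == 0) {
        double tot = 0.0;
        std::vector<double> per_cl(n_classes, 0.0);
        for (int a : an_spikes) {
          tot += w_an_inh;
          per_cl[a / an_cluster] += w_an_inh;
          q_an_inh += w_an_inh * (n_an - an_cluster);
        }
        for (int i = 0; i < n_an; ++i)
          an.pi[i] += tot - per_cl[i / an_cluster];
      } else {
        for (int a : an_spikes) {
          const int c = a / an_cluster;
          for (int i = c * ln_an_cluster; i < (c + 1) * ln_an_cluster; ++i)
            lna.pe[i] += w_an_ln;
          q_an_ln += w_an_ln * ln_an_cluster;
        }
      }
      if (record_an)
        for (int a : an_spikes) { rec_an_id.push_back(a); rec_an_step.push_back(s); }
    }

    // LN spikes (spikey preset): mediate lateral inhibition
    if (preset == 1) {
      if (!lnp_spikes.empty()) {
        double tot = 0.0;
        std::vector<double> per_cl(n_vr, 0.0);
        for (int l : lnp_spikes) {
          tot += w_ln_pn;
          per_cl[l / ln_pn_cluster] += w_ln_pn;
          q_ln_pn += w_ln_pn * (n_pn - pn_cluster);
        }
        for (int i = 0; i < n_pn; ++i)
          pn.pi[i] += tot - per_cl[i / pn_cluster];
      }
      if (!lna_spikes.empty()) {
        double tot = 0.0;
        std::vector<double> per_cl(n_classes, 0.0);
        for (int l : lna_spikes) {
          tot += w_ln_an;
          per_cl[l / ln_an_cluster] += w_ln_an;
          q_ln_an += w_ln_an * (n_an - an_cluster);
        }
        for (int i = 0; i < n_an; ++i)
          an.pi[i] += tot - per_cl[i / an_cluster];
      }
      if (record_ln) {
        for (int l : lnp_spikes) { rec_ln_id.push_back(l); rec_ln_step.push_back(s); }
        for (int l : lna_spikes) { rec_ln_id.push_back(n_lnp + l); rec_ln_step.push_back(s); }
      }
    }

    // 5. symmetric STDP on PN->AN pairs (nearest-neighbour pairing)
    if (plastic) {
      // pre spikes pair with the most recent post spike of each AN neuron
      for (int j : pn_spikes) {
        double* wcol = &Wt[(size_t)j * n_an];
        for (int a = 0; a < n_an; ++a) {
          if (s - last_post[a] <= win_steps) {
            wcol[a] += a_plus;
            if (wcol[a] > w_max) wcol[a] = w_max;
            if (wcol[a] > w_hi_seen) w_hi_seen = wcol[a];
          }
        }
        last_pre[j] = s;
      }
      // post spikes pair with the most recent pre spike (incl. this step,
      // so a simultaneous pair is counted exactly once)
      for (int a : an_spikes) {
        for (int j = 0; j < n_pn; ++j) {
          if (s - last_pre[j] <= win_steps) {
            double& w = Wt[(size_t)j * n_an + a];
            w += a_plus;
            if (w > w_max) w = w_max;
            if (w > w_hi_seen) w_hi_seen = w;
          }
        }
        last_post[a] = s;
      }
    }
  }

  NumericMatrix W_out(n_pn, n_an);
  for (int j = 0; j < n_pn; ++j)
    for (int a = 0; a < n_an; ++a)
      W_out(j, a) = Wt[(size_t)j * n_an + a];
  for (size_t k = 0; k < Wt.size(); ++k)
    if (Wt[k] < w_lo_seen) w_lo_seen = Wt[k];

  NumericVector charge = NumericVector::create(
      _["rn_pn"] = q_rn_pn, _["pn_inh"] = q_pn_inh, _["pn_an"] = q_pn_an,
      _["an_inh"] = q_an_inh, _["teach"] = q_teach,
      _["pn_ln"] = q_pn_ln, _["ln_pn"] = q_ln_pn,
      _["an_ln"] = q_an_ln, _["ln_an"] = q_ln_an);

  return List::create(
      _["pn_id"] = wrap(rec_pn_id), _["pn_step"] = wrap(rec_pn_step),
      _["an_id"] = wrap(rec_an_id), _["an_step"] = wrap(rec_an_step),
      _["ln_id"] = wrap(rec_ln_id), _["ln_step"] = wrap(rec_ln_step),
      _["W"] = W_out,
      _["w_min_seen"] = w_lo_seen, _["w_max_seen"] = w_hi_seen,
      _["charge"] = charge,
      _["vm"] = wrap(vm_trace));
}
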