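// Core per-step simulation loop.
//
// One call advances the network through one task phase (fixed targets and
// STDP rate gamma). Per-step order: stimulus pulses -> continuous decays
// (conductances, STP variables, STDP traces) -> membrane Euler step with
// refractory clamp -> threshold detection -> presynaptic spike processing
// (facilitation, release, conductance injection) -> triplet STDP (traces
// read before this step's increments) -> trace increments -> error-driven
// STP learning on the spikers' incoming synapses -> single clipped update
// of the maximum strengths -> rate EMA and population means -> recording.
//
// Matrix convention: entry (i, j) belongs to the synapse j -> i.
// Time constants are stored in ms; the learning rules convert to seconds.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double symmetry_sub(const NumericMatrix& A, const IntegerVector& idx) {
  int n = idx.size();
  double acc = 0.0;
  int M = 0;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double x = A(idx[a], idx[b]), y = A(idx[b], idx[a]);
      if (x == 0.0 && y == 0.0) { ++M; continue; }
      acc += std::fabs(x - y) / (x + y);
    }
  }
  double denom = n * (n - 1) - 2.0 * M;  // = 2 * (#pairs - M)
  if (denom <= 0) return NA_REAL;
  return 1.0 - 2.0 * acc / denom;
}

static double group_mean(const NumericMatrix& P, const LogicalMatrix& mask,
                         const IntegerVector& tgt, const IntegerVector& src) {
  double s = 0.0; int n = 0;
  for (int a = 0; a < tgt.size(); ++a)
    for (int b = 0; b < src.size(); ++b) {
      int i = tgt[a], j = src[b];
      if (i == j || !mask(i, j)) continue;
      s += P(i, j); ++n;
    }
  return n ? s / n : NA_REAL;
}

// [[Rcpp::export]]
List sim_phase_cpp(List state, List consts, List cfg,
                   IntegerVector pop, NumericVector targets,
                   IntegerVector stim_step, IntegerVector stim_neuron,
                   double stim_amp,
                   int n_steps, double t0,
                   int record_every, List sym_groups, List param_groups,
                   bool record_raster) {
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector ref_until = clone(as<NumericVector>(state["ref_until"]));
  NumericMatrix g = clone(as<NumericMatrix>(state["g"]));
  NumericMatrix r = clone(as<NumericMatrix>(state["r"]));
  NumericMatrix u = clone(as<NumericMatrix>(state["u"]));
  NumericMatrix Umat = clone(as<NumericMatrix>(state["U"]));
  NumericMatrix trec = clone(as<NumericMatrix>(state["tau_rec"]));
  NumericMatrix tfac = clone(as<NumericMatrix>(state["tau_facil"]));
  NumericMatrix A = clone(as<NumericMatrix>(state["A"]));
  NumericVector m1 = clone(as<NumericVector>(state["m1"]));
  NumericVector m2 = clone(as<NumericVector>(state["m2"]));
  NumericVector o1 = clone(as<NumericVector>(state["o1"]));
  NumericVector o2 = clone(as<NumericVector>(state["o2"]));
  NumericVector nu = clone(as<NumericVector>(state["nu"]));
  LogicalMatrix mask = as<LogicalMatrix>(state["mask"]);

  const int N = V.size();
  const double dt = as<double>(consts["dt"]);
  const double gL = as<double>(consts["g_L"]);
  const double Erev = as<double>(consts["E_rev"]);
  const double Vthr = as<double>(consts["V_thr"]);
  const double tref = as<double>(consts["t_ref"]);
  const double tau_g = as<double>(consts["tau_g"]);
  const double tau_nu = as<double>(consts["tau_nu"]);
  const double nu_lim = as<double>(consts["nu_lim"]);
  const double Umin = as<double>(consts["U_min"]), Umax = as<double>(consts["U_max"]);
  const double trmin = as<double>(consts["tau_rec_min"]), trmax = as<double>(consts["tau_rec_max"]);
  const double tfmin = as<double>(consts["tau_facil_min"]), tfmax = as<double>(consts["tau_facil_max"]);
  const double Amin = as<double>(consts["A_min"]), Amax = as<double>(consts["A_max"]);
  const double A2p = as<double>(consts["A2_plus"]), A3p = as<double>(consts["A3_plus"]);
  const double A2m = as<double>(consts["A2_minus"]), A3m = as<double>(consts["A3_minus"]);
  const double dm1 = std::exp(-dt / as<double>(consts["tau_m1"]));
  const double dm2 = std::exp(-dt / as<double>(consts["tau_m2"]));
  const double do1 = std::exp(-dt / as<double>(consts["tau_o1"]));
  const double do2 = std::exp(-dt / as<double>(consts["tau_o2"]));
  const double eg = std::exp(-dt / tau_g);
  const double enu = std::exp(-dt / tau_nu);

  const double gamma = as<double>(cfg["gamma"]);
  const double eta_bar = as<double>(cfg["eta_bar"]);
  const double scale = as<double>(cfg["learn_scale"]);
  LogicalVector learn = as<LogicalVector>(cfg["learn"]);  // U, taurec, taufacil, A
  const bool lU = learn[0], lTR = learn[1], lTF = learn[2], lA = learn[3];
  const bool facil_first = as<bool>(cfg["facil_first"]);
  const double g_scale = cfg.containsElementNamed("g_scale") ?
    as<double>(cfg["g_scale"]) : 1.0;
  const bool refrac_gate = cfg.containsElementNamed("refrac_gate") ?
    as<bool>(cfg["refrac_gate"]) : false;

  const int n_pop = targets.size();
  std::vector<int> pop_size(n_pop, 0);
  for (int i = 0; i < N; ++i) pop_size[pop[i] - 1]++;

  // cached per-synapse relaxation factors
  NumericMatrix Drec(N, N), Dfac(N, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      Drec(i, j) = std::exp(-dt / trec(i, j));
      Dfac(i, j) = std::exp(-dt / tfac(i, j));
    }

  NumericMatrix dA(N, N);
  std::vector<int> spikers; spikers.reserve(N);
  std::vector<double> popmean(n_pop, 0.0);
  for (int i = 0; i < N; ++i) popmean[pop[i] - 1] += nu[i];
  for (int p = 0; p < n_pop; ++p) popmean[p] /= pop_size[p];

  // recording buffers
  int n_samp = (record_every > 0) ? n_steps / record_every : 0;
  int nG = sym_groups.size(), nK = param_groups.size();
  NumericVector rec_time(n_samp);
  NumericMatrix rec_rates(n_samp, n_pop), rec_sym(n_samp, nG);
  NumericMatrix rec_trec(n_samp, nK), rec_U(n_samp, nK), rec_tfac(n_samp, nK);
  std::vector<int> ras_step, ras_neuron;

  int ev = 0;                        // cursor into the stimulus event list
  const int n_ev = stim_step.size();
  std::vector<double> m2pre(N), o2pre(N), m1pre(N), o1pre(N);

  // raw column-major views of the hot matrices
  double *pg = REAL(g), *pr = REAL(r), *pu = REAL(u), *pU = REAL(Umat);
  double *ptr_ = REAL(trec), *ptf = REAL(tfac), *pA = REAL(A);
  double *pDr = REAL(Drec), *pDf = REAL(Dfac), *pdA = REAL(dA);
  int *pmask = LOGICAL(mask);
  const int NN = N * N;

  for (int s = 0; s < n_steps; ++s) {
    double t_now = t0 + s * dt;

    // 1. stimulus pulses due this step (events sorted by step)
    while (ev < n_ev && stim_step[ev] == s) {
      int n = stim_neuron[ev];
      if (t_now >= ref_until[n]) V[n] += stim_amp;  // absorbed if refractory
      ++ev;
    }
    while (ev < n_ev && stim_step[ev] < s) ++ev;

    // 2. continuous decays
    for (int k = 0; k < NN; ++k) {
      pg[k] *= eg;
      pr[k] += (1.0 - pr[k]) * (1.0 - pDr[k]);
      pu[k] += (pU[k] - pu[k]) * (1.0 - pDf[k]);
    }
    for (int i = 0; i < N; ++i) {
      m1[i] *= dm1; m2[i] *= dm2; o1[i] *= do1; o2[i] *= do2;
    }

    // 3. membrane Euler step (refractory neurons clamped at 0)
    {
      std::vector<double> gin(N, 0.0);
      for (int j = 0; j < N; ++j) {
        const double *col = pg + (size_t)j * N;
        for (int i = 0; i < N; ++i) gin[i] += col[i];
      }
      for (int i = 0; i < N; ++i) {
        if (t_now < ref_until[i]) { V[i] = 0.0; continue; }
        V[i] += dt * (-gL * V[i] + gin[i] * (Erev - V[i]));
        if (!std::isfinite(V[i]))
          stop("membrane potential diverged at t = %f ms (neuron %d)", t_now, i + 1);
      }
    }

    // 4. threshold detection
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      if (t_now >= ref_until[i] && V[i] >= Vthr) {
        spikers.push_back(i);
        V[i] = 0.0;
        ref_until[i] = t_now + tref;
      }
    }

    if (!spikers.empty()) {
      if (record_raster)
        for (int i : spikers) { ras_step.push_back(s); ras_neuron.push_back(i); }

      // 5. presynaptic STP update + conductance injection (column j)
      for (int j : spikers) {
        const size_t off = (size_t)j * N;
        for (int i = 0; i < N; ++i) {
          if (i == j) continue;
          const size_t k = off + i;
          double rel;
          if (facil_first) {
            pu[k] += pU[k] * (1.0 - pu[k]);
            rel = pr[k] * pu[k];
            pr[k] -= rel;
          } else {
            rel = pr[k] * pu[k];
            pr[k] -= rel;
            pu[k] += pU[k] * (1.0 - pu[k]);
          }
          if (!refrac_gate || t_now >= ref_until[i])
            pg[k] += rel * pA[k] * g_scale;
        }
      }

      // 6. triplet STDP from pre-increment traces
      for (int i = 0; i < N; ++i) {
        m1pre[i] = m1[i]; m2pre[i] = m2[i];
        o1pre[i] = o1[i]; o2pre[i] = o2[i];
      }
      for (int i : spikers) {
        double pot = gamma * (A2p + A3p * o2pre[i]);
        double dep = gamma * (A2m + A3m * m2pre[i]);
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          size_t kij = (size_t)j * N + i;   // synapse j -> i
          size_t kji = (size_t)i * N + j;   // synapse i -> j
          if (pmask[kij]) pdA[kij] += pot * m1pre[j];   // LTP on incoming
          if (pmask[kji]) pdA[kji] -= dep * o1pre[j];   // LTD on outgoing
        }
      }

      // 7. trace increments
      for (int i : spikers) { m1[i] += 1; m2[i] += 1; o1[i] += 1; o2[i] += 1; }

      // 8. error-driven STP learning on incoming synapses of each spiker
      for (int i : spikers) {
        int p = pop[i] - 1;
        double err = targets[p] - popmean[p];          // Hz
        if (err == 0.0) continue;
        double eta = eta_bar * std::pow(1.0 + err / nu_lim, 2) * scale;
        double nl2 = nu_lim * nu_lim;
        for (int j = 0; j < N; ++j) {
          size_t k = (size_t)j * N + i;                // synapse j -> i
          if (j == i || !pmask[k]) continue;
          double trs = ptr_[k] / 1000.0;               // seconds in the rules
          double a = pA[k];
          if (lA) pdA[k] += 2.0 * gamma * scale * err / (nl2 * trs);
          if (lTR) {
            double v = ptr_[k] - 2.0 * eta * err * a / (nl2 * trs * trs) * 1000.0;
            ptr_[k] = std::min(trmax, std::max(trmin, v));
            pDr[k] = std::exp(-dt / ptr_[k]);
          }
          if (lU) {
            double v = pU[k] - 2.0 * eta * err * a / (nl2 * pU[k] * pU[k]);
            pU[k] = std::min(Umax, std::max(Umin, v));
          }
          if (lTF) {
            double v = ptf[k] + 2.0 * eta * err * a / nl2 * 1000.0;
            ptf[k] = std::min(tfmax, std::max(tfmin, v));
            pDf[k] = std::exp(-dt / ptf[k]);
          }
        }
      }

      // 9. one clipped update of the maximum strengths
      for (int k = 0; k < NN; ++k) {
        if (pdA[k] == 0.0) continue;
        double v = pA[k] + pdA[k];
        pA[k] = std::min(Amax, std::max(Amin, v));
        pdA[k] = 0.0;
      }
    }

    // 10. rate EMA (unit impulse per spike, capped at the refractory limit)
    for (int i = 0; i < N; ++i) nu[i] *= enu;
    for (int i : spikers) nu[i] = std::min(nu[i] + 1.0, nu_lim);
    std::fill(popmean.begin(), popmean.end(), 0.0);
    for (int i = 0; i < N; ++i) popmean[pop[i] - 1] += nu[i];
    for (int p = 0; p < n_pop; ++p) popmean[p] /= pop_size[p];

    // 11. recording
    if (record_every > 0 && (s + 1) % record_every == 0) {
      int k = (s + 1) / record_every - 1;
      rec_time[k] = t0 + (s + 1) * dt;
      for (int p = 0; p < n_pop; ++p) rec_rates(k, p) = popmean[p];
      for (int gidx = 0; gidx < nG; ++gidx)
        rec_sym(k, gidx) = symmetry_sub(A, as<IntegerVector>(sym_groups[gidx]));
      for (int kk = 0; kk < nK; ++kk) {
        List pg = param_groups[kk];
        IntegerVector tg = pg["targets"], sc = pg["sources"];
        rec_trec(k, kk) = group_mean(trec, mask, tg, sc);
        rec_U(k, kk) = group_mean(Umat, mask, tg, sc);
        rec_tfac(k, kk) = group_mean(tfac, mask, tg, sc);
      }
    }
  }

  List rec = List::create(
    _["time_ms"] = rec_time, _["rates"] = rec_rates, _["symmetry"] = rec_sym,
    _["tau_rec"] = rec_trec, _["U"] = rec_U, _["tau_facil"] = rec_tfac);
  List out = List::create(
    _["V"] = V, _["ref_until"] = ref_until, _["g"] = g, _["r"] = r,
    _["u"] = u, _["U"] = Umat, _["tau_rec"] = trec, _["tau_facil"] = tfac,
    _["A"] = A, _["m1"] = m1, _["m2"] = m2, _["o1"] = o1, _["o2"] = o2,
    _["nu"] = nu, _["rec"] = rec);
  if (record_raster)
    out["raster"] = List::create(_["step"] = wrap(ras_step),
                                 _["neuron"] = wrap(ras_neuron));
  return out;
}

// Symmetry index of a weight matrix (exported for the analysis module).
// [[Rcpp::export]]
List symmetry_index_cpp(NumericMatrix A) {
  int n = A.nrow();
  double acc = 0.0;
  int M = 0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double x = A(a, b), y = A(b, a);
      if (x == 0.0 && y == 0.0) { ++M; continue; }
      acc += std::fabs(x - y) / (x + y);
    }
  double denom = n * (n - 1) - 2.0 * M;
  double s = (denom > 0) ? 1.0 - 2.0 * acc / denom : NA_REAL;
  return List::create(_["s"] = s, _["M"] = M);
}
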