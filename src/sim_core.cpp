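// Hot loop of the embodied working-memory simulator.
//
// One call advances the network across a single stimulus phase (constant
// external current). Per step, in order:
//   1. exact exponential decay of the STP variables (u -> U, x -> 1)
//   2. delivery of background spikes falling in [t, t+dt): STP jump of the
//      source unit, current injection through its efferent column
//   3. exponential decay + impulse update of I_syn
//   4. forward-Euler update of the aEIF membrane and adaptation equations,
//      threshold test, reset (V -> E_L, w -> w + b_w)
//   5. STP jump and (optionally) recurrent current delivery for this step's
//      somatic spikes
//   6. nearest-neighbour multiplicative STDP for this step's spikes, with
//      structural growth of absent synapses
// Matrix orientation: J(i, j), C(i, j) = synapse from presynaptic j onto
// postsynaptic i (column j = efferents of unit j).
//
// The R-level functions membrane_step(), stp_decay(), stp_on_spike(),
// stdp_delta(), apply_stdp() and syn_current_step() define the same rules
// and serve as the oracle for this core in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EXP_ARG_CLAMP = 20.0;

static inline double stdp_dj(double J, double delta_t, double lam_p,
                             double lam_m, double tau_p, double tau_m,
                             double mu, double alpha) {
  // beyond ~50 window constants the factor (< 2e-22) is smaller than one
  // ulp of any weight of interest; skip the exp
  if (delta_t > 50.0 * tau_p || delta_t < -50.0 * tau_m) return 0.0;
  if (delta_t > 0.0) {
    double f = 1.0 - J;
    double fp = (mu == 1.0) ? f : ((f < 0 ? -1.0 : 1.0) * std::pow(std::fabs(f), mu));
    return lam_p * fp * std::exp(-delta_t / tau_p);
  }
  double fm = (mu == 1.0) ? J : ((J < 0 ? -1.0 : 1.0) * std::pow(std::fabs(J), mu));
  return -lam_m * alpha * fm * std::exp(delta_t / tau_m);
}

// Continuous STDP evaluation: while a pair's most recent spikes are fixed,
// the per-evaluation update J += stdp_dj(J, dt_pair) applied every eval_dt
// is a linear recurrence with the exact closed form
//   LTP state (dt_pair > 0):  1-J  <-  (1-J) * (1 - lam_p K)^n
//   LTD state (dt_pair <= 0):   J  <-    J   * (1 - lam_m a K')^n
// (mu = 1), n = elapsed/eval_dt. The matrix t_sync records, per synapse,
// the time up to which the accrual has been committed.

// [[Rcpp::export]]
List sim_phase_cpp(NumericMatrix J, IntegerMatrix C,
                   NumericVector V, NumericVector w,
                   NumericVector u, NumericVector x,
                   NumericVector I_syn, NumericVector last_spike,
                   double t0, double t_end, double dt,
                   NumericVector I_ext,
                   List bg_trains, IntegerVector bg_pos,
                   List np, List pp,
                   bool transmit_somatic, bool background_drives_stdp,
                   bool allow_self,
                   double record_every,
                   bool stdp_continuous, double stdp_eval_dt,
                   NumericMatrix t_sync) {
  const int N = J.nrow();
  const double C_m = np["C_m"], g_L = np["g_L"], E_L = np["E_L"],
               V_T = np["V_T"], Delta_T = np["Delta_T"], tau_w = np["tau_w"],
               a_w = np["a_w"], b_w = np["b_w"], tau_syn = np["tau_syn"];
  const double tau_f = pp["tau_f"], tau_d = pp["tau_d"], U = pp["U"],
               tau_p = pp["tau_plus"], tau_m = pp["tau_minus"],
               lam_p = pp["lambda_plus"], lam_m = pp["lambda_minus"],
               mu = pp["mu"], alpha = pp["alpha"], g_scale = pp["g_scale"];

  const double dec_f = std::exp(-dt / tau_f);
  const double dec_d = std::exp(-dt / tau_d);
  const double dec_s = std::exp(-dt / tau_syn);

  const long nsteps = (long)std::llround((t_end - t0) / dt);

  double* Jp = REAL(J);
  int* Cp = INTEGER(C);
  double* Sp = stdp_continuous ? REAL(t_sync) : (double*)0;
  const double* lsp0 = last_spike.begin();

  // commit the continuous accrual of synapse j->i (pre j, post i) up to
  // time tn, using the pair's current last-spike times
  auto sync_syn = [&](int i, int j, double tn) {
    size_t idx = (size_t)i + (size_t)N * j;
    double li = lsp0[i], lj = lsp0[j];
    if (std::isnan(li) || std::isnan(lj)) { Sp[idx] = tn; return; }
    double T = tn - Sp[idx];
    if (T <= 0) { Sp[idx] = tn; return; }
    Sp[idx] = tn;
    double n = T / stdp_eval_dt;
    double dtp = li - lj;
    double Jv = Cp[idx] ? Jp[idx] : 0.0;
    if (dtp > 0.0) {                          // LTP state
      if (dtp < 50.0 * tau_p) {
        double K = lam_p * std::exp(-dtp / tau_p);
        Jv = 1.0 - (1.0 - Jv) * std::exp(n * std::log1p(-K));
      }
    } else {                                  // LTD state
      if (dtp > -50.0 * tau_m && Jv != 0.0) {
        double K = lam_m * alpha * std::exp(dtp / tau_m);
        Jv = Jv * std::exp(n * std::log1p(-K));
      }
    }
    Jp[idx] = std::min(1.0, std::max(-1.0, Jv));
    Cp[idx] = 1;
  };
  auto sync_col = [&](int j, double tn) {
    for (int i = 0; i < N; ++i) {
      if (i == j && !allow_self) continue;
      sync_syn(i, j, tn);
    }
  };
  auto sync_all = [&](double tn) {
    for (int j = 0; j < N; ++j) sync_col(j, tn);
  };

  // background trains: raw views extracted once (the hot loop must not
  // re-wrap R objects)
  std::vector<const double*> bgp(N);
  std::vector<int> bgn(N);
  for (int j = 0; j < N; ++j) {
    NumericVector train = bg_trains[j];
    bgp[j] = train.begin();
    bgn[j] = train.size();
  }

  std::vector<double> sp_t;   sp_t.reserve(4096);
  std::vector<int>    sp_u;   sp_u.reserve(4096);
  std::vector<double> tr_t, tr_meanJ, tr_density;
  std::vector<double> incoming(N);
  std::vector<int> spikers;   spikers.reserve(64);

  double t = t0;
  double next_rec = (record_every > 0) ? t0 : R_PosInf;

  // local copies of per-unit bg cursors
  std::vector<int> pos(bg_pos.begin(), bg_pos.end());

  for (long step = 0; step < nsteps; ++step) {
    // additive clock: bit-identical to the R reference functions, which
    // advance state$t by dt per step
    double t_next = t + dt;

    // 1. STP inter-spike decay
    for (int j = 0; j < N; ++j) {
      u[j] = U + (u[j] - U) * dec_f;
      x[j] = 1.0 + (x[j] - 1.0) * dec_d;
    }

    // 2. background spikes in [t, t_next)
    std::fill(incoming.begin(), incoming.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      const double* train = bgp[j];
      int k = pos[j], nk = bgn[j];
      while (k < nk && train[k] < t_next) {
        double tb = train[k];
        double u2 = u[j] + U * (1.0 - u[j]);
        double release = u2 * x[j];
        x[j] = (1.0 - u2) * x[j];
        u[j] = u2;
        if (stdp_continuous) {
          sync_col(j, t);    // commit accrual before reading the column
          if (background_drives_stdp) last_spike[j] = tb;
        }
        // absent synapses carry J = 0, so the C mask is redundant here
        const double amp = g_scale * release;
        const double* Jcol = Jp + (size_t)N * j;
        for (int i = 0; i < N; ++i) incoming[i] += amp * Jcol[i];
        if (background_drives_stdp && !stdp_continuous) {
          // the background event acts as a presynaptic spike of j: it
          // triggers the LTD branch on j's efferents and becomes j's most
          // recent spike for later pairings
          for (int i = 0; i < N; ++i) {
            if (i == j && !allow_self) continue;
            double li = last_spike[i];
            if (std::isnan(li)) continue;
            double Jij = C(i, j) ? J(i, j) : 0.0;
            double nj = Jij + stdp_dj(Jij, li - tb, lam_p, lam_m,
                                      tau_p, tau_m, mu, alpha);
            J(i, j) = std::min(1.0, std::max(-1.0, nj));
            C(i, j) = 1;
          }
          last_spike[j] = tb;
        }
        ++k;
      }
      pos[j] = k;
    }

    // 3. synaptic current decay + impulses
    for (int i = 0; i < N; ++i)
      I_syn[i] = I_syn[i] * dec_s + incoming[i];

    // 4. membrane + adaptation Euler step, threshold, reset
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      double arg = (V[i] - V_T) / Delta_T;
      if (arg > EXP_ARG_CLAMP) arg = EXP_ARG_CLAMP;
      double dV = (-g_L * (V[i] - E_L) + g_L * Delta_T * std::exp(arg)
                   - w[i] + I_syn[i] + I_ext[i]) / C_m;
      double dw = (a_w * (V[i] - E_L) - w[i]) / tau_w;
      V[i] += dt * dV;
      w[i] += dt * dw;
      if (!std::isfinite(V[i]) || !std::isfinite(w[i]))
        stop("sim_phase_cpp: non-finite state at t = %f ms (unit %d); "
             "numerical blow-up, reduce dt", t_next, i + 1);
      if (V[i] > V_T) {
        V[i] = E_L;
        w[i] += b_w;
        spikers.push_back(i);
      }
    }

    if (!spikers.empty()) {
      for (int s : spikers) {
        sp_t.push_back(t_next);
        sp_u.push_back(s + 1);
      }
      if (stdp_continuous) {
        // commit each spiker's pair accruals under the pre-spike timing,
        // then advance its last-spike time (sequential over co-spikers)
        for (int s : spikers) {
          for (int p = 0; p < N; ++p) {
            if (p == s) { if (allow_self) sync_syn(s, s, t_next); continue; }
            sync_syn(s, p, t_next);
            sync_syn(p, s, t_next);
          }
          last_spike[s] = t_next;
        }
      } else {
        for (int s : spikers) last_spike[s] = t_next;
      }

      // 5. STP jump + recurrent delivery for somatic spikes
      for (int s : spikers) {
        double u2 = u[s] + U * (1.0 - u[s]);
        double release = u2 * x[s];
        x[s] = (1.0 - u2) * x[s];
        u[s] = u2;
        if (transmit_somatic) {
          const double amp = g_scale * release;
          const double* Jcol = Jp + (size_t)N * s;
          double* Ip = I_syn.begin();
          for (int i = 0; i < N; ++i) Ip[i] += amp * Jcol[i];
        }
      }

      // 6. event-wise nearest-neighbour STDP with structural growth
      if (!stdp_continuous) for (int s : spikers) {
        const double* lsp = last_spike.begin();
        double* Jrow = Jp + s;              // J(s, .) strided by N
        int* Crow = Cp + s;
        double* Jcol = Jp + (size_t)N * s;  // J(., s) contiguous
        int* Ccol = Cp + (size_t)N * s;
        for (int p = 0; p < N; ++p) {
          if (p == s && !allow_self) continue;
          double lp = lsp[p];
          if (std::isnan(lp)) continue;
          // s as postsynaptic: synapse p -> s, delta_t = t_next - lp
          double Jsp = Crow[(size_t)N * p] ? Jrow[(size_t)N * p] : 0.0;
          double nsp = Jsp + stdp_dj(Jsp, t_next - lp, lam_p, lam_m,
                                     tau_p, tau_m, mu, alpha);
          Jrow[(size_t)N * p] = std::min(1.0, std::max(-1.0, nsp));
          Crow[(size_t)N * p] = 1;
          // s as presynaptic: synapse s -> p, delta_t = lp - t_next <= 0
          double Jps = Ccol[p] ? Jcol[p] : 0.0;
          double nps = Jps + stdp_dj(Jps, lp - t_next, lam_p, lam_m,
                                     tau_p, tau_m, mu, alpha);
          Jcol[p] = std::min(1.0, std::max(-1.0, nps));
          Ccol[p] = 1;
        }
      }
    }

    t = t_next;

    if (t >= next_rec - 1e-9) {
      if (stdp_continuous) sync_all(t);
      long npresent = 0; double sumJ = 0.0;
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i)
          if (C(i, j)) { ++npresent; sumJ += J(i, j); }
      tr_t.push_back(t);
      tr_meanJ.push_back(npresent ? sumJ / npresent : NA_REAL);
      tr_density.push_back((double)npresent / ((double)N * (N - 1)));
      next_rec += record_every;
    }
  }

  if (stdp_continuous) sync_all(t);

  return List::create(
    _["t"] = t,
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_unit"] = IntegerVector(sp_u.begin(), sp_u.end()),
    _["bg_pos"] = IntegerVector(pos.begin(), pos.end()),
    _["trace_t"] = NumericVector(tr_t.begin(), tr_t.end()),
    _["trace_mean_J"] = NumericVector(tr_meanJ.begin(), tr_meanJ.end()),
    _["trace_density"] = NumericVector(tr_density.begin(), tr_density.end()));
}
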