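#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact (modified Gillespie) simulation of one cell between deterministic
// cell-cycle events. Seven reaction channels per gene plus one volume
// channel; volume-dependent channels carry a Vref/V factor; the volume
// channel fires at (growth rate)/dV and adds the fixed quantum dV.
// Scheduled events (S entry -> promoter replication; division or t_end ->
// stop) are interleaved by the next-event-time rule: a sampled reaction
// that would land past the next scheduled event is rejected and
// propensities are recomputed at the event.
//
// rates: 7 x n matrix, rows r_act, r_off, rm_true, b_true, r_p, d_m, d_p.
// noise: 5 multiplicative factors (promoter switching, transcription,
//        translation, mRNA decay, protein decay).
// ff_par: S3, S1, S80, alpha, beta, g (inducer coupling already applied).
// ff_idx: 0-based gene indices of Gal3p, Gal1p, Gal80p (-1 = absent);
//         ff_type 0 => F identically 1.
// trace: state recorded at multiples of snap_dt (absolute time), columns
//        time, V, mRNA and protein and ON-promoter count of gene 0.

static inline double gal_F(const double *prot, double V, double Vref,
                           const double *ff, const int *idx) {
  const double g = ff[5];
  double c3 = idx[0] >= 0 ? prot[idx[0]] * Vref / V : 0.0;
  double c1 = idx[1] >= 0 ? prot[idx[1]] * Vref / V : 0.0;
  double c80 = idx[2] >= 0 ? prot[idx[2]] * Vref / V : 0.0;
  if (c80 <= 0.0) return 1.0;
  double act = ff[0] * g * c3 + ff[1] * g * c1;
  double ratio = ff[2] * c80 / (1.0 + std::pow(act, ff[3]));
  return 1.0 / (1.0 + std::pow(ratio, ff[4]));
}

// [[Rcpp::export]]
List ssa_cell_kernel(IntegerVector pr_on0, IntegerVector pr_off0,
                     NumericVector mrna0, NumericVector prot0,
                     double V0, double t0, double t_end,
                     double t_s_entry, double t_division, bool replicated,
                     double r_growth1, double r_growth2, double dV,
                     NumericMatrix rates, NumericVector noise, double Vref,
                     int ff_type, NumericVector ff_par, IntegerVector ff_idx,
                     double snap_dt, bool scale_decay = true) {
  const int n = rates.ncol();
  std::vector<int> pr_on(pr_on0.begin(), pr_on0.end());
  std::vector<int> pr_off(pr_off0.begin(), pr_off0.end());
  std::vector<double> R(mrna0.begin(), mrna0.end());
  std::vector<double> P(prot0.begin(), prot0.end());
  double V = V0, t = t0;
  const double *ffp = ff_par.begin();
  int idx[3] = {ff_idx[0], ff_idx[1], ff_idx[2]};
  const double n_sw = noise[0], n_tx = noise[1], n_tl = noise[2],
               n_md = noise[3], n_pd = noise[4];

  std::vector<double> a(7 * n + 1);
  std::vector<double> trace;
  double next_snap = R_PosInf;
  if (snap_dt > 0) next_snap = std::ceil(t0 / snap_dt) * snap_dt;
  const double t_stop = std::min(t_end, t_division);
  long n_events = 0;

  auto record_until = [&](double upto) {
    while (next_snap <= upto + 1e-9) {
      trace.push_back(next_snap); trace.push_back(V);
      trace.push_back(R[0]); trace.push_back(P[0]);
      trace.push_back((double)pr_on[0]);
      next_snap += snap_dt;
    }
  };

  for (;;) {
    const double s = Vref / V;
    const double F = (ff_type == 1) ? gal_F(P.data(), V, Vref, ffp, idx) : 1.0;
    double a_tot = 0.0;
    for (int x = 0; x < n; ++x) {
      const double r_act = rates(0, x), r_off = rates(1, x),
                   rm = rates(2, x), bt = rates(3, x), rp = rates(4, x),
                   dm = rates(5, x), dp = rates(6, x);
      const double sd = scale_decay ? s : 1.0;
      double *ax = &a[7 * x];
      ax[0] = n_sw * r_act * F * pr_off[x];
      ax[1] = n_sw * r_off * pr_on[x];
      ax[2] = n_tx * rm * bt * pr_off[x] * s;
      ax[3] = n_tx * rm * pr_on[x] * s;
      ax[4] = n_md * dm * R[x] * sd;
      ax[5] = n_tl * rp * R[x] * s;
      ax[6] = n_pd * dp * P[x] * sd;
      a_tot += ax[0] + ax[1] + ax[2] + ax[3] + ax[4] + ax[5] + ax[6];
    }
    const double rg = (t < t_s_entry) ? r_growth1 : r_growth2;
    a[7 * n] = (dV > 0) ? rg / dV : 0.0;
    a_tot += a[7 * n];

    double t_next = (a_tot > 0) ? t + exp_rand() / a_tot : R_PosInf;
    double t_event = replicated ? t_stop : std::min(t_s_entry, t_stop);

    if (t_next >= t_event) {
      record_until(t_event);
      t = t_event;
      if (!replicated && t_s_entry <= t_stop && t_event == t_s_entry) {
        for (int x = 0; x < n; ++x) { pr_on[x] *= 2; pr_off[x] *= 2; }
        replicated = true;
        continue;
      }
      break;  // division or t_end
    }

    record_until(t_next);
    t = t_next;
    ++n_events;
    double u = unif_rand() * a_tot;
    int ch = 7 * n;  // default: volume channel
    for (int i = 0; i < 7 * n + 1; ++i) {
      if (u < a[i]) { ch = i; break; }
      u -= a[i];
    }
    if (ch == 7 * n) {
      V += dV;
    } else {
      int x = ch / 7;
      switch (ch % 7) {
      case 0: --pr_off[x]; ++pr_on[x]; break;
      case 1: --pr_on[x]; ++pr_off[x]; break;
      case 2: case 3: R[x] += 1; break;
      case 4: R[x] -= 1; break;
      case 5: P[x] += 1; break;
      case 6: P[x] -= 1; break;
      }
    }
  }

  NumericMatrix tr(trace.size() / 5, 5);
  for (size_t i = 0; i < trace.size() / 5; ++i)
    for (int j = 0; j < 5; ++j) tr(i, j) = trace[5 * i + j];
  colnames(tr) = CharacterVector::create("time", "V", "mrna0", "prot0", "pr_on0");

  return List::create(
      _["pr_on"] = IntegerVector(pr_on.begin(), pr_on.end()),
      _["pr_off"] = IntegerVector(pr_off.begin(), pr_off.end()),
      _["mrna"] = NumericVector(R.begin(), R.end()),
      _["prot"] = NumericVector(P.begin(), P.end()),
      _["V"] = V, _["t"] = t, _["replicated"] = replicated,
      _["n_events"] = (double)n_events,
      _["reason"] = (t >= t_division - 1e-12) ? "division" : "t_end",
      _["trace"] = tr);
}
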