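#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Ensemble driver: advances every cluster through n_days simulated days.
//
// Within-day semantics (synchronous update): per cluster,
//   (a) snapshot N_st and per-synapse strong flags from the start-of-day
//       state; these feed both the mean LTP amplitude and regeneration;
//   (b) every day-start-active synapse draws r1 (mean a1(N_st)) then r2
//       (mean a2) and receives dW = A_LTP - A_LTD;
//   (c) active synapses whose updated W fell below T_wk are silenced
//       (W = W_sil);
//   (d) every day-start-silent synapse draws one uniform and regenerates
//       (W = W_reset, active) with probability P_bas * N_st / N_cl, gated on
//       a chain-adjacent synapse having been strong at day start.
// A synapse silenced in (c) cannot regenerate the same day.
//
// Draw order is fixed (clusters in index order; pass (b) then pass (d),
// synapses in index order, r1 before r2) and uses R's RNG, so the R-level
// step_cluster() reference loop reproduces trajectories exactly.

// [[Rcpp::export]]
List run_engine(NumericMatrix W0, LogicalMatrix A0, List par, int n_days,
                int record_every, bool rec_weights, bool rec_deltas,
                bool rec_nstrong) {
  const int ncl = W0.nrow();
  const int C = W0.ncol();
  const int nsyn = ncl * C;

  NumericMatrix W = clone(W0);
  LogicalMatrix A = clone(A0);

  const double w_reset = par["w_reset"], w_sil = par["w_sil"],
    t_wk = par["t_wk"], t_st = par["t_st"], v_hi = par["v_hi"],
    v_lo = par["v_lo"], w_med = par["w_med"], x1 = par["x1"],
    x2 = par["x2"], a2 = par["a2"], sd_ratio = par["sd_ratio"],
    k_hi = par["k_hi"], w_hi = par["w_hi"], p_bas = par["p_bas"],
    a1_fixed = par["a1_fixed"], sd1_fixed = par["sd1_fixed"],
    lambda1 = par["lambda1"], lambda2 = par["lambda2"];
  const std::string variant = as<std::string>(par["variant"]);
  const bool fixed_ltp = variant == "fixed_ltp";
  const bool no_regen = variant == "no_regeneration";
  const bool expo = variant == "exponential_increments";
  const double sd2 = a2 / sd_ratio;

  const int n_rec = (record_every > 0) ? n_days / record_every : 0;
  IntegerVector rec_days(n_rec);
  IntegerVector rec_nact(n_rec);
  NumericVector rec_meanw(n_rec), rec_meanw_act(n_rec);
  NumericMatrix Wrec(rec_weights ? n_rec : 0, rec_weights ? nsyn : 0);
  LogicalMatrix Arec(rec_weights ? n_rec : 0, rec_weights ? nsyn : 0);
  NumericMatrix WPrec(rec_deltas ? n_rec : 0, rec_deltas ? nsyn : 0);
  NumericMatrix DWrec(rec_deltas ? n_rec : 0, rec_deltas ? nsyn : 0);
  IntegerMatrix NSTrec(rec_nstrong ? n_rec : 0, rec_nstrong ? C : 0);

  std::vector<char> strong(ncl), was_sil(ncl);
  std::vector<double> dw_day(nsyn), wpre_day(nsyn);
  std::vector<int> nst_day(C);

  int r = 0;
  for (int d = 1; d <= n_days; ++d) {
    const bool rec = record_every > 0 && (d % record_every == 0);
    for (int c = 0; c < C; ++c) {
      int nst = 0;
      for (int i = 0; i < ncl; ++i) {
        const bool s = A(i, c) && W(i, c) > t_st;
        strong[i] = s;
        if (s) ++nst;
        was_sil[i] = !A(i, c);
      }
      const double a1 = fixed_ltp ? a1_fixed : x2 - (x2 - x1) * nst / ncl;
      const double sd1 = fixed_ltp ? sd1_fixed : a1 / sd_ratio;

      for (int i = 0; i < ncl; ++i) {
        const int k = c * ncl + i;
        if (!A(i, c)) {
          if (rec && rec_deltas) {
            dw_day[k] = NA_REAL;
            wpre_day[k] = W(i, c);
          }
          continue;
        }
        const double w = W(i, c);
        double r1, r2;
        if (expo) {
          r1 = R::rexp(1.0 / lambda1);
          r2 = R::rexp(1.0 / lambda2);
        } else {
          r1 = R::rnorm(a1, sd1);
          if (r1 < 0) r1 = 0;
          r2 = R::rnorm(a2, sd2);
          if (r2 < 0) r2 = 0;
        }
        const double vo = v_hi - (v_hi - v_lo) * w / (w + w_med);
        const double a_ltp = w * r1 * vo * (1 - k_hi * w / (w + w_hi));
        const double a_ltd = w * r2 * vo;
        const double dwi = a_ltp - a_ltd;
        if (rec && rec_deltas) {
          dw_day[k] = dwi;
          wpre_day[k] = w;
        }
        W(i, c) = w + dwi;
      }

      for (int i = 0; i < ncl; ++i) {
        if (A(i, c) && W(i, c) < t_wk) {
          A(i, c) = false;
          W(i, c) = w_sil;
        }
      }

      for (int i = 0; i < ncl; ++i) {
        if (!was_sil[i]) continue;
        const double u = R::unif_rand();
        if (no_regen) continue;
        const bool gate = (i > 0 && strong[i - 1]) ||
                          (i < ncl - 1 && strong[i + 1]);
        const double pact = p_bas * nst / ncl;
        if (gate && u < pact) {
          A(i, c) = true;
          W(i, c) = w_reset;
        }
      }
      if (rec && rec_nstrong) nst_day[c] = nst;
    }

    if (rec) {
      rec_days[r] = d;
      int nact = 0;
      double sw = 0.0, swa = 0.0;
      for (int c = 0; c < C; ++c) {
        for (int i = 0; i < ncl; ++i) {
          const int k = c * ncl + i;
          const double w = W(i, c);
          sw += w;
          if (A(i, c)) {
            ++nact;
            swa += w;
          }
          if (rec_weights) {
            Wrec(r, k) = w;
            Arec(r, k) = A(i, c);
          }
          if (rec_deltas) {
            WPrec(r, k) = wpre_day[k];
            DWrec(r, k) = dw_day[k];
          }
        }
        if (rec_nstrong) NSTrec(r, c) = nst_day[c];
      }
      rec_nact[r] = nact;
      rec_meanw[r] = sw / nsyn;
      rec_meanw_act[r] = nact > 0 ? swa / nact : NA_REAL;
      ++r;
    }
    if (d % 10000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["w"] = W, _["active"] = A, _["rec_days"] = rec_days,
    _["w_rec"] = Wrec, _["active_rec"] = Arec, _["w_pre_rec"] = WPrec,
    _["dw_rec"] = DWrec, _["n_strong_rec"] = NSTrec,
    _["n_active"] = rec_nact, _["mean_w"] = rec_meanw,
    _["mean_w_active"] = rec_meanw_act);
}
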