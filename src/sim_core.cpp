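// Evolutionary loop: one game round (pairwise play/abstain draws, counter
// updates) followed by asynchronous predictive strategy revision.  The
// forecast tables (engagement p_t and the horizon-summed play forecasts)
// are computed in R by the exported forecast functions and passed in, so
// the compiled core only does bookkeeping, sampling and linear algebra on
// them.  All randomness flows through R's RNG (set.seed() reproduces runs).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// strat0: 1 = C, 0 = D.
// hmode: 0 = finite horizon (uses the scc/scd tables), 1 = infinite
//        (threshold rule on rho = P_inf / (1 - P_inf)).
// stop_mode: 0 = stop on absorption, 1 = stop at first strategy flip,
//            2 = never stop early (forced continuation).
// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(IntegerVector xadj, IntegerVector adjn, IntegerVector rev,
                 IntegerVector strat0, double r, double delta,
                 NumericVector ptab, NumericVector scc, NumericVector scd,
                 int hmode, double rho, bool allc_absorbing,
                 int max_rounds, int stop_mode,
                 double noise_sd, double flip_prob, bool record)
{
  const int N = xadj.size() - 1;
  const int ndir = adjn.size();
  const int t_cap = ptab.size() - 1;
  std::vector<int> t(ndir, 0);
  std::vector<int> strat(strat0.begin(), strat0.end());
  int nC = 0;
  for (int i = 0; i < N; ++i) nC += strat[i];
  long n_active = 0;

  const bool knobs = (noise_sd > 0.0) || (flip_prob > 0.0);
  const bool can_stop = (stop_mode == 0) && !knobs;

  NumericVector frac_C(record ? max_rounds : 0);
  NumericVector pay_C(record ? max_rounds : 0);
  NumericVector pay_D(record ? max_rounds : 0);
  IntegerVector inhib(record ? max_rounds : 0);

  int absorbed = 0;          // 0 none, 1 all-D, 2 all-C
  int absorption_round = -1;
  int first_CD = -1, first_DC = -1;
  int rounds_run = 0;

  std::vector<int> revisers;
  std::vector<char> decision;
  revisers.reserve(64);
  decision.reserve(64);

  RNGScope scope;

  for (int round = 1; round <= max_rounds; ++round) {
    // ---- play phase: iterate each undirected edge once (i < j slots) ----
    double totC = 0.0, totD = 0.0;
    n_active = 0;
    for (int i = 0; i < N; ++i) {
      for (int idx = xadj[i]; idx < xadj[i + 1]; ++idx) {
        int j = adjn[idx];
        if (j < i) continue;
        int d1 = idx, d2 = rev[idx];
        int t1 = t[d1], t2 = t[d2];
        bool part1 = true, part2 = true;
        if (t1 > 0) part1 = unif_rand() < ptab[t1];
        if (t2 > 0) part2 = unif_rand() < ptab[t2];
        bool played = part1 && part2;
        if (strat[i] == 1) { // i is C
          if (t1 > 0) {
            if (part1) t[d1] = (strat[j] == 0) ? 1 : 0;
            else t[d1] = (t1 >= t_cap) ? t_cap : t1 + 1;
          } else if (played && strat[j] == 0) {
            t[d1] = 1; // exploited while fully engaged
          }
        }
        if (strat[j] == 1) {
          if (t2 > 0) {
            if (part2) t[d2] = (strat[i] == 0) ? 1 : 0;
            else t[d2] = (t2 >= t_cap) ? t_cap : t2 + 1;
          } else if (played && strat[i] == 0) {
            t[d2] = 1;
          }
        }
        if (played) {
          if (strat[i] == 1 && strat[j] == 1) totC += 2.0 * (r - 1.0);
          else if (strat[i] != strat[j]) { totC += -1.0; totD += r; }
          // D-D: nothing
        }
        n_active += (t[d1] > 0) + (t[d2] > 0);
      }
    }

    // ---- revision phase: each agent flagged independently with prob delta
    const int nC_play = nC; // composition that earned this round's payoffs
    int nrev = (int) R::rbinom((double) N, delta);
    revisers.clear();
    decision.clear();
    if (nrev > 0) {
      // distinct uniform ids by rejection (nrev << N in the regimes used)
      for (int kdrawn = 0; kdrawn < nrev; ++kdrawn) {
        int id;
        bool dup;
        do {
          id = (int)(unif_rand() * N);
          if (id >= N) id = N - 1;
          dup = false;
          for (size_t q = 0; q < revisers.size(); ++q)
            if (revisers[q] == id) { dup = true; break; }
        } while (dup);
        revisers.push_back(id);
      }
      // decisions from the common post-round state
      for (size_t q = 0; q < revisers.size(); ++q) {
        int i = revisers[q];
        int k = xadj[i + 1] - xadj[i];
        double sCC = 0.0, sCDc = 0.0, sD = 0.0;
        int kC = 0;
        for (int idx = xadj[i]; idx < xadj[i + 1]; ++idx) {
          int tij = t[idx], tji = t[rev[idx]];
          if (strat[i] == 1) {
            if (tij > 0) sD += scd[tij];
            else { sCC += scc[tji]; sCDc += scd[tji]; ++kC; }
          } else {
            if (tji > 0) { sCC += scc[tji]; sCDc += scd[tji]; ++kC; }
            else sD += scd[1];
          }
        }
        bool sw;
        if (hmode == 1) {
          if (kC == 0) {
            sw = (strat[i] == 1); // isolated C defects; isolated D stays
          } else {
            double thr = 1.0 + ((double) k / (double) kC) * rho;
            sw = (strat[i] == 1) ? (r < thr) : (r > thr);
          }
        } else {
          double gain = (strat[i] == 1)
            ? (-r * (sCC - sCDc) + sCC + sD)
            : ( r * (sCC - sCDc) - sCC - sD);
          if (noise_sd > 0.0) gain *= (1.0 + noise_sd * norm_rand());
          sw = gain > 0.0;
        }
        if (flip_prob > 0.0 && unif_rand() < flip_prob) sw = !sw;
        decision.push_back(sw ? 1 : 0);
      }
      // apply simultaneously: C->D engagement resets first, then D->C
      bool anyCD = false, anyDC = false;
      for (size_t q = 0; q < revisers.size(); ++q) {
        if (!decision[q]) continue;
        int i = revisers[q];
        if (strat[i] == 1) {
          anyCD = true;
          for (int idx = xadj[i]; idx < xadj[i + 1]; ++idx) {
            if (t[idx] > 0) { t[idx] = 0; --n_active; }
          }
        }
      }
      for (size_t q = 0; q < revisers.size(); ++q) {
        if (!decision[q]) continue;
        int i = revisers[q];
        if (strat[i] == 0) {
          anyDC = true;
          for (int idx = xadj[i]; idx < xadj[i + 1]; ++idx) {
            if (t[rev[idx]] > 0) {
              if (t[idx] > 0) { t[idx] = 0; --n_active; }
            } else if (t[idx] == 0) {
              t[idx] = 1; ++n_active; // p_1 toward perceived defectors
            }
          }
        }
      }
      for (size_t q = 0; q < revisers.size(); ++q) {
        if (!decision[q]) continue;
        int i = revisers[q];
        if (strat[i] == 1) { strat[i] = 0; --nC; }
        else { strat[i] = 1; ++nC; }
      }
      if (anyCD && first_CD < 0) first_CD = round;
      if (anyDC && first_DC < 0) first_DC = round;
    }
    bool flip_stop = (stop_mode == 1) && (first_CD > 0 || first_DC > 0);

    rounds_run = round;
    if (record) {
      frac_C[round - 1] = (double) nC / N;
      pay_C[round - 1] = nC_play > 0 ? totC / nC_play : NA_REAL;
      pay_D[round - 1] = nC_play < N ? totD / (N - nC_play) : NA_REAL;
      inhib[round - 1] = (int) n_active;
    }

    // ---- absorption detection ----
    if (!knobs && absorbed == 0) {
      if (nC == 0) { absorbed = 1; absorption_round = round; }
      else if (nC == N && n_active == 0 && allc_absorbing) {
        absorbed = 2; absorption_round = round;
      }
    }
    if (flip_stop) break;
    if (can_stop && absorbed != 0) break;
  }

  List out = List::create(
    _["rounds"] = rounds_run,
    _["absorbed"] = absorbed,
    _["absorption_round"] = absorption_round,
    _["first_CD_round"] = first_CD,
    _["first_DC_round"] = first_DC,
    _["final_strategy"] = IntegerVector(strat.begin(), strat.end()),
    _["final_t"] = IntegerVector(t.begin(), t.end()),
    _["final_frac_C"] = (double) nC / N
  );
  if (record) {
    out["frac_C"] = frac_C[Range(0, rounds_run - 1)];
    out["pay_C"] = pay_C[Range(0, rounds_run - 1)];
    out["pay_D"] = pay_D[Range(0, rounds_run - 1)];
    out["inhibited"] = inhib[Range(0, rounds_run - 1)];
  }
  return out;
}
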