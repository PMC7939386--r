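#include <Rcpp.h>
using namespace Rcpp;

// Exponential waiting time for one transition; a FAST (infinite) rate
// resolves instantaneously. Uses R's RNG so set.seed() governs everything.
static inline double dwell(double rate) {
  if (!R_finite(rate)) return 0.0;
  return R::exp_rand() / rate;
}

// One processive run of the canonical stepping cycle, starting in the
// one-head-bound ATP-waiting state (state 3) at position start_nm.
// States follow the standard numbering: 3 ATP-waiting, 4 ATP-bound,
// 5 post-hydrolysis weak state (kinetic race), 6 two-heads-bound ADP,
// 7 two-heads-bound tight. Position advances by step_nm at the 6 -> 7
// transition (ADP release completes the step).
// Termination: 1 = detached, 2 = ran off the track end, 3 = capped at
// max_steps.
// [[Rcpp::export]]
List sim_run_cpp(double k_atp, double k_hyd, double kon_th, double k_detach,
                 double koff_adp, double koff_rh, double k_off_th,
                 double step_nm, double track_end_nm, double start_nm,
                 int max_steps, bool record) {
  RNGScope scope;
  double t = 0.0, pos = start_nm;
  int steps = 0, term = 3;

  std::vector<double> ev_state, ev_time, ev_pos;
  if (record) {
    ev_state.reserve(256); ev_time.reserve(256); ev_pos.reserve(256);
    ev_state.push_back(3); ev_time.push_back(0.0); ev_pos.push_back(pos);
  }
  auto log_ev = [&](int s) {
    if (record) {
      ev_state.push_back(s); ev_time.push_back(t); ev_pos.push_back(pos);
    }
  };

  while (steps < max_steps) {
    // the next step would carry the motor past the plus end: censored
    if (R_finite(track_end_nm) && pos + step_nm > track_end_nm) {
      term = 2;
      break;
    }
    t += dwell(k_atp);          // 3 -> 4, ATP binding
    log_ev(4);
    t += dwell(k_hyd);          // 4 -> 5, hydrolysis
    log_ev(5);

    // kinetic race out of the weak state: attach (-> 6) vs detach (-> end)
    bool detached;
    if (!R_finite(kon_th)) {
      detached = false;
    } else if (!R_finite(k_detach)) {
      detached = true;
    } else {
      double total = kon_th + k_detach;
      t += R::exp_rand() / total;
      detached = (R::unif_rand() * total < k_detach);
    }
    if (detached) {
      term = 1;
      log_ev(1);
      break;
    }
    // state 6: ADP release (-> 7) optionally races tethered-head release
    // (-> back to 5); reverse rate is 0 by default
    for (;;) {
      log_ev(6);
      if (k_off_th > 0 && R_finite(koff_adp)) {
        double total = koff_adp + k_off_th;
        t += R::exp_rand() / total;
        if (R::unif_rand() * total < k_off_th) {  // unbind, race again
          bool det2;
          if (!R_finite(kon_th)) det2 = false;
          else if (!R_finite(k_detach)) det2 = true;
          else {
            double tot2 = kon_th + k_detach;
            t += R::exp_rand() / tot2;
            det2 = (R::unif_rand() * tot2 < k_detach);
          }
          if (det2) { term = 1; break; }
          continue;
        }
      } else {
        t += dwell(koff_adp);
      }
      pos += step_nm;           // 6 -> 7 completes the mechanical step
      ++steps;
      log_ev(7);
      break;
    }
    if (term == 1) { log_ev(1); break; }
    t += dwell(koff_rh);        // 7 -> 3, rear-head detachment
    log_ev(3);
  }

  List out = List::create(
    _["n_steps"] = steps,
    _["total_time_s"] = t,
    _["final_position_nm"] = pos,
    _["termination"] = term);
  if (record) {
    int n = ev_state.size();
    NumericMatrix ev(n, 3);
    for (int i = 0; i < n; ++i) {
      ev(i, 0) = ev_state[i];
      ev(i, 1) = ev_time[i];
      ev(i, 2) = ev_pos[i];
    }
    colnames(ev) = CharacterVector::create("state", "t_s", "position_nm");
    out["events"] = ev;
  }
  return out;
}
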