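#include <Rcpp.h>
using namespace Rcpp;

// Forward time-marching integrator for the race dynamics.  Steps of at most
// dt; steps are additionally capped at command times and at the no-input
// penalty expiry so those state changes happen at their exact instants, and
// a field-boundary crossing inside a step is located by linear interpolation
// (speed is constant within a step).  kind: 0 = no-input, 1..3 = action
// fields whose correct command is kind-1.  cmd: 0 = rotate, 1 = jump,
// 2 = slide.  par: s_reward_action, s_default_noinput, s_default_action,
// s_punish_noinput, s_punish_action, t_max_punish_noinput.

static double speed_for(int state, int kind, const NumericVector& par) {
  // state: 0 default, 1 reward, 2 penalty
  if (kind == 0) return state == 2 ? par[3] : par[1];
  if (state == 1) return par[0];
  if (state == 2) return par[4];
  return par[2];
}

// [[Rcpp::export]]
double stepped_race_cpp(IntegerVector kind, NumericVector len,
                        NumericVector start, NumericVector cmd_time,
                        IntegerVector cmd, NumericVector par, double dt) {
  const int nf = kind.size();
  const int nc = cmd_time.size();
  const double eps = 1e-9;
  double t = 0.0, pos = 0.0, deadline = R_PosInf;
  int fi = 0, state = 0, ci = 0;

  while (fi < nf) {
    const double fend = start[fi] + len[fi];
    const double v = speed_for(state, kind[fi], par);
    double step = dt;
    if (ci < nc && cmd_time[ci] - t < step) step = cmd_time[ci] - t;
    if (deadline - t < step) step = deadline - t;
    if (step < 0.0) step = 0.0;
    const double newpos = pos + v * step;
    if (newpos >= fend) {
      // crossing within the step: interpolate, reset to default speed
      t += (fend - pos) / v;
      pos = fend;
      ++fi;
      state = 0;
      deadline = R_PosInf;
      continue;
    }
    t += step;
    pos = newpos;
    if (deadline <= t + eps) {  // no-input penalty timed out
      state = 0;
      deadline = R_PosInf;
    }
    while (ci < nc && cmd_time[ci] <= t + eps) {
      if (kind[fi] == 0) {
        state = 2;
        deadline = t + par[5];
      } else if (cmd[ci] == kind[fi] - 1) {
        state = 1;
        deadline = R_PosInf;
      } else {
        state = 2;
        deadline = R_PosInf;
      }
      ++ci;
    }
  }
  return t;
}
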