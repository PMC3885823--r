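#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Standard normal density of z.
static inline double dnorm_std(double z) {
  return M_1_SQRT_2PI * std::exp(-0.5 * z * z);
}

// Trial type codes (keep in sync with R/tasks.R)
enum TrialType {
  PAVLOVIAN = 0,   // reward at a scheduled step (or absent)
  PEAK_FI   = 1,   // reward at first "respond" at or after fi_step
  PEAK_PROBE = 2,  // actions sampled, never rewarded
  BIS_TRAIN = 3,   // choice window; correct anchor choice rewarded
  BIS_PROBE = 4    // choice window; never rewarded
};

// Fill the feature vector for step t of a trial.
// Layout: cue block (length B) then reward block (length B), B = D (microstimulus)
// or horizon (CSC). Gains are folded into the precomputed microstimulus tables.
struct FeatureGen {
  int kind;              // 0 microstimulus, 1 csc
  int B;                 // block length
  std::vector<double> mb_cue;   // (maxk x D), row-major: microstimulus blocks by steps-since-onset
  std::vector<double> mb_rew;
  const double *gc, *gr;        // csc gains (length horizon)

  void fill(std::vector<double> &x, int t, int cue_on, int rew_on) const {
    std::fill(x.begin(), x.end(), 0.0);
    if (kind == 0) {
      if (cue_on >= 0 && t >= cue_on) {
        const double *row = &mb_cue[(size_t)(t - cue_on) * B];
        for (int d = 0; d < B; ++d) x[d] = row[d];
      }
      if (rew_on >= 0 && t >= rew_on) {
        const double *row = &mb_rew[(size_t)(t - rew_on) * B];
        for (int d = 0; d < B; ++d) x[B + d] = row[d];
      }
    } else {
      if (cue_on >= 0 && t >= cue_on && t - cue_on < B) x[t - cue_on] = gc[t - cue_on];
      if (rew_on >= 0 && t >= rew_on && t - rew_on < B) x[B + (t - rew_on)] = gr[t - rew_on];
    }
  }
};

static inline double dot(const std::vector<double> &w, const std::vector<double> &x) {
  double s = 0.0;
  for (size_t i = 0; i < w.size(); ++i) s += w[i] * x[i];
  return s;
}

// Online TD(lambda) actor-critic session over a schedule of trials.
//
// sched columns: 0 duration, 1 cue_onset, 2 reward_step (-1 none), 3 type,
//                4 fi_step (-1), 5 choice_open (-1), 6 choice_close (-1),
//                7 correct_action (-1)
// [[Rcpp::export]]
List cpp_run_session(IntegerMatrix sched,
                     NumericVector rew_mag,
                     int kind, int D, double sigma, double rho, int horizon,
                     NumericVector gain_cue, NumericVector gain_rew,
                     double alpha, double gamma_, double lambda_,
                     bool use_actor, double eta, int n_actions,
                     NumericVector w0, NumericMatrix u0,
                     bool learn, LogicalVector record_trial,
                     int post_steps) {
  const int n_trials = sched.nrow();
  const int B = (kind == 0) ? D : horizon;
  const int M = 2 * B;

  if (w0.size() != M) stop("weight vector has length %d, expected %d", (int)w0.size(), M);
  if (use_actor && (u0.nrow() != n_actions || u0.ncol() != M))
    stop("policy matrix must be n_actions x n_features");

  int maxdur = 0;
  for (int i = 0; i < n_trials; ++i) if (sched(i, 0) > maxdur) maxdur = sched(i, 0);

  FeatureGen fg;
  fg.kind = kind; fg.B = B;
  fg.gc = gain_cue.begin(); fg.gr = gain_rew.begin();
  if (kind == 0) {
    // Precompute microstimulus blocks for every possible steps-since-onset.
    fg.mb_cue.resize((size_t)maxdur * D);
    fg.mb_rew.resize((size_t)maxdur * D);
    double y = 1.0;
    for (int k = 0; k < maxdur; ++k) {
      for (int d = 0; d < D; ++d) {
        double c = (double)(d + 1) / D;
        double v = y * dnorm_std((y - c) / sigma);
        fg.mb_cue[(size_t)k * D + d] = v * gain_cue[d];
        fg.mb_rew[(size_t)k * D + d] = v * gain_rew[d];
      }
      y *= rho;
    }
  }

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<std::vector<double> > u(use_actor ? n_actions : 0,
                                      std::vector<double>(M, 0.0));
  if (use_actor)
    for (int a = 0; a < n_actions; ++a)
      for (int j = 0; j < M; ++j) u[a][j] = u0(a, j);

  std::vector<double> e(M), x(M), x_next(M), x_act(M), f(use_actor ? n_actions : 0),
      p(use_actor ? n_actions : 0);

  // per-trial summaries
  NumericVector tr_cue_delta(n_trials, NA_REAL), tr_rew_delta(n_trials, NA_REAL);
  IntegerVector tr_rew_step(n_trials, NA_INTEGER), tr_choice(n_trials, NA_INTEGER),
      tr_end(n_trials);

  // per-step records
  std::vector<int> rc_trial, rc_step, rc_action;
  std::vector<double> rc_value, rc_delta, rc_reward, rc_p0;
  size_t cap = 0;
  for (int i = 0; i < n_trials; ++i) if (record_trial[i]) cap += sched(i, 0);
  rc_trial.reserve(cap); rc_step.reserve(cap); rc_action.reserve(cap);
  rc_value.reserve(cap); rc_delta.reserve(cap); rc_reward.reserve(cap);
  rc_p0.reserve(cap);

  for (int i = 0; i < n_trials; ++i) {
    const int dur = sched(i, 0), cue_on = sched(i, 1), rew_sched = sched(i, 2),
              type = sched(i, 3), fi = sched(i, 4), copen = sched(i, 5),
              cclose = sched(i, 6), correct = sched(i, 7);
    const double mag = rew_mag[i];
    const bool rec = record_trial[i];

    std::fill(e.begin(), e.end(), 0.0);
    int rew_on = -1, choice = -1, end = dur;
    bool rewarded = false;

    for (int t = 0; t < end; ++t) {
      fg.fill(x_act, t, cue_on, rew_on);

      // --- action selection -------------------------------------------------
      int a = -1;
      double pa = 1.0, p0 = NA_REAL;
      bool window = (type == BIS_TRAIN || type == BIS_PROBE)
                        ? (copen >= 0 && t >= copen && t <= cclose && choice < 0)
                        : (type == PEAK_FI || type == PEAK_PROBE);
      if (use_actor && window) {
        double fmax = -HUGE_VAL;
        for (int k = 0; k < n_actions; ++k) {
          f[k] = dot(u[k], x_act);
          if (f[k] > fmax) fmax = f[k];
        }
        double z = 0.0;
        for (int k = 0; k < n_actions; ++k) { p[k] = std::exp(f[k] - fmax); z += p[k]; }
        for (int k = 0; k < n_actions; ++k) p[k] /= z;
        double udraw = R::unif_rand(), acc = 0.0;
        a = n_actions - 1;
        for (int k = 0; k < n_actions; ++k) { acc += p[k]; if (udraw < acc) { a = k; break; } }
        pa = p[a];
        p0 = p[0];
      }

      // --- reward contingency ----------------------------------------------
      double r = 0.0;
      if (type == PAVLOVIAN) {
        if (rew_sched >= 0 && t == rew_sched) { r = mag; rew_on = t; rewarded = true; }
      } else if (type == PEAK_FI) {
        if (!rewarded && a == 0 && fi >= 0 && t >= fi) {
          r = mag; rew_on = t; rewarded = true;
          if (t + post_steps + 1 < end) end = t + post_steps + 1;
        }
      } else if (type == BIS_TRAIN || type == BIS_PROBE) {
        if (a >= 0 && a < n_actions - 1 && choice < 0) {  // last action = withhold
          choice = a;
          if (type == BIS_TRAIN && a == correct) { r = mag; rew_on = t; rewarded = true; }
          if (t + post_steps + 1 < end) end = t + post_steps + 1;
        }
      }

      // critic state includes reward-elicited features from the delivery step on
      if (rew_on == t) fg.fill(x, t, cue_on, rew_on); else x = x_act;

      double v = dot(w, x);
      double v_next = 0.0;
      if (t + 1 < end) {
        // The successor state contains whatever is observed at t+1,
        // including reward-onset features when the (Pavlovian) schedule
        // delivers the reward then.
        int rew_on_next = rew_on;
        if (rew_on_next < 0 && type == PAVLOVIAN && rew_sched == t + 1)
          rew_on_next = rew_sched;
        fg.fill(x_next, t + 1, cue_on, rew_on_next);
        v_next = dot(w, x_next);
      }
      double delta = r + gamma_ * v_next - v;

      if (learn) {
        const double gl = gamma_ * lambda_, ad = alpha * delta;
        for (int j = 0; j < M; ++j) {
          e[j] = gl * e[j] + x[j];
          w[j] += ad * e[j];
        }
        if (a >= 0 && pa < 1.0) {
          const double step = eta * delta * (1.0 - pa);
          for (int j = 0; j < M; ++j) u[a][j] += step * x_act[j];
        }
      }

      if (cue_on >= 1 && t == cue_on - 1) tr_cue_delta[i] = delta;
      if (rew_on == t) { tr_rew_delta[i] = delta; tr_rew_step[i] = t; }
      else if (!rewarded && rew_sched >= 0 && t == rew_sched) tr_rew_delta[i] = delta;

      if (rec) {
        rc_trial.push_back(i + 1); rc_step.push_back(t);
        rc_value.push_back(v); rc_delta.push_back(delta); rc_reward.push_back(r);
        rc_action.push_back(a); rc_p0.push_back(p0);
      }
    }
    tr_choice[i] = (choice >= 0) ? choice : NA_INTEGER;
    tr_end[i] = end;
  }

  NumericMatrix u_out(use_actor ? n_actions : 0, use_actor ? M : 0);
  if (use_actor)
    for (int a = 0; a < n_actions; ++a)
      for (int j = 0; j < M; ++j) u_out(a, j) = u[a][j];

  IntegerVector rc_action_out(rc_action.size());
  for (size_t i = 0; i < rc_action.size(); ++i)
    rc_action_out[i] = rc_action[i] < 0 ? NA_INTEGER : rc_action[i];

  return List::create(
      _["steps"] = List::create(
          _["trial"] = wrap(rc_trial), _["step"] = wrap(rc_step),
          _["value"] = wrap(rc_value), _["delta"] = wrap(rc_delta),
          _["reward"] = wrap(rc_reward), _["action"] = rc_action_out,
          _["p_first"] = wrap(rc_p0)),
      _["trials"] = List::create(
          _["cue_delta"] = tr_cue_delta, _["reward_delta"] = tr_rew_delta,
          _["reward_step"] = tr_rew_step, _["choice"] = tr_choice,
          _["end_step"] = tr_end),
      _["weights"] = wrap(w),
      _["preferences"] = u_out);
}
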