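#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Room grid: states are 0-based indices s = row * n_cols + col.
// Actions: 0 = up (row-1), 1 = down (row+1), 2 = left (col-1), 3 = right (col+1).
static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

static inline int step_state(int s, int a, int nr, int nc) {
  int r = s / nc + DR[a];
  int c = s % nc + DC[a];
  if (r < 0 || r >= nr || c < 0 || c >= nc) return -1;
  return r * nc + c;
}

enum Kind { K_TD0 = 0, K_TD1 = 1, K_TDL = 2, K_MB = 3, K_HYBRID = 4 };

// One learner: per-goal model-free Q tables plus a per-trial eligibility
// trace. The same object drives the generative agent and the likelihood
// replay so the fitted model class contains the generator by construction.
struct Learner {
  int kind, nS, nr, nc, nG;
  double alpha, lam, omega;
  bool td1_acc;                 // TD(1) as accumulating (lambda = 1) trace
  std::vector<double> q;        // nG * nS * 4, model-free values
  const double *qmb;            // same layout, frozen model-based values
  std::vector<double> trace;    // nS * 4, reset each trial
  std::vector<int> active;      // indices with nonzero trace (visited pairs)
  std::vector<char> is_active;

  Learner(int kind_, int nr_, int nc_, int nG_, double alpha_, double lam_,
          double omega_, const double *qmb_, bool td1_acc_)
      : kind(kind_), nS(nr_ * nc_), nr(nr_), nc(nc_), nG(nG_), alpha(alpha_),
        lam(lam_), omega(omega_), td1_acc(td1_acc_), q(nG_ * nr_ * nc_ * 4, 0.0),
        qmb(qmb_), trace(nr_ * nc_ * 4, 0.0), is_active(nr_ * nc_ * 4, 0) {}

  void reset_trial() {
    for (size_t j = 0; j < active.size(); ++j) {
      trace[active[j]] = 0.0;
      is_active[active[j]] = 0;
    }
    active.clear();
  }

  void reset_q() { std::fill(q.begin(), q.end(), 0.0); }

  double qeff(int g, int s, int a) const {
    int i = g * nS * 4 + s * 4 + a;
    // qmb arrives as an R array (nS x 4 x nG, column-major)
    int imb = g * nS * 4 + a * nS + s;
    switch (kind) {
    case K_MB:     return qmb[imb];
    case K_HYBRID: return (1.0 - omega) * q[i] + omega * qmb[imb];
    default:       return q[i];
    }
  }

  // Softmax over the legal actions at s; returns their count, fills acts/p.
  int probs(int g, int s, double theta, int *acts, double *p) const {
    int m = 0;
    double mx = -1e300;
    for (int a = 0; a < 4; ++a) {
      if (step_state(s, a, nr, nc) < 0) continue;
      acts[m] = a;
      p[m] = theta * qeff(g, s, a);
      if (p[m] > mx) mx = p[m];
      ++m;
    }
    double z = 0.0;
    for (int j = 0; j < m; ++j) { p[j] = std::exp(p[j] - mx); z += p[j]; }
    for (int j = 0; j < m; ++j) p[j] /= z;
    return m;
  }

  // Stable log-probability of one action: z_a - max - log(sum exp(z - max)).
  // Never underflows, so extreme parameter corners (where Q can grow very
  // large) yield a finite, very poor likelihood instead of log(0).
  double log_prob(int g, int s, double theta, int a) const {
    double mx = -1e300;
    double za = NA_REAL;
    double z[4];
    int m = 0;
    for (int ac = 0; ac < 4; ++ac) {
      if (step_state(s, ac, nr, nc) < 0) continue;
      z[m] = theta * qeff(g, s, ac);
      if (z[m] > mx) mx = z[m];
      if (ac == a) za = z[m];
      ++m;
    }
    if (ISNA(za)) return NA_REAL;  // observed action illegal at this state
    double se = 0.0;
    for (int j = 0; j < m; ++j) se += std::exp(z[j] - mx);
    return za - mx - std::log(se);
  }

  // SARSA-style update for the transition (s, a) -> s_next with reward r and
  // next action a_next; a_next < 0 marks the terminal (goal-entering) step,
  // whose bootstrap term is 0.
  void update(int g, int s, int a, double r, int s_next, int a_next) {
    if (kind == K_MB) return;
    int off = g * nS * 4;
    int cur = s * 4 + a;
    double boot = (a_next < 0) ? 0.0 : q[off + s_next * 4 + a_next];
    double delta = r + boot - q[off + cur];
    if (kind == K_TD0) {
      q[off + cur] += alpha * delta;
      return;
    }
    bool accumulate = (kind == K_TDL || kind == K_HYBRID || (kind == K_TD1 && td1_acc));
    if (accumulate) {
      double l = (kind == K_TD1) ? 1.0 : lam;
      if (l != 1.0)
        for (size_t j = 0; j < active.size(); ++j) trace[active[j]] *= l;
      trace[cur] += 1.0;
    } else {
      trace[cur] = 1.0;  // TD(1): replacing, never decays within the trial
    }
    if (!is_active[cur]) { is_active[cur] = 1; active.push_back(cur); }
    for (size_t j = 0; j < active.size(); ++j) {
      int i = active[j];
      q[off + i] += alpha * delta * trace[i];
    }
  }
};

// Deterministic value-iteration sweep for one goal. Converged values obey
// Q(s, a) = reward * gamma^d(s') with d the room distance from s' to the
// goal (d = 0 at the goal itself). Illegal actions are NA in the output.
// [[Rcpp::export]]
NumericMatrix mb_values_cpp(int n_rows, int n_cols, int goal_state,
                            double gamma, double tol, double reward,
                            int max_iter = 100000) {
  if (tol <= 0) stop("tol must be positive");
  int nS = n_rows * n_cols;
  std::vector<double> Q(nS * 4, 0.0), V(nS, 0.0);
  double diff = R_PosInf;
  int it = 0;
  while (diff >= tol && it++ < max_iter) {
    diff = 0.0;
    for (int s = 0; s < nS; ++s) {
      double vmax = -1e300;
      bool any = false;
      for (int a = 0; a < 4; ++a) {
        int s2 = step_state(s, a, n_rows, n_cols);
        if (s2 < 0) continue;
        double qn = (s2 == goal_state) ? reward : gamma * V[s2];
        double d = std::fabs(qn - Q[s * 4 + a]);
        if (d > diff) diff = d;
        Q[s * 4 + a] = qn;
        if (qn > vmax) vmax = qn;
        any = true;
      }
      if (any) V[s] = vmax;
    }
  }
  if (diff >= tol) stop("value iteration did not converge");
  NumericMatrix out(nS, 4);
  for (int s = 0; s < nS; ++s)
    for (int a = 0; a < 4; ++a)
      out(s, a) = (step_state(s, a, n_rows, n_cols) < 0) ? NA_REAL : Q[s * 4 + a];
  return out;
}

// Single-step TD update on one goal's table (R-facing; the replay and the
// simulator use the same Learner::update).
// [[Rcpp::export]]
List td_update_cpp(NumericMatrix q, NumericMatrix trace, int kind, double alpha,
                   double lam, int s, int a, double r, int s_next, int a_next,
                   int n_rows, int n_cols, bool td1_accumulating) {
  if (a_next < 0 && r <= 0)
    stop("terminal update with zero reward: step is inconsistent with a goal entry");
  Learner L(kind, n_rows, n_cols, 1, alpha, lam, 0.0, NULL, td1_accumulating);
  int nS = n_rows * n_cols;
  for (int st = 0; st < nS; ++st)
    for (int ac = 0; ac < 4; ++ac) {
      L.q[st * 4 + ac] = q(st, ac);
      double e = trace(st, ac);
      if (e != 0.0) {
        L.trace[st * 4 + ac] = e;
        L.is_active[st * 4 + ac] = 1;
        L.active.push_back(st * 4 + ac);
      }
    }
  L.update(0, s, a, r, s_next, a_next);
  NumericMatrix qo(nS, 4), eo(nS, 4);
  for (int st = 0; st < nS; ++st)
    for (int ac = 0; ac < 4; ++ac) {
      qo(st, ac) = L.q[st * 4 + ac];
      eo(st, ac) = L.trace[st * 4 + ac];
    }
  return List::create(_["q"] = qo, _["trace"] = eo);
}

// Deterministic likelihood replay over a flattened step table (one
// participant, steps in chronological order). Choice probabilities for step
// i are computed before the pending update of step i-1 is applied, exactly
// mirroring the generative agent's choose-then-update order.
// [[Rcpp::export]]
List replay_nll_cpp(IntegerVector state, IntegerVector action, NumericVector rew,
                    IntegerVector goal, LogicalVector new_trial,
                    LogicalVector terminal, LogicalVector count,
                    LogicalVector reset_q, int kind, double alpha, double theta,
                    double lam, double omega, NumericVector qmb, int n_rows,
                    int n_cols, int n_goals, bool td1_accumulating) {
  int n = state.size();
  Learner L(kind, n_rows, n_cols, n_goals, alpha, lam, omega, REAL(qmb),
            td1_accumulating);
  double nll = 0.0;
  long n_choices = 0;
  int prev = -1;
  for (int i = 0; i < n; ++i) {
    if (new_trial[i]) { L.reset_trial(); prev = -1; }
    if (reset_q[i]) L.reset_q();
    int g = goal[i], s = state[i], a = action[i];
    if (count[i]) {
      double lp = L.log_prob(g, s, theta, a);
      if (ISNA(lp))
        stop("observed action is not legal at its state (step %d)", i + 1);
      nll -= lp;
      ++n_choices;
    }
    if (prev >= 0)
      L.update(g, state[prev], action[prev], rew[prev], s, a);
    prev = i;
    if (terminal[i]) {
      int s2 = step_state(s, a, n_rows, n_cols);
      L.update(g, s, a, rew[i], s2, -1);
      prev = -1;
    }
  }
  NumericVector qout(L.q.begin(), L.q.end());
  return List::create(_["nll"] = nll, _["n_choices"] = (double)n_choices,
                      _["q"] = qout);
}

// Generative softmax agent on the trial plan (goal index, start state and
// phase per trial). Uses R's RNG so set.seed() on the R side fixes the run.
// [[Rcpp::export]]
List simulate_agent_cpp(int n_rows, int n_cols, IntegerVector goal_states,
                        IntegerVector trial_goal, IntegerVector trial_start,
                        IntegerVector trial_phase, int kind, double alpha,
                        NumericVector theta_by_phase, double lam,
                        NumericVector omega_by_phase, NumericVector qmb,
                        double reward, int max_steps, bool td1_accumulating) {
  int nT = trial_goal.size();
  Learner L(kind, n_rows, n_cols, goal_states.size(), alpha, lam, 0.0,
            REAL(qmb), td1_accumulating);
  std::vector<int> v_trial, v_step, v_s, v_a, v_s2;
  std::vector<double> v_r;
  std::vector<int> v_trunc(nT, 0);
  int acts[4];
  double p[4];
  for (int t = 0; t < nT; ++t) {
    int g = trial_goal[t];
    int gs = goal_states[g];
    int ph = trial_phase[t];
    double theta = theta_by_phase[ph];
    L.omega = omega_by_phase[ph];
    L.reset_trial();
    int s = trial_start[t];
    int prev_s = -1, prev_a = -1;
    for (int k = 0; k < max_steps; ++k) {
      int m = L.probs(g, s, theta, acts, p);
      double u = unif_rand(), cum = 0.0;
      int a = acts[m - 1];
      for (int j = 0; j < m; ++j) { cum += p[j]; if (u <= cum) { a = acts[j]; break; } }
      if (prev_s >= 0) L.update(g, prev_s, prev_a, 0.0, s, a);
      int s2 = step_state(s, a, n_rows, n_cols);
      bool at_goal = (s2 == gs);
      v_trial.push_back(t); v_step.push_back(k);
      v_s.push_back(s); v_a.push_back(a); v_s2.push_back(s2);
      v_r.push_back(at_goal ? reward : 0.0);
      if (at_goal) { L.update(g, s, a, reward, s2, -1); break; }
      prev_s = s; prev_a = a; s = s2;
      if (k == max_steps - 1) v_trunc[t] = 1;
    }
  }
  return List::create(
      _["trial"] = IntegerVector(v_trial.begin(), v_trial.end()),
      _["step"] = IntegerVector(v_step.begin(), v_step.end()),
      _["state"] = IntegerVector(v_s.begin(), v_s.end()),
      _["action"] = IntegerVector(v_a.begin(), v_a.end()),
      _["next_state"] = IntegerVector(v_s2.begin(), v_s2.end()),
      _["reward"] = NumericVector(v_r.begin(), v_r.end()),
      _["truncated"] = IntegerVector(v_trunc.begin(), v_trunc.end()));
}
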