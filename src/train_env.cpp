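// C++ batch environment and rollout collector used by the trainer.
//
// Semantically equivalent to the R batch_env()/be_step() engine (same
// task rules, same epoch distributions, same rewards); kept free of
// trial logging so a full rollout chunk runs without touching R. All
// randomness uses R's RNG, so runs are reproducible given set.seed().
// The R implementation remains the reference path for evaluation and
// rate collection (which need trial logs).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

struct TaskDef {
  int rule;                    // rule-cue index 0..4
  bool sequential, determin, constrained;
  std::vector<std::vector<int>> slots;  // good indices (0..4) per slot
  arma::vec rho;               // length 5
  int fix_lo, fix_hi, rule_lo, rule_hi, off_lo, off_hi, del_lo, del_hi,
      resp_n;                  // epoch ranges in steps
};

struct EnvBatch {
  std::vector<TaskDef> tasks;
  int n;
  // per-env state
  std::vector<int> task, t, fix_end, rule_end, o1_end, d_end, resp_start,
      resp_end, first, second, n_choices;
  std::vector<char> seqf;
  arma::mat q, p, qn0, p0;     // 5 x n
  arma::mat vals;              // 3 x n
  // counters
  long n_trials = 0, n_completed = 0, n_correct = 0, n_aborted = 0,
       n_timeout = 0;
};

static int draw_steps(int lo, int hi) {
  if (lo >= hi) return lo;
  return lo + (int)(R::unif_rand() * (hi - lo + 1));
}

static void reset_env(EnvBatch& eb, int j) {
  int k = eb.tasks.size() == 1 ? 0
            : (int)(R::unif_rand() * eb.tasks.size());
  const TaskDef& td = eb.tasks[k];
  eb.task[j] = k;
  eb.t[j] = 0;
  eb.seqf[j] = td.sequential;
  eb.n_choices[j] = td.slots.size();
  int fix_n = draw_steps(td.fix_lo, td.fix_hi);
  int rule_n = draw_steps(td.rule_lo, td.rule_hi);
  eb.fix_end[j] = fix_n;
  eb.rule_end[j] = fix_n + rule_n;
  // offers
  for (int g = 0; g < 5; ++g) {
    eb.q(g, j) = NA_REAL; eb.p(g, j) = NA_REAL;
    eb.qn0(g, j) = 0; eb.p0(g, j) = 0;
  }
  bool fix_p_arm = td.constrained && (R::unif_rand() < 0.5);
  bool fix_q_arm = td.constrained && !fix_p_arm;
  for (size_t s = 0; s < td.slots.size(); ++s) {
    double v = 0;
    for (int g : td.slots[s]) {
      double rho = td.rho[g], qq, pp;
      if (td.constrained) {
        if (fix_p_arm) {
          pp = 0.5;
          do { qq = R::unif_rand() * 10.0 / rho; } while (rho * qq * pp < 1);
        } else {
          qq = 5.0 / rho;
          do { pp = R::unif_rand(); } while (rho * qq * pp < 1);
        }
      } else {
        do {
          qq = R::unif_rand() * 10.0 / rho;
          pp = td.determin ? 1.0 : R::unif_rand();
        } while (rho * qq * pp < 1);
      }
      eb.q(g, j) = qq; eb.p(g, j) = pp;
      eb.qn0(g, j) = qq / (10.0 / rho); eb.p0(g, j) = pp;
      v += rho * qq * pp;
    }
    eb.vals(s, j) = v;
  }
  for (size_t s = td.slots.size(); s < 3; ++s) eb.vals(s, j) = NA_REAL;
  if (td.sequential) {
    int o1 = draw_steps(td.off_lo, td.off_hi);
    int dl = draw_steps(td.del_lo, td.del_hi);
    int o2 = draw_steps(td.off_lo, td.off_hi);
    bool c_second = R::unif_rand() < 0.5;
    // slots are (C), (E): goods indices slots[0][0] = C, slots[1][0] = E
    eb.first[j] = c_second ? td.slots[1][0] : td.slots[0][0];
    eb.second[j] = c_second ? td.slots[0][0] : td.slots[1][0];
    eb.o1_end[j] = eb.rule_end[j] + o1;
    eb.d_end[j] = eb.o1_end[j] + dl;
    eb.resp_start[j] = eb.d_end[j] + o2;
  } else {
    int off_n = draw_steps(td.off_lo, td.off_hi);
    eb.o1_end[j] = eb.rule_end[j];
    eb.d_end[j] = eb.rule_end[j];
    eb.resp_start[j] = eb.rule_end[j] + off_n;
    eb.first[j] = -1; eb.second[j] = -1;
  }
  eb.resp_end[j] = eb.resp_start[j] + td.resp_n;
}

static void build_obs(const EnvBatch& eb, arma::mat& u, double u0,
                      double in_sd) {
  const int n = eb.n;
  u.zeros();
  for (int j = 0; j < n; ++j) {
    int t = eb.t[j];
    if (t < eb.resp_start[j]) u(0, j) = 1.0;
    if (t >= eb.fix_end[j]) u(1 + eb.tasks[eb.task[j]].rule, j) = 1.0;
    if (eb.seqf[j]) {
      if (t >= eb.rule_end[j] && t < eb.o1_end[j]) {
        int g = eb.first[j];
        u(6 + g, j) = eb.qn0(g, j); u(11 + g, j) = eb.p0(g, j);
      }
      if (t >= eb.d_end[j] && t < eb.resp_end[j]) {
        int g = eb.second[j];
        u(6 + g, j) = eb.qn0(g, j); u(11 + g, j) = eb.p0(g, j);
      }
    } else if (t >= eb.rule_end[j] && t < eb.resp_end[j]) {
      for (int g = 0; g < 5; ++g) {
        u(6 + g, j) = eb.qn0(g, j);
        u(11 + g, j) = eb.p0(g, j);
      }
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < 16; ++i)
      u(i, j) += u0 + in_sd * R::norm_rand();
}

// step: returns per-env reward and done, mutating state (auto-reset)
static void step_envs(EnvBatch& eb, const std::vector<int>& act,
                      arma::vec& reward, std::vector<char>& done) {
  for (int j = 0; j < eb.n; ++j) {
    reward[j] = 0; done[j] = 0;
    int a = act[j];
    bool in_resp = eb.t[j] >= eb.resp_start[j] && eb.t[j] < eb.resp_end[j];
    if (a != 0 && !in_resp) {
      reward[j] = -1; done[j] = 1; eb.n_aborted++;
    } else if (a != 0 && in_resp && a > eb.n_choices[j]) {
      done[j] = 1; eb.n_timeout++;  // error response: unoffered slot
    } else if (a != 0 && in_resp) {
      const TaskDef& td = eb.tasks[eb.task[j]];
      double rew = 0;
      for (int g : td.slots[a - 1])
        if (R::unif_rand() < eb.p(g, j)) rew += td.rho[g] * eb.q(g, j);
      reward[j] = rew; done[j] = 1;
      double vmax = 0;
      for (int s = 0; s < eb.n_choices[j]; ++s)
        vmax = std::max(vmax, eb.vals(s, j));
      eb.n_completed++;
      if (eb.vals(a - 1, j) >= vmax - 1e-12) eb.n_correct++;
    } else {
      eb.t[j]++;
      if (eb.t[j] >= eb.resp_end[j]) { done[j] = 1; eb.n_timeout++; }
    }
    if (done[j]) { eb.n_trials++; reset_env(eb, j); }
  }
}

// [[Rcpp::export]]
SEXP cpp_env_new(List specs, int n_envs) {
  EnvBatch* eb = new EnvBatch();
  for (int k = 0; k < specs.size(); ++k) {
    List sp = specs[k];
    TaskDef td;
    td.rule = as<int>(sp["rule"]);
    td.sequential = as<bool>(sp["sequential"]);
    td.determin = as<bool>(sp["deterministic"]);
    td.constrained = as<bool>(sp["constrained"]);
    td.rho = as<arma::vec>(sp["rho"]);
    List slots = sp["slots"];
    for (int s = 0; s < slots.size(); ++s)
      td.slots.push_back(as<std::vector<int>>(slots[s]));
    IntegerVector er = sp["epochs"];  // lo/hi pairs in steps + resp_n
    td.fix_lo = er[0]; td.fix_hi = er[1];
    td.rule_lo = er[2]; td.rule_hi = er[3];
    td.off_lo = er[4]; td.off_hi = er[5];
    td.del_lo = er[6]; td.del_hi = er[7];
    td.resp_n = er[8];
    eb->tasks.push_back(td);
  }
  eb->n = n_envs;
  eb->task.resize(n_envs); eb->t.resize(n_envs);
  eb->fix_end.resize(n_envs); eb->rule_end.resize(n_envs);
  eb->o1_end.resize(n_envs); eb->d_end.resize(n_envs);
  eb->resp_start.resize(n_envs); eb->resp_end.resize(n_envs);
  eb->first.resize(n_envs); eb->second.resize(n_envs);
  eb->n_choices.resize(n_envs); eb->seqf.resize(n_envs);
  eb->q.set_size(5, n_envs); eb->p.set_size(5, n_envs);
  eb->qn0.set_size(5, n_envs); eb->p0.set_size(5, n_envs);
  eb->vals.set_size(3, n_envs);
  GetRNGstate();
  for (int j = 0; j < n_envs; ++j) reset_env(*eb, j);
  PutRNGstate();
  return XPtr<EnvBatch>(eb, true);
}

// [[Rcpp::export]]
List cpp_env_counters(SEXP ptr) {
  XPtr<EnvBatch> eb(ptr);
  return List::create(_["n_trials"] = (double)eb->n_trials,
                      _["n_completed"] = (double)eb->n_completed,
                      _["n_correct"] = (double)eb->n_correct,
                      _["n_aborted"] = (double)eb->n_aborted,
                      _["n_timeout"] = (double)eb->n_timeout);
}

// Full rollout chunk: T environment steps for all envs, acting with the
// current policy; returns everything the PPO update needs.
// [[Rcpp::export]]
List cpp_rollout(SEXP ptr, const arma::mat& Wrec, const arma::mat& Win,
                 const arma::mat& Wa, const arma::rowvec& Wc,
                 const arma::vec& b, const arma::vec& ba, double bc,
                 arma::mat hidden, int T, double alpha, double kn,
                 double in_sd, double u0) {
  XPtr<EnvBatch> eb(ptr);
  const int N = Wrec.n_rows, B = eb->n, A = Wa.n_rows, NI = Win.n_cols;
  arma::cube obs(NI, B, T), xi(N, B, T);
  arma::imat actions(B, T);
  arma::mat logp(B, T), values(B, T), rewards(B, T), dones(B, T);
  arma::mat r0 = hidden;
  arma::mat u(NI, B);
  arma::vec reward(B);
  std::vector<char> done(B);
  std::vector<int> act(B);
  GetRNGstate();
  for (int t = 0; t < T; ++t) {
    build_obs(*eb, u, u0, in_sd);
    obs.slice(t) = u;
    arma::mat& x = xi.slice(t);
    for (arma::uword i = 0; i < x.n_elem; ++i) x(i) = R::norm_rand();
    arma::mat drive = Wrec * hidden + Win * u + kn * x;
    drive.each_col() += b;
    hidden = (1.0 - alpha) * hidden + alpha * drive;
    hidden.clamp(0.0, arma::datum::inf);
    arma::mat logits = Wa * hidden;
    logits.each_col() += ba;
    arma::rowvec mx = arma::max(logits, 0);
    logits.each_row() -= mx;
    arma::mat pr = arma::exp(logits);
    pr.each_row() /= arma::sum(pr, 0);
    for (int j = 0; j < B; ++j) {
      double uu = R::unif_rand(), cum = 0; int a = A - 1;
      for (int k = 0; k < A; ++k) {
        cum += pr(k, j);
        if (uu < cum) { a = k; break; }
      }
      act[j] = a;
      actions(j, t) = a;
      logp(j, t) = std::log(std::max(pr(a, j), 1e-300));
      values(j, t) = arma::dot(Wc, hidden.col(j)) + bc;
    }
    step_envs(*eb, act, reward, done);
    for (int j = 0; j < B; ++j) {
      rewards(j, t) = reward[j];
      dones(j, t) = done[j] ? 1.0 : 0.0;
      if (done[j]) hidden.col(j).zeros();
    }
  }
  // bootstrap value of the next state
  build_obs(*eb, u, u0, in_sd);
  arma::mat x2(N, B);
  for (arma::uword i = 0; i < x2.n_elem; ++i) x2(i) = R::norm_rand();
  arma::mat drive = Wrec * hidden + Win * u + kn * x2;
  drive.each_col() += b;
  arma::mat rn = (1.0 - alpha) * hidden + alpha * drive;
  rn.clamp(0.0, arma::datum::inf);
  arma::vec vboot(B);
  for (int j = 0; j < B; ++j) vboot[j] = arma::dot(Wc, rn.col(j)) + bc;
  PutRNGstate();
  return List::create(_["obs"] = obs, _["xi"] = xi, _["r0"] = r0,
                      _["actions"] = actions, _["logp_old"] = logp,
                      _["values"] = values, _["rewards"] = rewards,
                      _["dones"] = dones, _["v_boot"] = vboot,
                      _["hidden_out"] = hidden);
}
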