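// Hot loops of the recurrent actor-critic: one policy step (dynamics,
// readout, action sampling) and the full BPTT replay gradient of the PPO
// objective over a rollout minibatch. All randomness is drawn in R and
// passed in, so results are reproducible under R's RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One Euler step of the rate dynamics plus actor/critic readout and
// inverse-CDF action sampling from the softmax policy.
// r, u, xi: N x B, n_in x B, N x B; unif: B uniform draws (or empty to
// skip sampling). kn = sigma_rec * sqrt(2/alpha).
// [[Rcpp::export]]
List cpp_policy_step(const arma::mat& Wrec, const arma::mat& Win,
                     const arma::mat& Wa, const arma::rowvec& Wc,
                     const arma::vec& b, const arma::vec& ba, double bc,
                     const arma::mat& r, const arma::mat& u,
                     const arma::mat& xi, double alpha, double kn,
                     const arma::vec& unif) {
  arma::mat drive = Wrec * r + Win * u + kn * xi;
  drive.each_col() += b;
  arma::mat rn = (1.0 - alpha) * r + alpha * drive;
  rn.clamp(0.0, arma::datum::inf);
  arma::mat logits = Wa * rn;
  logits.each_col() += ba;
  arma::rowvec mx = arma::max(logits, 0);
  logits.each_row() -= mx;
  arma::mat probs = arma::exp(logits);
  probs.each_row() /= arma::sum(probs, 0);
  arma::rowvec value = Wc * rn + bc;
  const arma::uword B = r.n_cols;
  IntegerVector act(B);
  NumericVector logp(B);
  if (unif.n_elem == B) {
    for (arma::uword j = 0; j < B; ++j) {
      double cum = 0.0;
      arma::uword a = probs.n_rows - 1;
      for (arma::uword k = 0; k < probs.n_rows; ++k) {
        cum += probs(k, j);
        if (unif(j) < cum) { a = k; break; }
      }
      act[j] = (int)a;  // 0-based; 0 = hold
      logp[j] = std::log(std::max(probs(a, j), 1e-300));
    }
  }
  return List::create(_["r"] = rn, _["probs"] = probs,
                      _["value"] = NumericVector(value.begin(), value.end()),
                      _["action"] = act, _["logp"] = logp);
}

// Full forward + backward pass of the PPO objective over a minibatch of
// whole sequences. Gradients are returned in *effective*-weight space;
// the caller applies the magnitude-parametrization chain rule.
// obs: n_in x B x T; xi: N x B x T; actions (0-based), logp_old, dones,
// returns, adv: B x T; r0: N x B.
// [[Rcpp::export]]
List cpp_ppo_grad(const arma::mat& Wrec, const arma::mat& Win,
                  const arma::mat& Wa, const arma::rowvec& Wc,
                  const arma::vec& b, const arma::vec& ba, double bc,
                  const arma::cube& obs, const arma::cube& xi,
                  const arma::mat& r0, const arma::imat& actions,
                  const arma::mat& logp_old, const arma::mat& dones,
                  const arma::mat& returns, const arma::mat& adv,
                  double alpha, double kn, double clip_eps, double c1,
                  double c2, const arma::mat& values_old,
                  bool clip_vloss) {
  const arma::uword N = Wrec.n_rows, A = Wa.n_rows;
  const arma::uword B = r0.n_cols, T = obs.n_slices;
  const double denom = (double)(B * T);

  arma::cube r_in(N, B, T), r_out(N, B, T);
  arma::cube probs(A, B, T);
  arma::mat vals(B, T);
  arma::mat r = r0;
  // forward replay
  for (arma::uword t = 0; t < T; ++t) {
    r_in.slice(t) = r;
    arma::mat drive = Wrec * r + Win * obs.slice(t) + kn * xi.slice(t);
    drive.each_col() += b;
    arma::mat z = (1.0 - alpha) * r + alpha * drive;
    z.clamp(0.0, arma::datum::inf);
    r_out.slice(t) = z;
    arma::mat logits = Wa * z;
    logits.each_col() += ba;
    arma::rowvec mx = arma::max(logits, 0);
    logits.each_row() -= mx;
    arma::mat pr = arma::exp(logits);
    pr.each_row() /= arma::sum(pr, 0);
    probs.slice(t) = pr;
    for (arma::uword j = 0; j < B; ++j)
      vals(j, t) = arma::dot(Wc, z.col(j)) + bc;
    r = z;
    for (arma::uword j = 0; j < B; ++j)
      if (dones(j, t) > 0.5) r.col(j).zeros();
  }
  // loss terms
  double loss_pg = 0.0, loss_vf = 0.0, loss_ent = 0.0;
  arma::mat coef_lp(B, T), dV(B, T), ent(B, T);
  for (arma::uword t = 0; t < T; ++t) {
    for (arma::uword j = 0; j < B; ++j) {
      double pa = std::max(probs(actions(j, t), j, t), 1e-300);
      double lp = std::log(pa);
      double ratio = std::exp(lp - logp_old(j, t));
      double a_ = adv(j, t);
      double unc = ratio * a_;
      double rc = std::min(std::max(ratio, 1.0 - clip_eps), 1.0 + clip_eps);
      double cl = rc * a_;
      loss_pg += -std::min(unc, cl);
      bool active = (unc <= cl) ||
        (ratio >= 1.0 - clip_eps && ratio <= 1.0 + clip_eps);
      coef_lp(j, t) = active ? -(ratio * a_) / denom : 0.0;
      double vd = vals(j, t) - returns(j, t);
      if (clip_vloss) {
        // clip the value update around the rollout-time estimate: the
        // larger of the clipped and unclipped squared errors is used
        double dv = vals(j, t) - values_old(j, t);
        double dvc = std::min(std::max(dv, -clip_eps), clip_eps);
        double vdc = values_old(j, t) + dvc - returns(j, t);
        if (vd * vd >= vdc * vdc) {
          loss_vf += 0.5 * vd * vd;
          dV(j, t) = c1 * vd / denom;
        } else {
          loss_vf += 0.5 * vdc * vdc;
          dV(j, t) = (std::abs(dv) <= clip_eps) ? c1 * vdc / denom : 0.0;
        }
      } else {
        loss_vf += 0.5 * vd * vd;
        dV(j, t) = c1 * vd / denom;
      }
      double H = 0.0;
      for (arma::uword k = 0; k < A; ++k) {
        double p = std::max(probs(k, j, t), 1e-12);
        H -= p * std::log(p);
      }
      ent(j, t) = H;
      loss_ent += H;
    }
  }
  double loss = loss_pg / denom + c1 * loss_vf / denom - c2 * loss_ent / denom;

  // backward
  arma::mat gWrec(N, N, arma::fill::zeros), gWin(N, Win.n_cols, arma::fill::zeros);
  arma::mat gWa(A, N, arma::fill::zeros);
  arma::rowvec gWc(N, arma::fill::zeros);
  arma::vec gb(N, arma::fill::zeros), gba(A, arma::fill::zeros);
  double gbc = 0.0;
  arma::mat carry(N, B, arma::fill::zeros);
  arma::mat WrecT = Wrec.t(), WaT = Wa.t();
  arma::vec WcCol = Wc.t();
  for (arma::uword tt = T; tt-- > 0;) {
    const arma::mat& p = probs.slice(tt);
    const arma::mat& rp = r_out.slice(tt);
    const arma::mat& rin = r_in.slice(tt);
    arma::mat dlogits(A, B);
    for (arma::uword j = 0; j < B; ++j) {
      for (arma::uword k = 0; k < A; ++k) {
        double oh = (actions(j, tt) == (int)k) ? 1.0 : 0.0;
        dlogits(k, j) = coef_lp(j, tt) * (oh - p(k, j)) +
          (c2 / denom) * p(k, j) *
            (std::log(std::max(p(k, j), 1e-12)) + ent(j, tt));
      }
    }
    gWa += dlogits * rp.t();
    gba += arma::sum(dlogits, 1);
    for (arma::uword j = 0; j < B; ++j) {
      gWc += dV(j, tt) * rp.col(j).t();
      gbc += dV(j, tt);
    }
    arma::mat dr = WaT * dlogits + carry;
    for (arma::uword j = 0; j < B; ++j)
      dr.col(j) += WcCol * dV(j, tt);
    arma::mat dz = dr % (rp > 0);
    gWrec += alpha * dz * rin.t();
    gWin += alpha * dz * obs.slice(tt).t();
    gb += alpha * arma::sum(dz, 1);
    if (tt > 0) {
      carry = (1.0 - alpha) * dz + alpha * (WrecT * dz);
      for (arma::uword j = 0; j < B; ++j)
        if (dones(j, tt - 1) > 0.5) carry.col(j).zeros();
    }
  }
  return List::create(_["loss"] = loss, _["W_rec"] = gWrec,
                      _["W_in"] = gWin, _["W_a"] = gWa, _["W_c"] = gWc,
                      _["b"] = gb, _["b_a"] = gba, _["b_c"] = gbc);
}
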