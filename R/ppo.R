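# ---------------------------------------------------------------------------
# Proximal policy optimization of the actor-critic E/I network.
#
# The total objective (maximized) is
#   L = E[ L_PPO ] - c1 * L_VF + c2 * entropy
# with the clipped surrogate L_PPO = min(ratio * A, clip(ratio) * A),
# advantages A_t = R_t - V_old(s_t) and bootstrapped returns
#   R_t = sum_k gamma^k r_{t+k} + gamma^{T-t} V(s_T),
# truncated at trial boundaries. Gradients are computed analytically by
# backpropagation through time over the stored rollout (observations and
# recurrent noise are replayed exactly), then applied with Adam under a
# global gradient-norm clip, preserving Dale's law via the magnitude
# parametrization of the weights.
# ---------------------------------------------------------------------------

#' PPO hyperparameters
#'
#' Defaults: discount 0.99, clip 0.1, value coefficient 0.5, entropy
#' coefficient 0.01, Adam learning rate 2.5e-4 (annealed linearly over
#' the budget), gradient-norm clip 1.0, 20 parallel environments,
#' 128-step rollouts, 4 optimization epochs of 4 whole-sequence
#' minibatches per rollout, generalized advantage estimation with
#' lambda 0.95 (set \code{gae_lambda = NULL} for the plain
#' bootstrapped-return advantage).
#'
#' @param gamma Discount factor.
#' @param clip_eps Clipping parameter of the surrogate objective.
#' @param c1,c2 Value-loss and entropy coefficients.
#' @param lr Adam learning rate.
#' @param grad_clip Global gradient-norm clip.
#' @param n_envs Parallel environments per rollout.
#' @param T Steps per rollout chunk.
#' @param n_epochs,n_minibatches Optimization epochs over each rollout and
#'   minibatches (of whole sequences) per epoch.
#' @param norm_adv Normalize advantages within each minibatch.
#' @param gae_lambda Generalized-advantage-estimation lambda; NULL uses
#'   the plain bootstrapped-return advantage (the lambda = 1 case).
#' @param anneal_lr Linearly decay the learning rate to zero over the
#'   training budget.
#' @param clip_vloss Clip the per-update value change around the
#'   rollout-time estimate (same epsilon as the policy clip), bounding
#'   how hard the critic can pull on the shared recurrent weights in one
#'   update.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return List of class \code{ppo_config}.
#' @export
ppo_config <- function(gamma = 0.99, clip_eps = 0.1, c1 = 0.5, c2 = 0.01,
                       lr = 2.5e-4, grad_clip = 1.0, n_envs = 20, T = 128,
                       n_epochs = 4, n_minibatches = 4, norm_adv = FALSE,
                       gae_lambda = 0.95, anneal_lr = TRUE,
                       clip_vloss = TRUE,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_eps = 1e-8) {
  stopifnot(gamma > 0, gamma <= 1, clip_eps > 0)
  structure(as.list(environment()), class = "ppo_config")
}

# Returns and advantages for a rollout sub-batch. With gae_lambda = NULL
# the plain bootstrapped return is used (A = R - V_old); with a numeric
# lambda, generalized advantage estimation (the plain return is the
# lambda = 1 special case) with value targets R = A + V_old.
compute_targets <- function(batch, cfg, idx) {
  rew <- batch$rewards[idx, , drop = FALSE]
  done <- batch$dones[idx, , drop = FALSE]
  vals <- batch$values[idx, , drop = FALSE]
  vb <- batch$v_boot[idx]
  if (is.null(cfg$gae_lambda)) {
    ret <- bootstrapped_return(rew, done, vb, cfg$gamma)
    adv <- advantage(ret, vals)
  } else {
    Tn <- ncol(rew)
    adv <- matrix(0, nrow(rew), Tn)
    lastg <- 0
    nextv <- vb
    for (t in Tn:1) {
      nd <- 1 - done[, t]
      delta <- rew[, t] + cfg$gamma * nextv * nd - vals[, t]
      lastg <- delta + cfg$gamma * cfg$gae_lambda * nd * lastg
      adv[, t] <- lastg
      nextv <- vals[, t]
    }
    ret <- adv + vals
  }
  list(returns = ret, adv = adv)
}

#' Bootstrapped discounted returns
#'
#' \code{R_t = r_t + gamma * (1 - done_t) * R_{t+1}} computed backwards
#' from the bootstrap value of the post-rollout state; accumulation is
#' truncated wherever a trial ended (done).
#'
#' @param rewards Matrix (envs x steps) or vector of rewards.
#' @param dones Logical/0-1 matrix matching \code{rewards}.
#' @param bootstrap Value estimate of the state after the last step (per
#'   env); zeroed automatically where the last step was terminal.
#' @param gamma Discount factor.
#' @return Matrix (or vector) of returns, same shape as \code{rewards}.
#' @export
bootstrapped_return <- function(rewards, dones, bootstrap, gamma = 0.99) {
  vec <- is.null(dim(rewards))
  if (vec) {
    rewards <- matrix(rewards, 1)
    dones <- matrix(as.numeric(dones), 1)
  }
  Tn <- ncol(rewards)
  R <- matrix(0, nrow(rewards), Tn)
  nxt <- bootstrap * (1 - dones[, Tn])
  for (t in Tn:1) {
    R[, t] <- rewards[, t] + gamma * nxt
    if (t > 1) nxt <- R[, t] * (1 - dones[, t - 1])
  }
  if (vec) R <- as.numeric(R)
  R
}

#' Advantages from returns and value predictions
#' @param returns Bootstrapped returns.
#' @param values Critic predictions at the same states (from the rollout).
#' @return \code{returns - values}.
#' @export
advantage <- function(returns, values) returns - values

# --- rollout collection -----------------------------------------------------

# One forward policy step on the fast path (C++ kernel); handles the
# clamp lesion by zeroing the clamped rates after the update. All random
# draws come from R's RNG. unif = NULL skips action sampling.
policy_step <- function(net, w, r, u, xi, unif = NULL) {
  ncfg <- net$cfg
  kn <- ncfg$sigma_rec * sqrt(2 / ncfg$alpha)
  st <- cpp_policy_step(w$W_rec, w$W_in, w$W_a, w$W_c, net$b, net$b_a,
                        net$b_c, r, u, xi, ncfg$alpha, kn,
                        if (is.null(unif)) numeric(0) else unif)
  if (!is.null(net$lesion) && net$lesion$type == "clamp" &&
      length(net$lesion$neurons)) {
    st$r[net$lesion$neurons, ] <- 0
    ro <- readout(net, st$r, weights = w)
    st$probs <- ro$probs
    st$value <- ro$value
    if (!is.null(unif)) {
      cum <- apply(st$probs, 2, cumsum)
      st$action <- colSums(cum < rep(unif, each = nrow(cum)))
      st$logp <- log(st$probs[cbind(st$action + 1L, seq_along(unif))])
    }
  }
  st
}

# Collect one rollout chunk of cfg$T steps from the batch env, acting with
# the current (stochastic) policy. Hidden state is carried across chunks
# within a trial and reset at trial boundaries.
collect_rollout <- function(net, be, cfg, hidden) {
  w <- effective_weights(net)
  ncfg <- net$cfg
  N <- ncfg$n; B <- be$n; Tn <- cfg$T
  obs <- array(0, c(ncfg$n_in, B, Tn))
  xi <- array(stats::rnorm(N * B * Tn), c(N, B, Tn))
  actions <- matrix(0L, B, Tn)
  logp <- matrix(0, B, Tn)
  values <- matrix(0, B, Tn)
  rewards <- matrix(0, B, Tn)
  dones <- matrix(0, B, Tn)
  r0 <- hidden
  r <- hidden
  for (t in seq_len(Tn)) {
    u <- be_obs(be, noise = TRUE, sigma_in = ncfg$sigma_in,
                alpha = ncfg$alpha)
    obs[, , t] <- u
    st <- policy_step(net, w, r, u, xi[, , t], unif = stats::runif(B))
    r <- st$r
    actions[, t] <- st$action  # 0 = hold
    logp[, t] <- st$logp
    values[, t] <- st$value
    es <- be_step(be, actions[, t])
    rewards[, t] <- es$reward
    dones[, t] <- as.numeric(es$done)
    if (any(es$done)) r[, es$done] <- 0
  }
  # bootstrap value of the next state (fresh noise; not part of the batch)
  u_next <- be_obs(be, noise = TRUE, sigma_in = ncfg$sigma_in,
                   alpha = ncfg$alpha)
  v_boot <- policy_step(net, w, r, u_next,
                        matrix(stats::rnorm(N * B), N, B))$value
  list(obs = obs, xi = xi, r0 = r0, actions = actions, logp_old = logp,
       values = values, rewards = rewards, dones = dones, v_boot = v_boot,
       hidden_out = r)
}

# --- loss and analytic gradient --------------------------------------------

# Forward replay of a (sub)batch under the current parameters.
# Returns per-step rates and policy quantities needed by the loss/backward.
replay_forward <- function(net, batch, idx) {
  w <- effective_weights(net)
  ncfg <- net$cfg
  N <- ncfg$n; A <- ncfg$n_actions
  B <- length(idx); Tn <- dim(batch$obs)[3]
  kn <- ncfg$sigma_rec * sqrt(2 / ncfg$alpha)
  al <- ncfg$alpha
  r_in <- array(0, c(N, B, Tn))   # rates entering each step (post-reset)
  r_out <- array(0, c(N, B, Tn))  # rates after each step
  pos <- array(FALSE, c(N, B, Tn))
  probs <- array(0, c(A, B, Tn))
  vals <- matrix(0, B, Tn)
  r <- batch$r0[, idx, drop = FALSE]
  for (t in seq_len(Tn)) {
    u <- batch$obs[, idx, t, drop = FALSE]; dim(u) <- c(ncfg$n_in, B)
    x <- batch$xi[, idx, t, drop = FALSE]; dim(x) <- c(N, B)
    r_in[, , t] <- r
    z <- (1 - al) * r + al * (w$W_rec %*% r + w$W_in %*% u + net$b + kn * x)
    rp <- pmax(z, 0)
    pos[, , t] <- z > 0
    r_out[, , t] <- rp
    logits <- w$W_a %*% rp + net$b_a
    m <- apply(logits, 2, max)
    e <- exp(sweep(logits, 2, m))
    probs[, , t] <- sweep(e, 2, colSums(e), `/`)
    vals[, t] <- as.numeric(w$W_c %*% rp) + net$b_c
    r <- rp * rep(1 - batch$dones[idx, t], each = N)
  }
  list(w = w, r_in = r_in, r_out = r_out, pos = pos, probs = probs,
       vals = vals, B = B, Tn = Tn)
}

# Per-step loss pieces shared by value and gradient paths.
ppo_loss_terms <- function(fw, batch, idx, returns, adv, cfg) {
  B <- fw$B; Tn <- fw$Tn
  aidx <- batch$actions[idx, , drop = FALSE] + 1L
  lp_new <- matrix(0, B, Tn)
  ent <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    p <- fw$probs[, , t, drop = FALSE]; dim(p) <- dim(fw$probs)[1:2]
    lp_new[, t] <- log(p[cbind(aidx[, t], seq_len(B))])
    ent[, t] <- -colSums(p * log(pmax(p, 1e-12)))
  }
  ratio <- exp(lp_new - batch$logp_old[idx, , drop = FALSE])
  unclipped <- ratio * adv
  clipped <- pmin(pmax(ratio, 1 - cfg$clip_eps), 1 + cfg$clip_eps) * adv
  pg <- -pmin(unclipped, clipped)
  vd <- fw$vals - returns
  if (isTRUE(cfg$clip_vloss)) {
    v_old <- batch$values[idx, , drop = FALSE]
    dv <- pmin(pmax(fw$vals - v_old, -cfg$clip_eps), cfg$clip_eps)
    vdc <- v_old + dv - returns
    vf <- 0.5 * pmax(vd^2, vdc^2)
  } else {
    vf <- 0.5 * vd^2
  }
  loss <- mean(pg) + cfg$c1 * mean(vf) - cfg$c2 * mean(ent)
  list(loss = loss, ratio = ratio, unclipped = unclipped,
       clipped = clipped, lp_new = lp_new, ent = ent)
}

#' PPO loss of a rollout minibatch under the current parameters
#'
#' Re-runs the network over the stored observations and noise and
#' evaluates the clipped-surrogate + value + entropy objective (as a loss
#' to be minimized; its negative is the maximized objective).
#'
#' @param net An \code{ei_network}.
#' @param batch Rollout from the internal collector.
#' @param cfg A \code{ppo_config}.
#' @param idx Environment indices forming the minibatch.
#' @return Scalar loss.
#' @export
ppo_total_loss <- function(net, batch, cfg, idx = seq_len(dim(batch$obs)[2])) {
  fw <- replay_forward(net, batch, idx)
  tg <- compute_targets(batch, cfg, idx)
  returns <- tg$returns
  adv <- tg$adv
  if (cfg$norm_adv) adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
  ppo_loss_terms(fw, batch, idx, returns, adv, cfg)$loss
}

# Analytic gradient of ppo_total_loss (fast C++ BPTT kernel); gradients
# are chained from effective- to free-parameter space.
ppo_gradient <- function(net, batch, cfg, idx = seq_len(dim(batch$obs)[2])) {
  w <- effective_weights(net)
  ncfg <- net$cfg
  tg <- compute_targets(batch, cfg, idx)
  returns <- tg$returns
  adv <- tg$adv
  if (cfg$norm_adv) adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
  kn <- ncfg$sigma_rec * sqrt(2 / ncfg$alpha)
  res <- cpp_ppo_grad(w$W_rec, w$W_in, w$W_a, w$W_c, net$b, net$b_a,
                      net$b_c,
                      batch$obs[, idx, , drop = FALSE],
                      batch$xi[, idx, , drop = FALSE],
                      batch$r0[, idx, drop = FALSE],
                      batch$actions[idx, , drop = FALSE],
                      batch$logp_old[idx, , drop = FALSE],
                      batch$dones[idx, , drop = FALSE],
                      returns, adv, ncfg$alpha, kn, cfg$clip_eps,
                      cfg$c1, cfg$c2,
                      batch$values[idx, , drop = FALSE],
                      isTRUE(cfg$clip_vloss))
  g <- list(W_rec = res$W_rec * rep(net$dale_sign, each = ncfg$n) *
              sign(net$W_rec),
            W_in = res$W_in * sign(net$W_in),
            W_a = res$W_a * sign(net$W_a),
            W_c = matrix(res$W_c, 1) * sign(net$W_c),
            b = as.numeric(res$b), b_a = as.numeric(res$b_a),
            b_c = res$b_c)
  list(loss = res$loss, grads = g)
}

# Reference R implementation of the gradient (used as a cross-check of
# the C++ kernel; same derivation, independent code path).
ppo_gradient_r <- function(net, batch, cfg,
                           idx = seq_len(dim(batch$obs)[2])) {
  fw <- replay_forward(net, batch, idx)
  ncfg <- net$cfg
  N <- ncfg$n; A <- ncfg$n_actions
  B <- fw$B; Tn <- fw$Tn
  al <- ncfg$alpha
  tg <- compute_targets(batch, cfg, idx)
  returns <- tg$returns
  adv <- tg$adv
  if (cfg$norm_adv) adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
  lt <- ppo_loss_terms(fw, batch, idx, returns, adv, cfg)
  denom <- B * Tn
  aidx <- batch$actions[idx, , drop = FALSE] + 1L
  dones <- batch$dones[idx, , drop = FALSE]
  # gradient flows through the surrogate only where the min() picks the
  # unclipped term or the ratio is inside the clipping band
  active <- (lt$unclipped <= lt$clipped) |
    (lt$ratio >= 1 - cfg$clip_eps & lt$ratio <= 1 + cfg$clip_eps)
  coef_lp <- -(lt$ratio * adv * active) / denom
  if (isTRUE(cfg$clip_vloss)) {
    v_old <- batch$values[idx, , drop = FALSE]
    dvfree <- fw$vals - v_old
    dvc <- pmin(pmax(dvfree, -cfg$clip_eps), cfg$clip_eps)
    vd <- fw$vals - returns
    vdc <- v_old + dvc - returns
    use_unc <- vd^2 >= vdc^2
    dV <- cfg$c1 / denom *
      ifelse(use_unc, vd, ifelse(abs(dvfree) <= cfg$clip_eps, vdc, 0))
  } else {
    dV <- cfg$c1 * (fw$vals - returns) / denom
  }
  g <- list(W_rec = matrix(0, N, N), W_in = matrix(0, N, ncfg$n_in),
            W_a = matrix(0, A, N), W_c = matrix(0, 1, N),
            b = numeric(N), b_a = numeric(A), b_c = 0)
  carry <- matrix(0, N, B)  # dL/dz_{t+1} already through the Jacobian
  WrecT <- t(fw$w$W_rec)
  WaT <- t(fw$w$W_a)
  Wc_col <- as.numeric(fw$w$W_c)
  for (t in Tn:1) {
    p <- fw$probs[, , t, drop = FALSE]; dim(p) <- c(A, B)
    rp <- fw$r_out[, , t, drop = FALSE]; dim(rp) <- c(N, B)
    rin <- fw$r_in[, , t, drop = FALSE]; dim(rin) <- c(N, B)
    onehot <- matrix(0, A, B)
    onehot[cbind(aidx[, t], seq_len(B))] <- 1
    dlogits <- sweep(onehot - p, 2, coef_lp[, t], `*`)
    # entropy term: d(-c2*H)/dlogits = c2 * p * (log p + H)
    dlogits <- dlogits + (cfg$c2 / denom) *
      p * sweep(log(pmax(p, 1e-12)), 2, lt$ent[, t], `+`)
    g$W_a <- g$W_a + dlogits %*% t(rp)
    g$b_a <- g$b_a + rowSums(dlogits)
    g$W_c <- g$W_c + matrix(dV[, t], 1) %*% t(rp)
    g$b_c <- g$b_c + sum(dV[, t])
    dr <- WaT %*% dlogits + outer(Wc_col, dV[, t]) + carry
    dz <- dr * (fw$pos[, , t] * 1)
    g$W_rec <- g$W_rec + al * dz %*% t(rin)
    g$W_in <- g$W_in + al * dz %*% t(matrix(batch$obs[, idx, t],
                                            ncfg$n_in, B))
    g$b <- g$b + al * rowSums(dz)
    if (t > 1) {
      reset <- rep(1 - dones[, t - 1], each = N)
      carry <- ((1 - al) * dz + al * (WrecT %*% dz)) * reset
    }
  }
  # chain effective -> free parameters (magnitude parametrization)
  g$W_rec <- g$W_rec * rep(net$dale_sign, each = N) * sign(net$W_rec)
  g$W_in <- g$W_in * sign(net$W_in)
  g$W_a <- g$W_a * sign(net$W_a)
  g$W_c <- g$W_c * sign(net$W_c)
  list(loss = lt$loss, grads = g)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  pn <- c("W_rec", "W_in", "W_a", "W_c", "b", "b_a", "b_c")
  list(t = 0,
       m = stats::setNames(lapply(pn, function(p) net[[p]] * 0), pn),
       v = stats::setNames(lapply(pn, function(p) net[[p]] * 0), pn))
}

adam_step <- function(net, grads, opt, cfg) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (gnorm > cfg$grad_clip) cfg$grad_clip / gnorm else 1
  opt$t <- opt$t + 1
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (p in names(grads)) {
    g <- grads[[p]] * scale
    opt$m[[p]] <- b1 * opt$m[[p]] + (1 - b1) * g
    opt$v[[p]] <- b2 * opt$v[[p]] + (1 - b2) * g^2
    net[[p]] <- net[[p]] - cfg$lr * (opt$m[[p]] / corr1) /
      (sqrt(opt$v[[p]] / corr2) + cfg$adam_eps)
  }
  list(net = net, opt = opt)
}

# --- training loop ----------------------------------------------------------

# Convert task specs to the compact description the C++ batch env uses.
cpp_spec_list <- function(tasks) {
  lapply(tasks, function(sp) {
    dt <- sp$dt_ms
    list(rule = match(sp$name, TASK_NAMES) - 1L,
         sequential = sp$sequential,
         deterministic = sp$deterministic,
         constrained = sp$constrained,
         rho = unname(sp$rho),
         slots = lapply(sp$slots, function(sl)
           match(sl$goods, GOOD_IDS) - 1L),
         epochs = as.integer(c(sp$fix_ms / dt, sp$rule_ms / dt,
                               sp$offer_ms / dt, sp$delay_ms / dt,
                               sp$response_ms / dt)))
  })
}

#' Train a network with PPO on one or more tasks
#'
#' Runs the rollout-update loop (20 parallel environments, 128-step
#' chunks, 4 epochs of 4 whole-sequence minibatches) until the performance
#' criteria are met on a held-out evaluation set or the step budget is
#' exhausted. For multitask training each environment draws its next
#' trial's task uniformly at random. Training statistics accumulated over
#' each evaluation window gate the (more expensive) held-out check: the
#' criteria are confirmed on freshly simulated trials before stopping.
#'
#' @param net An \code{ei_network} (initialized or pre-trained).
#' @param tasks A \code{choice_task} or list of them.
#' @param cfg A \code{ppo_config}.
#' @param total_steps Environment-step budget.
#' @param eval_every Window (in env steps) for logging/criteria checks.
#' @param eval_trials Held-out trials used to confirm the criteria.
#' @param criteria Named vector with \code{completion} and \code{accuracy}
#'   thresholds.
#' @param verbose Print progress lines.
#' @return List with the trained \code{net}, a \code{history} data frame,
#'   \code{criteria_met}, \code{steps} used and \code{trials} seen.
#' @export
train_network <- function(net, tasks, cfg = ppo_config(),
                          total_steps = 2e7, eval_every = 1e5,
                          eval_trials = 1000,
                          criteria = c(completion = 0.99, accuracy = 0.90),
                          verbose = FALSE) {
  if (inherits(tasks, "choice_task")) tasks <- list(tasks)
  env <- cpp_env_new(cpp_spec_list(tasks), cfg$n_envs)
  ncfg <- net$cfg
  kn <- ncfg$sigma_rec * sqrt(2 / ncfg$alpha)
  in_sd <- ncfg$sigma_in * sqrt(2 / ncfg$alpha)
  hidden <- matrix(0, net$cfg$n, cfg$n_envs)
  opt <- adam_init(net)
  steps <- 0; trials <- 0
  history <- list()
  criteria_met <- FALSE
  win_mark <- c(0, 0, 0)  # trials, completed, correct
  next_eval <- eval_every
  mb_sizes <- rep(cfg$n_envs %/% cfg$n_minibatches, cfg$n_minibatches)
  mb_sizes[seq_len(cfg$n_envs %% cfg$n_minibatches)] <-
    mb_sizes[seq_len(cfg$n_envs %% cfg$n_minibatches)] + 1
  base_lr <- cfg$lr
  while (steps < total_steps && !criteria_met) {
    if (cfg$anneal_lr)
      cfg$lr <- base_lr * max(1 - steps / total_steps, 0.02)
    w <- effective_weights(net)
    batch <- cpp_rollout(env, w$W_rec, w$W_in, w$W_a, w$W_c, net$b,
                         net$b_a, net$b_c, hidden, cfg$T, ncfg$alpha,
                         kn, in_sd, 0.2)
    hidden <- batch$hidden_out
    for (ep in seq_len(cfg$n_epochs)) {
      perm <- sample.int(cfg$n_envs)
      off <- 0
      for (sz in mb_sizes) {
        idx <- perm[(off + 1):(off + sz)]
        off <- off + sz
        gr <- ppo_gradient(net, batch, cfg, idx)
        upd <- adam_step(net, gr$grads, opt, cfg)
        net <- upd$net; opt <- upd$opt
      }
    }
    steps <- steps + cfg$n_envs * cfg$T
    if (steps >= next_eval) {
      next_eval <- next_eval + eval_every
      cnt <- cpp_env_counters(env)
      w_tr <- cnt$n_trials - win_mark[1]
      w_cp <- cnt$n_completed - win_mark[2]
      w_cr <- cnt$n_correct - win_mark[3]
      win_mark <- c(cnt$n_trials, cnt$n_completed, cnt$n_correct)
      w_completion <- if (w_tr > 0) w_cp / w_tr else NA
      w_accuracy <- if (w_cp > 0) w_cr / w_cp else NA
      confirmed <- NA
      if (!is.na(w_completion) && !is.na(w_accuracy) &&
          w_completion >= criteria["completion"] - 0.01 &&
          w_accuracy >= criteria["accuracy"] - 0.01) {
        ev <- evaluate_network(net, tasks, n_trials = eval_trials)
        confirmed <- ev$completion >= criteria["completion"] &&
          ev$accuracy >= criteria["accuracy"]
        criteria_met <- isTRUE(confirmed)
      }
      history[[length(history) + 1]] <- data.frame(
        steps = steps, trials = cnt$n_trials,
        completion = w_completion, accuracy = w_accuracy,
        confirmed = confirmed)
      if (verbose)
        message(sprintf("steps %.2e trials %d completion %.3f accuracy %.3f",
                        steps, cnt$n_trials, w_completion, w_accuracy))
    }
  }
  cnt <- cpp_env_counters(env)
  list(net = net, history = do.call(rbind, history),
       criteria_met = criteria_met, steps = steps, trials = cnt$n_trials)
}

#' Evaluate a (fixed) network on held-out trials
#'
#' Simulates trials with the stochastic policy and no weight updates.
#' Reproducible given the RNG seed set by the caller.
#'
#' @param net Trained \code{ei_network}.
#' @param tasks A \code{choice_task} or list of them.
#' @param n_trials Number of trials to simulate.
#' @param n_envs Parallel environments used for simulation.
#' @param log Return the full per-trial log.
#' @param fixed_epochs Use midpoint epoch durations.
#' @return List with \code{completion}, \code{accuracy}, \code{per_task}
#'   data frame, \code{n_trials}, and optionally \code{trials} (log).
#' @export
evaluate_network <- function(net, tasks, n_trials = 1000, n_envs = 50,
                             log = FALSE, fixed_epochs = FALSE) {
  if (inherits(tasks, "choice_task")) tasks <- list(tasks)
  be <- batch_env(tasks, n_envs, fixed_epochs = fixed_epochs,
                  log_trials = TRUE)
  hidden <- matrix(0, net$cfg$n, n_envs)
  w <- effective_weights(net)
  ncfg <- net$cfg
  while (be$n_trials < n_trials) {
    u <- be_obs(be, noise = TRUE, sigma_in = ncfg$sigma_in,
                alpha = ncfg$alpha)
    st <- policy_step(net, w, hidden, u,
                      matrix(stats::rnorm(ncfg$n * n_envs), ncfg$n),
                      unif = stats::runif(n_envs))
    hidden <- st$r
    es <- be_step(be, st$action)
    if (any(es$done)) hidden[, es$done] <- 0
  }
  d <- be_trial_log(be)
  per_task <- do.call(rbind, lapply(split(d, d$task), function(s) {
    data.frame(task = s$task[1], n = nrow(s),
               completion = mean(s$completed),
               accuracy = mean(s$correct[s$completed]))
  }))
  rownames(per_task) <- NULL
  out <- list(completion = mean(d$completed),
              accuracy = mean(d$correct[d$completed]),
              per_task = per_task, n_trials = nrow(d))
  if (log) out$trials <- d
  out
}

#' Zero-shot transfer evaluation
#'
#' Evaluates a trained network on every task without any weight updates.
#'
#' @param net Trained \code{ei_network} (typically single-task trained).
#' @param tasks Named list of \code{choice_task} specs.
#' @param n_trials Trials per task.
#' @return data.frame with one row per task: completion and accuracy.
#' @export
zero_shot_eval <- function(net, tasks, n_trials = 1000) {
  if (inherits(tasks, "choice_task")) tasks <- list(tasks)
  do.call(rbind, lapply(tasks, function(sp) {
    ev <- evaluate_network(net, sp, n_trials = n_trials)
    data.frame(task = sp$name, completion = ev$completion,
               accuracy = ev$accuracy)
  }))
}

#' Curriculum training
#'
#' Trains through an ordered list of pre-training stages, each to
#' criterion, then on the target task; reports the trial count of the
#' final (target) stage only. An empty curriculum reduces to training from
#' the random initialization.
#'
#' @param net Initialized \code{ei_network}.
#' @param target Target \code{choice_task}.
#' @param curriculum List of pre-training \code{choice_task} stages
#'   (possibly empty).
#' @param cfg A \code{ppo_config}.
#' @param ... Passed to \code{train_network} (budgets, criteria).
#' @return List with \code{net}, \code{target_trials} (final stage trial
#'   count), \code{stages} (per-stage summaries) and \code{criteria_met}
#'   for the target stage.
#' @export
curriculum_train <- function(net, target, curriculum = list(),
                             cfg = ppo_config(), ...) {
  stages <- list()
  for (sp in curriculum) {
    res <- train_network(net, sp, cfg, ...)
    if (!res$criteria_met)
      stop("curriculum stage '", sp$name, "' did not reach criterion")
    net <- res$net
    stages[[length(stages) + 1]] <- data.frame(
      task = sp$name, trials = res$trials, steps = res$steps)
  }
  res <- train_network(net, target, cfg, ...)
  stages[[length(stages) + 1]] <- data.frame(
    task = target$name, trials = res$trials, steps = res$steps)
  list(net = res$net, target_trials = res$trials,
       stages = do.call(rbind, stages), criteria_met = res$criteria_met)
}

#' Normalize curriculum trial counts by the per-target maximum
#'
#' @param counts data.frame with columns \code{target}, \code{condition},
#'   \code{trials}.
#' @return Same frame with a \code{normalized} column in (0, 1], computed
#'   within each target task.
#' @export
normalize_curriculum <- function(counts) {
  counts$normalized <- stats::ave(counts$trials, counts$target,
                                  FUN = function(x) x / max(x))
  counts
}
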