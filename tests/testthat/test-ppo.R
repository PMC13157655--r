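# PPO: returns, advantages, loss closed forms, analytic gradients.

test_that("bootstrapped returns match direct evaluation and a recursive oracle", {
  # terminal episode: R0 = gamma^2 * r2
  R <- bootstrapped_return(c(0, 0, 1), c(0, 0, 1), bootstrap = 5,
                           gamma = 0.99)
  expect_equal(R, c(0.9801, 0.99, 1))
  # no terminal: pure geometric bootstrap R_t = gamma^(T-t) * v
  v <- 2.5
  R <- bootstrapped_return(rep(0, 4), rep(0, 4), bootstrap = v,
                           gamma = 0.9)
  expect_equal(R, v * 0.9^(4:1))
  # random batches against an independent forward-sum oracle
  oracle <- function(r, d, boot, gamma) {
    Tn <- length(r)
    out <- numeric(Tn)
    for (t in seq_len(Tn)) {
      acc <- 0
      disc <- 1
      for (k in t:Tn) {
        acc <- acc + disc * r[k]
        if (d[k] == 1) { disc <- 0; break }
        disc <- disc * gamma
      }
      out[t] <- acc + disc * boot
    }
    out
  }
  set.seed(21)
  for (i in 1:20) {
    r <- rnorm(12); d <- rbinom(12, 1, 0.2); boot <- rnorm(1)
    expect_equal(bootstrapped_return(r, d, boot, 0.97),
                 oracle(r, d, boot, 0.97))
  }
  # advantages
  expect_equal(advantage(1, 0.3), 0.7)
  expect_equal(advantage(c(1, 2), c(1, 2)), c(0, 0))
})

test_that("surrogate clipping and entropy have their closed-form values", {
  # clip arithmetic of the surrogate objective
  clip_term <- function(ratio, A, eps)
    min(ratio * A, min(max(ratio, 1 - eps), 1 + eps) * A)
  expect_equal(clip_term(1, 1, 0.1), 1)      # clip inactive at ratio 1
  expect_equal(clip_term(1.5, 1, 0.1), 1.1)  # clipped at 1 + eps
  expect_equal(clip_term(0.5, -2, 0.1), -1.8)
  # uniform policy over 4 actions: entropy ln 4; with zero advantages and
  # zero returns the full loss reduces to -c2 * ln 4
  net <- zero_net(10)
  tb <- tiny_batch(net, T = 4)
  batch <- tb$batch
  batch$rewards[] <- 0; batch$dones[] <- 1; batch$values[] <- 0
  batch$v_boot[] <- 0
  expect_equal(ppo_total_loss(net, batch, tb$cfg), -0.01 * log(4),
               tolerance = 1e-10)
})

test_that("analytic BPTT gradient matches finite differences and the R reference", {
  set.seed(42)
  net <- tiny_net(10, seed = 3)
  tb <- tiny_batch(net, n_envs = 2, T = 6)
  batch <- tb$batch; cfg <- tb$cfg
  gr <- choicernn:::ppo_gradient(net, batch, cfg)
  grR <- choicernn:::ppo_gradient_r(net, batch, cfg)
  expect_equal(gr$loss, grR$loss, tolerance = 1e-12)
  for (p in names(gr$grads))
    expect_equal(gr$grads[[p]], grR$grads[[p]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  # central finite differences on the loss
  eps <- 1e-5
  worst <- 0
  for (p in c("W_rec", "W_in", "W_a", "W_c", "b", "b_a", "b_c")) {
    th <- net[[p]]
    for (i in sample(length(th), min(8, length(th)))) {
      n1 <- net; n1[[p]][i] <- th[i] + eps
      n2 <- net; n2[[p]][i] <- th[i] - eps
      fd <- (ppo_total_loss(n1, batch, cfg) -
               ppo_total_loss(n2, batch, cfg)) / (2 * eps)
      an <- gr$grads[[p]][i]
      if (abs(fd) > 1e-7 || abs(an) > 1e-7)
        worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("Dale constraints hold after optimizer updates", {
  set.seed(23)
  net <- tiny_net(10)
  cfg <- ppo_config(n_envs = 2, T = 8)
  be <- batch_env(task_spec("standard"), 2)
  hidden <- matrix(0, 10, 2)
  opt <- choicernn:::adam_init(net)
  for (i in 1:5) {
    batch <- choicernn:::collect_rollout(net, be, cfg, hidden)
    hidden <- batch$hidden_out
    gr <- choicernn:::ppo_gradient(net, batch, cfg)
    up <- choicernn:::adam_step(net, gr$grads, opt, cfg)
    net <- up$net; opt <- up$opt
    net <- enforce_dale(net)
    w <- effective_weights(net)
    expect_true(all(w$W_rec[, net$dale_sign > 0] >= 0))
    expect_true(all(w$W_rec[, net$dale_sign < 0] <= 0))
    expect_true(all(w$W_in >= 0) && all(w$W_a >= 0) && all(w$W_c >= 0))
  }
})

test_that("evaluation is reproducible given the RNG seed", {
  net <- tiny_net(20)
  set.seed(99)
  e1 <- evaluate_network(net, task_spec("standard"), n_trials = 60,
                         n_envs = 10)
  set.seed(99)
  e2 <- evaluate_network(net, task_spec("standard"), n_trials = 60,
                         n_envs = 10)
  expect_identical(e1$completion, e2$completion)
  expect_identical(e1$accuracy, e2$accuracy)
})

test_that("curriculum bookkeeping normalizes trial counts per target", {
  counts <- data.frame(
    target = rep(c("ternary", "sequential"), each = 3),
    condition = rep(c("rand", "stand", "stand_risky"), 2),
    trials = c(1000, 700, 400, 2000, 1500, 900))
  nn <- normalize_curriculum(counts)
  expect_true(all(nn$normalized > 0 & nn$normalized <= 1))
  expect_equal(sum(nn$normalized == 1), 2)  # one max per target
  expect_equal(nn$normalized[3], 0.4)
})

test_that("zero-shot evaluation covers every task without weight updates", {
  net <- tiny_net(20, seed = 24)
  w_before <- net$W_rec
  set.seed(25)
  tasks <- lapply(c("standard", "ternary"), task_spec)
  zs <- zero_shot_eval(net, tasks, n_trials = 40)
  expect_equal(zs$task, c("standard", "ternary"))
  expect_true(all(zs$completion >= 0 & zs$completion <= 1))
  expect_identical(net$W_rec, w_before)
})

test_that("an empty curriculum reduces to direct training", {
  set.seed(26)
  net <- tiny_net(20, seed = 26)
  res <- curriculum_train(net, task_spec("standard"), curriculum = list(),
                          cfg = ppo_config(n_envs = 4, T = 16),
                          total_steps = 128, eval_every = 1e9)
  expect_false(res$criteria_met)
  expect_equal(nrow(res$stages), 1)
  expect_equal(res$stages$task, "standard")
  expect_true(res$target_trials >= 0)
})
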