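# Task environments: offer sampling, trial structure, observations, rewards.

test_that("offer sampling respects value floor, quantity range and Eq-style product", {
  set.seed(11)
  rho <- goods_default()
  for (g in c("A", "C", "E")) {
    offs <- replicate(2000, sample_offer(g, rho[[g]]), simplify = FALSE)
    v <- vapply(offs, `[[`, 0, "value")
    q <- vapply(offs, `[[`, 0, "quantity")
    p <- vapply(offs, `[[`, 0, "probability")
    expect_true(all(v >= 1))
    expect_true(all(v <= 10 + 1e-12))
    expect_true(all(q <= 10 / rho[[g]] + 1e-12))
    expect_equal(v, rho[[g]] * q * p)
  }
  # deterministic slot: probability exactly 1
  od <- sample_offer("C", rho[["C"]], deterministic = TRUE)
  expect_identical(od$probability, 1)
  expect_equal(od$value, rho[["C"]] * od$quantity)
})

test_that("trial timelines stay in the stated uniform ranges on the 20-ms grid", {
  set.seed(12)
  sp <- task_spec("risky")
  for (i in 1:50) {
    tr <- build_trial(sp)
    tl <- tr$timeline
    durs <- c(tl["fix_end"], diff(tl)) * sp$dt_ms
    expect_true(all(durs[c("fix_end", "rule_end", "resp_start")] >= 500))
    expect_true(all(durs[c("fix_end", "rule_end", "resp_start")] <= 1500))
    expect_true(durs[["resp_end"]] <= 1000)
    expect_true(all(durs %% 20 == 0))
  }
  # fixed epochs are identical across trials (midpoints)
  t1 <- build_trial(sp, fixed_epochs = TRUE)$timeline
  t2 <- build_trial(sp, fixed_epochs = TRUE)$timeline
  expect_identical(t1, t2)
  # sequential presentation order is randomized ~50/50
  sq <- task_spec("sequential")
  ords <- replicate(2000, build_trial(sq)$order)
  expect_gt(mean(ords == 1), 0.45)
  expect_lt(mean(ords == 1), 0.55)
})

test_that("observations carry phase-specific signals over the 0.2 baseline", {
  set.seed(13)
  sp <- task_spec("standard")
  st <- env_reset(sp, fixed_epochs = TRUE)
  o <- encode_observation(st, noise = FALSE)
  expect_equal(unname(o["fix"]), 1.2)
  expect_true(all(o[setdiff(names(o), "fix")] == 0.2))
  # rule epoch: rule cue joins the fixation cue
  st$t <- st$trial$timeline[["fix_end"]]
  o <- encode_observation(st, noise = FALSE)
  expect_equal(unname(o["rule_standard"]), 1.2)
  expect_true(all(o[paste0("q_", c("A", "B", "D"))] == 0.2))
  # offer epoch: normalized quantity spans [0, 1] over baseline
  st$t <- st$trial$timeline[["rule_end"]]
  o <- encode_observation(st, noise = FALSE)
  qn <- st$trial$offers$q[["C"]] / (10 / sp$rho[["C"]])
  expect_equal(unname(o["q_C"]), 0.2 + qn)
  expect_equal(unname(o["p_C"]), 1.2)  # deterministic task: p = 1
  # response phase: fixation cue off (go signal)
  st$t <- st$trial$timeline[["resp_start"]]
  expect_equal(unname(encode_observation(st, noise = FALSE)["fix"]), 0.2)
})

test_that("sequential delay shows rule cue but no offers; one offer at a time", {
  set.seed(14)
  sp <- task_spec("sequential")
  st <- env_reset(sp, fixed_epochs = TRUE)
  tl <- st$trial$timeline
  st$t <- tl[["o1_end"]]  # delay phase
  o <- encode_observation(st, noise = FALSE)
  expect_true(all(o[paste0("q_", c("C", "E"))] == 0.2))
  expect_equal(unname(o["rule_sequential"]), 1.2)
  st$t <- tl[["rule_end"]]  # first offer only
  o <- encode_observation(st, noise = FALSE)
  shown <- names(which(o[paste0("q_", c("C", "E"))] > 0.2))
  expect_length(shown, 1)
  expect_equal(shown, paste0("q_", st$trial$first_good))
})

test_that("rewards follow the abort/Bernoulli/timeout rules", {
  set.seed(15)
  sp <- task_spec("standard")
  # premature choice aborts with -1
  st <- env_reset(sp)
  st <- env_step(st, 1L)
  expect_equal(st$reward, -1)
  expect_true(st$done && st$aborted && !st$completed)
  # choosing a deterministic offer pays rho * q
  st <- env_reset(sp)
  st$t <- st$trial$timeline[["resp_start"]]
  st <- env_step(st, 2L)
  expect_equal(st$reward, sp$rho[["E"]] * st$trial$offers$q[["E"]])
  expect_true(st$completed)
  expect_equal(st$rt_ms, 20)
  # risky offers pay rho*q with probability p (Monte-Carlo mean)
  sr <- task_spec("risky")
  st0 <- env_reset(sr)
  st0$t <- st0$trial$timeline[["resp_start"]]
  rew <- replicate(4000, env_step(st0, 1L)$reward)
  expected <- st0$trial$offers$values[1]
  expect_equal(mean(rew), expected, tolerance = 0.06)
  expect_true(all(rew %in% c(0, sr$rho[["C"]] * st0$trial$offers$q[["C"]])))
  # never responding ends the trial unrewarded and incomplete
  st <- env_reset(sp, fixed_epochs = TRUE)
  while (!st$done) st <- env_step(st, 0L)
  expect_equal(st$reward, 0)
  expect_false(st$completed)
  expect_false(st$aborted)
})

test_that("constrained risky offers form the orthogonal cross design", {
  set.seed(16)
  sp <- task_spec("risky", constrained = TRUE)
  n <- 1500
  arms <- character(n); qc <- pc <- qe <- numeric(n)
  for (i in seq_len(n)) {
    tr <- build_trial(sp)
    arms[i] <- tr$offers$arm
    qc[i] <- tr$offers$q[["C"]]; qe[i] <- tr$offers$q[["E"]]
    pc[i] <- tr$offers$p[["C"]]
    expect_true(all(tr$offers$values >= 1))
  }
  expect_gt(mean(arms == "fix_p"), 0.45)
  expect_lt(mean(arms == "fix_p"), 0.55)
  expect_true(all(pc[arms == "fix_p"] == 0.5))
  expect_true(all(qc[arms == "fix_q"] == 2.5))  # half of q_C max (rho_C = 2)
  expect_true(all(qe[arms == "fix_q"] == 5))
  # every trial lies on one arm of the cross: no trial varies both
  expect_true(all(arms %in% c("fix_p", "fix_q")))
})

test_that("batch environment matches the single-env contract", {
  set.seed(17)
  be <- batch_env(lapply(c("standard", "ternary"), task_spec), n = 6,
                  log_trials = TRUE)
  rho <- goods_default()
  for (i in 1:400) {
    st <- be_step(be, sample(0:3, 6, replace = TRUE,
                             prob = c(0.85, 0.05, 0.05, 0.05)))
    expect_true(all(st$reward >= -1))
  }
  d <- be_trial_log(be)
  expect_gt(nrow(d), 0)
  # rewards are 0, -1 or component sums of rho*q
  comp <- d[d$completed & !is.na(d$chosen), ]
  expect_true(all(d$reward[d$aborted] == -1))
  expect_true(all(comp$reward >= 0))
  # ternary trials expose three slot values, standard two
  expect_true(all(is.na(d$v3[d$task == "standard"])))
  expect_true(all(!is.na(d$v3[d$task == "ternary"])))
})

test_that("the C++ trainer environment matches the R environment's statistics", {
  # the trainer-side C++ batch env must implement the same task rules as
  # the reference R implementation: compare offer statistics, epoch
  # ranges and reward outcomes under a shared hold-then-timeout policy
  set.seed(18)
  sp <- task_spec("risky")
  env <- choicernn:::cpp_env_new(choicernn:::cpp_spec_list(list(sp)), 15)
  net <- zero_net(10)  # uniform policy network
  w <- effective_weights(net)
  kn <- net$cfg$sigma_rec * sqrt(2 / net$cfg$alpha)
  in_sd <- net$cfg$sigma_in * sqrt(2 / net$cfg$alpha)
  hidden <- matrix(0, 10, 15)
  rew_c <- c()
  for (i in 1:60) {
    b <- choicernn:::cpp_rollout(env, w$W_rec, w$W_in, w$W_a, w$W_c,
                                 net$b, net$b_a, net$b_c, hidden, 64,
                                 net$cfg$alpha, kn, in_sd, 0.2)
    hidden <- b$hidden_out
    rew_c <- c(rew_c, as.numeric(b$rewards))
    # observations: 16 channels with the 0.2 baseline
    expect_equal(dim(b$obs)[1], 16)
  }
  cnt <- choicernn:::cpp_env_counters(env)
  # uniform policy aborts nearly every trial with -1, as in the R env
  set.seed(19)
  be <- batch_env(sp, 15, log_trials = TRUE)
  for (i in 1:1500) be_step(be, sample(0:3, 15, TRUE))
  expect_gt(cnt$n_aborted / cnt$n_trials, 0.9)
  expect_gt(be$n_aborted / be$n_trials, 0.9)
  # nonzero rewards are either -1 or valid payoffs in (0, 10]
  nz <- rew_c[rew_c != 0]
  expect_true(all(nz == -1 | (nz > 0 & nz <= 10 + 1e-9)))
})
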