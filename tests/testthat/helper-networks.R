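# Small fixtures shared across test files.

# A tiny E/I network (n divisible by 5 keeps the 80/20 split integral).
tiny_net <- function(n = 20, seed = 1) {
  set.seed(seed)
  init_network(network_config(n = n))
}

# A network with all weights zeroed (pure leak dynamics).
zero_net <- function(n = 10) {
  net <- tiny_net(n)
  for (p in c("W_rec", "W_in", "W_a", "W_c")) net[[p]][] <- 0
  net$b[] <- 0; net$b_a[] <- 0; net$b_c <- 0
  net
}

# Collect a small rollout batch for PPO tests.
tiny_batch <- function(net, task = "standard", n_envs = 2, T = 6,
                       cfg = ppo_config(n_envs = n_envs, T = T,
                                        norm_adv = FALSE)) {
  be <- batch_env(task_spec(task), n_envs)
  hidden <- matrix(0, net$cfg$n, n_envs)
  batch <- choicernn:::collect_rollout(net, be, cfg, hidden)
  list(batch = batch, cfg = cfg)
}
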