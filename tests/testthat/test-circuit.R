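# Circuit analyses: input structure, pooled connectivity, SVD, lesions,
# output regressions, toy feedforward model.

test_that("selectivity index is exact, bounded and antisymmetric", {
  expect_equal(selectivity_index(1, 0), 1)
  expect_equal(selectivity_index(0.3, 0.3), 0)
  expect_equal(selectivity_index(3, 1), 0.5)
  expect_true(is.na(selectivity_index(0, 0)))
  set.seed(61)
  a <- runif(50); b <- runif(50)
  expect_equal(selectivity_index(a, b), -selectivity_index(b, a))
  expect_true(all(abs(selectivity_index(a, b)) <= 1))
})

test_that("input-weight correlations are unit on the diagonal and null when untrained", {
  net <- tiny_net(60, seed = 62)
  M <- input_weight_structure(net)
  expect_equal(unname(diag(M)), rep(1, 4))
  offdiag <- M[upper.tri(M)]
  expect_lt(max(abs(offdiag)), 0.35)  # independent random columns
})

test_that("value-weight regression detects planted linearity and rejects shuffles", {
  set.seed(63)
  nets <- lapply(1:8, function(i) tiny_net(20, seed = 100 + i))
  rho <- seq(1, 5, length.out = 8)
  # plant weights proportional to rho
  for (i in seq_along(nets)) {
    ch <- match("q_C", obs_channels())
    nets[[i]]$W_in[, ch] <- abs(nets[[i]]$W_in[, ch]) * 0 + rho[i] * 0.01
  }
  fits <- lapply(rho, function(r)
    structure(list(rho = c(C = r)), class = "behavior_fit"))
  vr <- suppressWarnings(value_weight_regression(fits, nets))  # exact fit
  expect_gt(vr$r2, 0.999)
  expect_gt(vr$slope, 0)
  # shuffled pairing destroys the association
  vr2 <- value_weight_regression(fits, nets[c(5, 3, 8, 1, 7, 2, 4, 6)])
  expect_lt(vr2$r2, 0.5)
})

test_that("reduced connectivity equals brute-force pool means and is equivariant", {
  set.seed(64)
  net <- tiny_net(20, seed = 65)
  labels <- rep(c("E:CHC", "E:CHE", "I:CHC", "I:CHE"), each = 5)
  red <- reduced_connectivity(net, labels)
  W <- effective_weights(net)$W_rec
  # brute-force average over all member pairs (off-diagonal within pool)
  rows <- which(labels == "E:CHC"); cols <- which(labels == "I:CHE")
  expect_equal(red$matrix["E:CHC", "I:CHE"], mean(W[rows, cols]))
  within <- W[rows, rows]
  expect_equal(red$matrix["E:CHC", "E:CHC"],
               mean(within[row(within) != col(within)]))
  # permuting labels permutes the pooled matrix accordingly
  perm <- sample(20)
  net2 <- net
  net2$W_rec <- net$W_rec[perm, perm]
  net2$dale_sign <- net$dale_sign[perm]
  red2 <- reduced_connectivity(net2, labels[perm])
  expect_equal(red2$matrix, red$matrix)
})

test_that("CRI score is positive iff cross-choice inhibition dominates", {
  lev <- c("E:CHC", "E:CHE", "I:CHC", "I:CHE")
  M <- matrix(0, 4, 4, dimnames = list(lev, lev))
  M["E:CHC", "I:CHE"] <- -0.8; M["E:CHE", "I:CHC"] <- -0.6  # cross
  M["E:CHC", "I:CHC"] <- -0.1; M["E:CHE", "I:CHE"] <- -0.1  # same
  expect_equal(cri_score(list(matrix = M)), 0.7 - 0.1)
  expect_true(is.na(cri_score(list(matrix = M[1:2, 1:2]))))
})

test_that("SVD spectrum identifies low-rank structure", {
  u <- rnorm(30); v <- rnorm(30)
  sp <- svd_spectrum(outer(u, v))
  expect_equal(sum(sp$d > 1e-10 * sp$d[1]), 1)
  expect_equal(sp$effective_rank, 1, tolerance = 1e-9)
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  spq <- svd_spectrum(Q)
  expect_equal(spq$d, rep(1, 10), tolerance = 1e-10)
  expect_equal(spq$effective_rank, 10, tolerance = 1e-9)
})

test_that("empty lesions leave paired performance unchanged", {
  net <- tiny_net(20, seed = 66)
  out <- lesion_battery(net, task_spec("standard"),
                        lesions = list(none = list(type = "clamp",
                                                   neurons = integer(0))),
                        n_trials = 40, seed = 5)
  expect_equal(out$completion_change_pct, 0)
})

test_that("output regressions isolate the driving variable", {
  set.seed(67)
  n <- 300
  cv <- runif(n, 1, 10); junk <- runif(n, 1, 10)
  outputs <- cbind(critic = cv + rnorm(n, 0, 0.3), flat = rep(1, n))
  r2 <- output_dynamics_regression(outputs, cbind(CV = cv, OTHER = junk))
  expect_gt(r2["critic", "CV"], 0.9)
  expect_lt(r2["critic", "OTHER"], 0.1)
  expect_equal(unname(r2["flat", ]), c(0, 0))
})

test_that("toy feedforward model: single unit is additive, population multiplies", {
  set.seed(68)
  q <- runif(400, 0, 5); p <- runif(400)
  # single ramp unit with b = 0: a plane in (q, p), no multiplicative gain
  act1 <- toy_feedforward(q, p, alpha = 1, beta = 0, n = 1)
  r1 <- mult_vs_add_readout(act1, q, p)
  expect_gt(r1$r2_additive, 0.99)
  expect_lt(r1$gap, 0)
  # piecewise linearity in (q, p): doubling inputs on the active side
  a <- toy_feedforward(c(1, 2), c(1, 2), alpha = 1, beta = 0, n = 1)
  expect_equal(a[2, 1], 2 * a[1, 1])
  # high-threshold regime: activity is better explained by the product
  # q*p than by the sum q+p (the corner-selective hinge resembles an AND)
  sweep <- toy_parameter_sweep(n_units = 50, n_trials = 2000)
  expect_gt(max(sweep$gap), 0.1)
  expect_true(all(sweep$r2_product <= 1 + 1e-9))
  # and a low-threshold regime where the additive account wins
  expect_lt(min(sweep$gap), -0.1)
})

test_that("mixed-selectivity pool rotates toy-model PCs toward the value sum", {
  set.seed(69)
  n <- 1500
  q1 <- runif(n); p1 <- runif(n); q2 <- runif(n); p2 <- runif(n)
  seg <- toy_two_offer_model(q1, p1, q2, p2, n_per_pool = 150,
                             variant = "segregated")
  mix <- toy_two_offer_model(q1, p1, q2, p2, n_per_pool = 150,
                             variant = "mixed")
  # mixed wiring pins PC1 to the value sum and away from the difference
  expect_gt(mix$axis_r2["PC1", "sum"], 0.8)
  expect_lt(mix$axis_r2["PC1", "diff"], 0.1)
  expect_gt(mix$axis_r2["PC1", "sum"],
            max(mix$axis_r2["PC1", c("OV1", "OV2")]))
  # and creates a dominant first dimension, unlike the segregated model
  ev_seg <- seg$pca$sdev[1:2]^2
  ev_mix <- mix$pca$sdev[1:2]^2
  expect_gt(ev_mix[1] / ev_mix[2], 1.5)
  expect_lt(ev_seg[1] / ev_seg[2], ev_mix[1] / ev_mix[2])
  # segregated pools represent both offer values in the top-2 subspace
  # without privileging their sum: the sum axis R2 never exceeds what a
  # rotation of two independent offer axes can produce
  r2_span <- function(v, pc) summary(lm(v ~ pc$x[, 1] + pc$x[, 2]))$r.squared
  expect_gt(r2_span(q1 * p1, seg$pca), 0.6)
  expect_gt(r2_span(q2 * p2, seg$pca), 0.6)
})
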