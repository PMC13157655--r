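# Neural analyses: regressions, selectivity, dimensionality, geometry,
# clustering — validated on planted-tuning fixtures with known truth.

test_that("per-neuron regression matches lm and flags degenerate input", {
  set.seed(41)
  x <- rnorm(40)
  y <- cbind(2 * x + 1, rnorm(40), -0.5 * x + rnorm(40, 0, 0.3))
  fit <- regress_neuron(y, x)
  # noiseless line: exact slope and R2 = 1
  expect_equal(fit$slope[1], 2, tolerance = 1e-10)
  expect_equal(fit$r2[1], 1, tolerance = 1e-10)
  for (j in 1:3) {
    lmfit <- suppressWarnings(summary(lm(y[, j] ~ x)))
    expect_equal(fit$slope[j], lmfit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(fit$r2[j], lmfit$r.squared, tolerance = 1e-8)
    expect_equal(fit$p[j], lmfit$coefficients[2, 4], tolerance = 1e-8)
  }
  expect_error(regress_neuron(y, rep(1, 40)), "degenerate")
})

test_that("slope p-values are calibrated under the null", {
  set.seed(42)
  x <- rnorm(60)
  y <- matrix(rnorm(60 * 1500), 60)  # 1500 independent null neurons
  fit <- regress_neuron(y, x)
  expect_lt(abs(mean(fit$p < 0.05) - 0.05), 0.015)
  expect_gt(suppressWarnings(ks.test(fit$p, "punif")$p.value), 0.01)
})

test_that("planted selectivity is recovered with correct fractions and TSI", {
  set.seed(43)
  fx <- synthetic_rate_fixture(
    "risky",
    groups = list(list(n = 12, var = "OVC", slope = 0.3),
                  list(n = 8, var = "CV", slope = 0.3),
                  list(n = 10, var = NA, slope = 0)),
    n_trials = 150, noise_sd = 0.05)
  prof <- classify_selectivity(fx$rates, fx$vars[, c("OVC", "OVE", "CV", "CH")])
  offer_bins <- (fx$epochs[["rule_end"]] + 1):fx$epochs[["resp_start"]]
  lab_offer <- prof$labels[offer_bins, ]
  # tuned groups are labelled with their planted variable in the offer epoch
  ovc_frac <- mean(lab_offer[, 1:12] == "OVC", na.rm = TRUE)
  expect_gt(ovc_frac, 0.8)
  # CV correlates with OVC/OVE by construction; require the planted label
  # to dominate within its group
  cv_lab <- table(factor(c(lab_offer[, 13:20]),
                         levels = c("OVC", "OVE", "CV", "CH")))
  expect_equal(names(which.max(cv_lab)), "CV")
  # untuned neurons are mostly unlabelled
  expect_lt(mean(!is.na(lab_offer[, 21:30])), 0.2)
  # TSI: pure coders are temporally stable (occasional false-positive
  # bins before offer onset dilute the index slightly below 1)
  tsi <- temporal_stability_index(prof)
  expect_gt(median(tsi[1:12], na.rm = TRUE), 0.7)
  expect_gt(median(tsi[1:12], na.rm = TRUE),
            median(tsi[21:30], na.rm = TRUE))
})

test_that("TSI arithmetic and tie-break are exact", {
  labs <- matrix(NA_character_, 10, 3)
  labs[, 1] <- "CV"                               # always CV -> 1
  labs[1:8, 2] <- "CV"; labs[9:10, 2] <- "OVC"    # 8/10 -> 0.8
  labs[1:5, 3] <- "OVC"; labs[6:10, 3] <- "CV"    # 5/5 tie -> 0.5
  tsi <- temporal_stability_index(labs, var_order = c("OVC", "OVE", "CV"))
  expect_equal(unname(tsi), c(1, 0.8, 0.5))
  # never-selective neuron is undefined
  expect_true(is.na(temporal_stability_index(
    matrix(NA_character_, 5, 1), var_order = "CV")))
})

test_that("delta-R2 separates categorical from mixed coding", {
  set.seed(44)
  # pure coders of each variable -> strict-mode bimodality at +/- max R2
  fx <- synthetic_rate_fixture(
    "risky",
    groups = list(list(n = 10, var = "OVC", slope = 0.5),
                  list(n = 10, var = "OVE", slope = 0.5)),
    n_trials = 150, noise_sd = 0.02)
  prof <- classify_selectivity(fx$rates, fx$vars[, c("OVC", "OVE")])
  dr <- delta_r2(prof, "OVC", "OVE", mode = "strict")
  expect_gt(length(dr), 0)
  expect_gt(max(dr), 0.5)
  expect_lt(min(dr), -0.5)
  expect_lt(mean(abs(dr) < 0.3), 0.1)  # few points near zero: bimodal
  # mixed coders (tuned to the sum) -> lenient-mode mass near zero
  fxm <- synthetic_rate_fixture(
    "risky",
    groups = list(list(n = 20, var = "VSUM", slope = 0.4)),
    n_trials = 150, noise_sd = 0.02)
  profm <- classify_selectivity(fxm$rates, fxm$vars[, c("OVC", "OVE", "VSUM")])
  drm <- delta_r2(profm, "OVC", "OVE", mode = "lenient")
  expect_gt(mean(abs(drm) < 0.3), 0.8)  # unimodal around zero
})

test_that("participation ratio has closed forms and invariances", {
  expect_equal(participation_ratio(c(1, 1)), 2)
  expect_equal(participation_ratio(c(1, 0, 0)), 1)
  expect_equal(participation_ratio(c(2, 1, 1)), 16 / 6)
  set.seed(45)
  X <- matrix(rnorm(200 * 6), 200) %*% diag(c(3, 2, 1, 0.5, 0.2, 0.1))
  pr <- participation_ratio(X)
  expect_gte(pr, 1); expect_lte(pr, 6)
  # invariant under orthogonal rotation of the neuron axes
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  expect_equal(participation_ratio(X %*% Q), pr, tolerance = 1e-9)
  # duplicating every neuron leaves PR unchanged (eigenvalues double)
  expect_equal(participation_ratio(cbind(X, X)), pr, tolerance = 1e-9)
  expect_error(participation_ratio(matrix(0, 10, 3)), "zero total variance")
})

test_that("planted two-axis geometry yields PR near 2 and PC regression recovers axes", {
  set.seed(46)
  n_tr <- 300
  # equal-variance planted axes so both dimensions carry the same power
  cv <- as.numeric(scale(runif(n_tr)))
  ch <- sample(c(-1, 1), n_tr, TRUE)
  ax1 <- rnorm(40); ax1 <- ax1 / sqrt(sum(ax1^2))
  ax2 <- rnorm(40); ax2 <- ax2 - ax1 * sum(ax1 * ax2)
  ax2 <- ax2 / sqrt(sum(ax2^2))
  # slightly unequal variances keep the two PCs identifiable
  X <- 1.3 * outer(cv, ax1) + outer(ch, ax2) +
    matrix(rnorm(n_tr * 40, 0, 0.05), n_tr)
  expect_equal(participation_ratio(X), 2, tolerance = 0.25)
  attr(X, "trial") <- seq_len(n_tr)
  vars <- cbind(CV = cv, CH = ch, junk = rnorm(n_tr))
  pcr <- pc_regression(X, vars, n_pc = 2)
  expect_gt(max(pcr$r2[, "CV"]), 0.9)
  expect_gt(max(pcr$r2[, "CH"]), 0.9)
  expect_lt(max(pcr$r2[, "junk"]), 0.1)
})

test_that("principal angles: identity, orthogonality, and Monte-Carlo null", {
  A <- diag(4)[, 1:2]
  expect_equal(max(principal_angles(A, A)), 0, tolerance = 1e-10)
  B <- diag(4)[, 3:4]
  expect_equal(principal_angles(A, B) * 180 / pi, c(90, 90))
  # random planes: smallest angle matches a brute-force sampling oracle
  set.seed(47)
  sim <- replicate(300, {
    X <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
    Y <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
    min(principal_angles(X, Y))
  })
  oracle <- replicate(300, {
    X <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
    Y <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
    acos(min(max(svd(crossprod(X, Y))$d), 1))  # independent formula
  })
  expect_gt(suppressWarnings(ks.test(sim, oracle)$p.value), 0.01)
})

test_that("orthogonal Procrustes recovers exact rotations and beats no alignment", {
  set.seed(48)
  X <- matrix(rnorm(5 * 3), 5)
  # identity case
  pa <- procrustes_align(X, X)
  expect_equal(pa$residual, 0, tolerance = 1e-18)
  # exact recovery of a known rotation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  pa2 <- procrustes_align(X %*% Q, X)
  expect_equal(pa2$rotation, t(Q), tolerance = 1e-10)
  expect_equal(pa2$residual, 0, tolerance = 1e-16)
  # noisy case: residual non-increasing vs unaligned, matches vegan oracle
  # (vegan centers configurations, so compare on centered data)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Xc %*% Q + matrix(rnorm(15, 0, 0.1), 5), scale = FALSE)
  pa3 <- procrustes_align(Yc, Xc)
  expect_lte(pa3$residual, pa3$residual_unaligned)
  skip_if_not_installed("vegan")
  vg <- vegan::procrustes(Xc, Yc, scale = FALSE, symmetric = FALSE)
  expect_equal(pa3$residual, sum(stats::residuals(vg)^2),
               tolerance = 1e-8)
})

test_that("task-variance clustering recovers planted modules", {
  set.seed(49)
  # three planted profiles: shared, ternary-specialized, sequential-specialized
  prof <- rbind(
    matrix(rep(c(1, 1, 1, 1, 1), each = 30), 30) ,
    matrix(rep(c(0.1, 0.1, 0.1, 1, 0.1), each = 30), 30),
    matrix(rep(c(0.1, 0.1, 0.1, 0.1, 1), each = 30), 30))
  colnames(prof) <- c("standard", "risky", "bundles", "ternary",
                      "sequential")
  prof <- pmin(pmax(prof + matrix(rnorm(450, 0, 0.05), 90), 0), 1)
  truth <- rep(1:3, each = 30)
  cl <- task_variance_clusters(prof, k_range = 2:8)
  expect_equal(unname(attr(cl, "k")["all"]), 3L)
  skip_if_not_installed("mclust")
  expect_gt(mclust::adjustedRandIndex(cl$cluster, truth), 0.9)
  # degenerate identical profiles are flagged
  flat <- matrix(1, 30, 5)
  cl2 <- task_variance_clusters(flat, k_range = 2:5)
  expect_true(attr(cl2, "degenerate"))
})

test_that("task-variance profiles normalize to unit maximum per neuron", {
  set.seed(50)
  mk_rec <- function(scale) {
    rates <- array(rnorm(40 * 60 * 8, 0, scale), c(40, 60, 8))
    list(rates = rates, dt_ms = 20,
         epochs = c(fix_end = 10, rule_end = 20, o1_end = 20, d_end = 20,
                    resp_start = 60, resp_end = 110))
  }
  recs <- list(standard = mk_rec(1), risky = mk_rec(0.2))
  prof <- task_variance_profiles(recs)
  expect_equal(unname(apply(prof, 1, max)), rep(1, 8))
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("fractional task variance is bounded with exact special cases", {
  expect_equal(fractional_task_variance(1, 1), 0)
  expect_equal(fractional_task_variance(2, 0), 1)
  expect_equal(fractional_task_variance(0, 3), -1)
  expect_length(fractional_task_variance(0, 0), 0)  # excluded
  set.seed(51)
  tv1 <- c(runif(30, 0.8, 1), runif(30, 0, 0.02))
  tv2 <- c(runif(30, 0, 0.02), runif(30, 0.8, 1))
  f <- fractional_task_variance(tv1, tv2)
  expect_true(all(abs(f) <= 1))
  expect_gt(mean(abs(f) > 0.9), 0.9)  # disjoint populations: peaks at +/-1
})

test_that("reaction-time regression is null for difficulty-independent RTs", {
  set.seed(52)
  d <- data.frame(completed = TRUE, v1 = runif(400, 1, 10),
                  v2 = runif(400, 1, 10),
                  rt_ms = 20 * sample(1:10, 400, TRUE))
  rt <- reaction_times(d)
  expect_gt(rt$p, 0.01)
  # RT on the first response step is one 20-ms bin
  expect_true(all(rt$rt_ms >= 20))
})
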