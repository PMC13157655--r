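# ---------------------------------------------------------------------------
# Single-neuron and population analyses on firing-rate tensors.
#
# Rate tensors are [trial, time, neuron] arrays collected on trials with
# fixed (midpoint) epoch durations so that time bins align across trials;
# sequential trials are thereby aligned to second-stimulus onset as well.
# ---------------------------------------------------------------------------

#' Collect a firing-rate tensor from a network
#'
#' Simulates time-synchronized trials with fixed epoch durations and
#' records the recurrent rates at every 20-ms bin from trial start up to
#' the response-phase onset (fixation + rule + offer epochs). The policy
#' acts as usual during the response phase so choices and reaction times
#' are logged; only completed trials enter the returned tensor unless
#' \code{keep_incomplete}.
#'
#' @param net An \code{ei_network} (possibly lesioned).
#' @param spec A \code{choice_task}.
#' @param n_trials Completed trials to collect.
#' @param n_envs Environments simulated in parallel per round.
#' @param force_hold If \code{TRUE}, the hold action is forced until the
#'   response phase (passive viewing) — used to measure stimulus-period
#'   activity of networks that can no longer perform the task (e.g. after
#'   a lesion); such trials are recorded regardless of behavioral outcome.
#' @param keep_incomplete Keep aborted/timeout trials in the tensor.
#' @param max_rounds Simulation-round cap; a network that completes few
#'   or no trials (e.g. after a severe lesion, or an unconverged
#'   training run) returns whatever was collected instead of looping.
#' @return List: \code{rates} [trial, time, neuron], \code{trials} (log
#'   rows matching the tensor's first dimension), \code{epochs} (named
#'   step boundaries), \code{dt_ms}.
#' @export
collect_rates <- function(net, spec, n_trials = 500, n_envs = 50,
                          force_hold = FALSE, keep_incomplete = FALSE,
                          max_rounds = ceiling(5 * n_trials / n_envs) + 5) {
  ncfg <- net$cfg
  w <- effective_weights(net)
  got <- 0
  rounds <- 0
  rate_blocks <- list()
  trial_blocks <- list()
  epochs <- NULL
  while (got < n_trials && rounds < max_rounds) {
    rounds <- rounds + 1
    be <- batch_env(spec, n_envs, fixed_epochs = TRUE, log_trials = TRUE,
                    auto_reset = FALSE)
    t_rec <- be$resp_start[1]
    t_end <- be$resp_end[1]
    if (is.null(epochs))
      epochs <- c(fix_end = be$fix_end[1], rule_end = be$rule_end[1],
                  o1_end = be$o1_end[1], d_end = be$d_end[1],
                  resp_start = be$resp_start[1], resp_end = be$resp_end[1])
    rr <- array(NA_real_, c(n_envs, t_rec, ncfg$n))
    hidden <- matrix(0, ncfg$n, n_envs)
    for (t in 0:(t_end - 1)) {
      u <- be_obs(be, noise = TRUE, sigma_in = ncfg$sigma_in,
                  alpha = ncfg$alpha)
      ps <- policy_step(net, w, hidden, u,
                        matrix(stats::rnorm(ncfg$n * n_envs), ncfg$n),
                        unif = stats::runif(n_envs))
      hidden <- ps$r
      if (t < t_rec) rr[, t + 1, ] <- t(hidden)
      a <- ps$action
      if (force_hold && t < t_rec) a[] <- 0L
      st <- be_step(be, a)
      if (all(st$terminal)) break
      hidden[, st$terminal] <- 0
    }
    d <- be_trial_log(be)
    d <- d[order(d$env), , drop = FALSE]
    keep <- if (keep_incomplete || force_hold) seq_len(nrow(d)) else
      which(d$completed)
    if (length(keep)) {
      rate_blocks[[length(rate_blocks) + 1]] <-
        rr[d$env[keep], , , drop = FALSE]
      trial_blocks[[length(trial_blocks) + 1]] <- d[keep, , drop = FALSE]
      got <- got + length(keep)
    }
  }
  if (length(rate_blocks) == 0)
    stop("no trials collected in ", max_rounds,
         " rounds (network completes no trials)")
  rates <- do.call(abind_1, rate_blocks)
  trials <- do.call(rbind, trial_blocks)
  if (got > n_trials) {
    rates <- rates[seq_len(n_trials), , , drop = FALSE]
    trials <- trials[seq_len(n_trials), , drop = FALSE]
  }
  list(rates = rates, trials = trials, epochs = epochs, dt_ms = spec$dt_ms)
}

# bind arrays along the first dimension
abind_1 <- function(...) {
  xs <- list(...)
  if (length(xs) == 1) return(xs[[1]])
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 0)),
                           d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Decision-variable matrix for a set of trials
#'
#' Builds the candidate regressors for selectivity analyses: per-slot
#' offer values (e.g. OVC, OVE; OVBC/OVDE for bundles; OVA/OVC/OVE for
#' ternary), chosen value CV, choice CH (+1 for slot 1, -1 for slot 2;
#' per-option indicators for ternary), value sum and difference, and the
#' conjunctive chosen-value variables (CVC = value of C on trials where C
#' was chosen, zero otherwise).
#'
#' @param trials Trial data.frame (completed trials).
#' @param task Task name (default: from the data).
#' @return Numeric matrix (trials x variables) with named columns.
#' @export
decision_variables <- function(trials, task = NULL) {
  if (is.null(task)) task <- trials$task[1]
  slot_names <- switch(task,
    standard = c("C", "E"), risky = c("C", "E"),
    sequential = c("C", "E"),
    bundles = c("BC", "DE"), ternary = c("A", "C", "E"))
  v <- cbind(trials$v1, trials$v2, if (task == "ternary") trials$v3)
  cv <- v[cbind(seq_len(nrow(v)), trials$chosen)]
  out <- list()
  for (k in seq_along(slot_names))
    out[[paste0("OV", slot_names[k])]] <- v[, k]
  out$CV <- cv
  if (task == "ternary") {
    for (k in seq_along(slot_names))
      out[[paste0("CH", slot_names[k])]] <- as.numeric(trials$chosen == k)
  } else {
    out$CH <- ifelse(trials$chosen == 1, 1, -1)
    out$VSUM <- v[, 1] + v[, 2]
    out$VDIFF <- v[, 1] - v[, 2]
  }
  for (k in seq_along(slot_names))
    out[[paste0("CV", slot_names[k])]] <-
      ifelse(trials$chosen == k, v[, k], 0)
  do.call(cbind, out)
}

#' Per-neuron linear regression at one time bin
#'
#' Ordinary least squares of rates on a single variable with the
#' closed-form slope, coefficient of determination and two-sided t-test
#' p-value for the slope.
#'
#' @param y Rate vector (or trials x neurons matrix).
#' @param x Regressor vector (variance > 0, length >= 3).
#' @return data.frame with \code{slope}, \code{intercept}, \code{r2},
#'   \code{p} (one row per neuron).
#' @export
regress_neuron <- function(y, x) {
  y <- as.matrix(y)
  n <- length(x)
  stopifnot(n >= 3, nrow(y) == n)
  if (stats::var(x) == 0) stop("degenerate regressor (zero variance)")
  sy <- apply(y, 2, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(x, y)))
  r[is.na(r)] <- 0
  slope <- r * sy / stats::sd(x)
  intercept <- colMeans(y) - slope * mean(x)
  r2 <- r^2
  tt <- r * sqrt((n - 2) / pmax(1 - r2, 1e-12))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(slope = slope, intercept = intercept, r2 = r2, p = p)
}

#' Selectivity classification over time and neurons
#'
#' Regresses every neuron's rate on every candidate variable at every
#' time bin and assigns, per neuron-time point, the variable with the
#' maximum R2 among those meeting the two-step criterion (p < 0.05 and
#' R2 >= 0.005); none otherwise.
#'
#' @param rates Tensor [trial, time, neuron].
#' @param vars Matrix (trials x variables) from
#'   \code{\link{decision_variables}}.
#' @param p_thresh,r2_thresh Selectivity criteria.
#' @return Object of class \code{selectivity_profile}: \code{labels}
#'   (time x neuron character matrix, NA = non-selective), and
#'   \code{r2}, \code{p}, \code{slope} arrays [time, neuron, variable].
#' @export
classify_selectivity <- function(rates, vars, p_thresh = 0.05,
                                 r2_thresh = 0.005) {
  nt <- dim(rates)[2]; nn <- dim(rates)[3]; nv <- ncol(vars)
  vn <- colnames(vars)
  r2 <- array(NA_real_, c(nt, nn, nv), dimnames = list(NULL, NULL, vn))
  pv <- array(NA_real_, c(nt, nn, nv), dimnames = list(NULL, NULL, vn))
  sl <- array(NA_real_, c(nt, nn, nv), dimnames = list(NULL, NULL, vn))
  for (t in seq_len(nt)) {
    y <- rates[, t, ]
    for (k in seq_len(nv)) {
      fit <- regress_neuron(y, vars[, k])
      r2[t, , k] <- fit$r2
      pv[t, , k] <- fit$p
      sl[t, , k] <- fit$slope
    }
  }
  labels <- matrix(NA_character_, nt, nn)
  for (t in seq_len(nt)) {
    pass <- pv[t, , ] < p_thresh & r2[t, , ] >= r2_thresh
    r2m <- r2[t, , ]
    r2m[!pass] <- -Inf
    best <- max.col(r2m, ties.method = "first")
    any_pass <- rowSums(pass, na.rm = TRUE) > 0
    labels[t, any_pass] <- vn[best[any_pass]]
  }
  structure(list(labels = labels, r2 = r2, p = pv, slope = sl,
                 variables = vn), class = "selectivity_profile")
}

#' Fraction of selective neurons per variable over time
#'
#' @param profile A \code{selectivity_profile}.
#' @param types Optional cell-type vector ("E"/"I") to split populations.
#' @return data.frame: time bin, variable, (type), fraction selective.
#' @export
fraction_selective <- function(profile, types = NULL) {
  nt <- nrow(profile$labels)
  grp <- if (is.null(types)) list(all = seq_len(ncol(profile$labels)))
         else split(seq_along(types), types)
  out <- list()
  for (g in names(grp)) {
    sub <- profile$labels[, grp[[g]], drop = FALSE]
    for (v in profile$variables) {
      out[[length(out) + 1]] <- data.frame(
        time = seq_len(nt), variable = v, population = g,
        fraction = rowMeans(sub == v, na.rm = FALSE))
    }
  }
  d <- do.call(rbind, out)
  d$fraction[is.na(d$fraction)] <- 0
  d
}

#' Temporal stability index
#'
#' For each neuron selective at one or more time bins, the primary
#' variable is the modal selectivity label (ties broken by the canonical
#' variable order of the profile); the TSI is the fraction of the
#' neuron's selective bins assigned to that primary variable.
#'
#' @param profile A \code{selectivity_profile} (or a time x neuron label
#'   matrix).
#' @param var_order Canonical tie-break order; defaults to the profile's
#'   variable order.
#' @return Numeric vector of TSI in [0, 1]; NA for never-selective
#'   neurons.
#' @export
temporal_stability_index <- function(profile, var_order = NULL) {
  labels <- if (inherits(profile, "selectivity_profile")) profile$labels
            else profile
  if (is.null(var_order))
    var_order <- if (inherits(profile, "selectivity_profile"))
      profile$variables else sort(unique(stats::na.omit(c(labels))))
  apply(labels, 2, function(l) {
    l <- l[!is.na(l)]
    if (length(l) == 0) return(NA_real_)
    cnt <- table(factor(l, levels = var_order))
    max(cnt) / length(l)
  })
}

#' Differences in explained variance between two variables
#'
#' Delta R2 = R2(var1) - R2(var2) over included neuron-time points.
#' Inclusion: \code{"strict"} requires max(R2) >= 0.5 (highly specialized
#' subpopulation); \code{"lenient"} requires the standard selectivity
#' criterion (p < 0.05 and R2 >= 0.005) for at least one of the pair.
#'
#' @param profile A \code{selectivity_profile}.
#' @param var1,var2 Variable names.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @param r2_strict,p_thresh,r2_thresh Thresholds.
#' @return Numeric vector of included Delta R2 values.
#' @export
delta_r2 <- function(profile, var1, var2, mode = c("strict", "lenient"),
                     r2_strict = 0.5, p_thresh = 0.05, r2_thresh = 0.005) {
  mode <- match.arg(mode)
  r1 <- profile$r2[, , var1]
  r2_ <- profile$r2[, , var2]
  if (mode == "strict") {
    inc <- pmax(r1, r2_) >= r2_strict
  } else {
    ok1 <- profile$p[, , var1] < p_thresh & r1 >= r2_thresh
    ok2 <- profile$p[, , var2] < p_thresh & r2_ >= r2_thresh
    inc <- ok1 | ok2
  }
  (r1 - r2_)[inc]
}

#' Participation ratio of population activity
#'
#' \code{D_PR = (sum lambda)^2 / sum lambda^2} over the eigenvalues of
#' the activity covariance matrix: 1 when all variance lies in one
#' dimension, M when spread evenly over M dimensions.
#'
#' @param X Samples x neurons activity matrix (or a vector of
#'   eigenvalues).
#' @return Scalar dimensionality in [1, rank].
#' @export
participation_ratio <- function(X) {
  lambda <- if (is.null(dim(X))) X else {
    stopifnot(nrow(X) >= 2)
    eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  }
  lambda <- pmax(lambda, 0)
  s <- sum(lambda)
  if (s <= 0) stop("zero total variance")
  s^2 / sum(lambda^2)
}

#' Stimulus-period activity window
#'
#' Extracts the last \code{window_ms} of the offer (stimulus) epoch from
#' a rate tensor and returns it concatenated across trials.
#'
#' @param rec Output of \code{\link{collect_rates}}.
#' @param window_ms Window length before response onset.
#' @param average Average over the window per trial (one row per trial)
#'   instead of concatenating time bins.
#' @return Samples x neurons matrix; attribute \code{"trial"} maps rows
#'   to trials.
#' @export
offer_window <- function(rec, window_ms = 200, average = FALSE) {
  nb <- window_ms / rec$dt_ms
  t_end <- rec$epochs[["resp_start"]]
  bins <- (t_end - nb + 1):t_end
  sub <- rec$rates[, bins, , drop = FALSE]
  n_tr <- dim(sub)[1]; nn <- dim(sub)[3]
  if (average) {
    out <- apply(sub, c(1, 3), mean)
    attr(out, "trial") <- seq_len(n_tr)
    return(out)
  }
  out <- matrix(aperm(sub, c(2, 1, 3)), n_tr * length(bins), nn)
  attr(out, "trial") <- rep(seq_len(n_tr), each = length(bins))
  out
}

#' Principal-component regression of population activity
#'
#' PCA (per-neuron mean centering, no scaling) on the stimulus-window
#' activity; the per-trial mean projections onto the first \code{n_pc}
#' PCs are each regressed on each decision variable; the R2 heatmap
#' summarizes which variables the leading population dimensions encode.
#'
#' @param X Samples x neurons activity (from \code{\link{offer_window}}).
#' @param vars Trials x variables matrix.
#' @param n_pc Number of leading PCs.
#' @return List: \code{r2} (n_pc x variables matrix), \code{pca}
#'   (prcomp), \code{scores} per trial.
#' @export
pc_regression <- function(X, vars, n_pc = 3) {
  trial <- attr(X, "trial")
  stopifnot(!is.null(trial), max(trial) == nrow(vars))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pca$x))
  sc <- pca$x[, seq_len(n_pc), drop = FALSE]
  sc_tr <- apply(sc, 2, function(s) tapply(s, trial, mean))
  r2 <- matrix(NA_real_, n_pc, ncol(vars),
               dimnames = list(paste0("PC", seq_len(n_pc)),
                               colnames(vars)))
  for (i in seq_len(n_pc)) for (k in seq_len(ncol(vars))) {
    if (stats::var(vars[, k]) == 0) { r2[i, k] <- 0; next }
    r2[i, k] <- suppressWarnings(stats::cor(sc_tr[, i], vars[, k])^2)
  }
  r2[is.na(r2)] <- 0
  list(r2 = r2, pca = pca, scores = sc_tr)
}

#' Principal angles between two subspaces
#'
#' @param A,B Matrices whose columns span the subspaces (orthonormalized
#'   internally).
#' @return Vector of canonical angles (radians, increasing).
#' @export
principal_angles <- function(A, B) {
  Qa <- qr.Q(qr(A)); Qb <- qr.Q(qr(B))
  s <- svd(crossprod(Qa, Qb))$d
  acos(pmin(pmax(sort(s, decreasing = TRUE), -1), 1))
}

#' Pairwise subspace angles between task representations
#'
#' For each task's activity matrix, a subspace is defined by the top
#' round(PR) principal components; the reported statistic is the largest
#' canonical angle between each pair of subspaces (the most conservative
#' overlap measure; \code{angle = "first"} gives the smallest).
#'
#' @param activity_by_task Named list of samples x neurons matrices.
#' @param angle \code{"largest"} or \code{"first"}.
#' @return List: \code{angles} (task x task matrix, degrees), \code{n_pc}
#'   per task.
#' @export
subspace_angle_matrix <- function(activity_by_task,
                                  angle = c("largest", "first")) {
  angle <- match.arg(angle)
  bases <- lapply(activity_by_task, function(X) {
    k <- max(1L, as.integer(round(participation_ratio(X))))
    pr <- stats::prcomp(X, center = TRUE)
    pr$rotation[, seq_len(min(k, ncol(pr$rotation))), drop = FALSE]
  })
  nt <- length(bases)
  ang <- matrix(0, nt, nt,
                dimnames = list(names(bases), names(bases)))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    a <- principal_angles(bases[[i]], bases[[j]])
    ang[i, j] <- (if (angle == "largest") max(a) else min(a)) * 180 / pi
  }
  list(angles = ang, n_pc = vapply(bases, ncol, 0L))
}

#' Orthogonal Procrustes alignment to a reference configuration
#'
#' Finds the orthogonal matrix Q minimizing ||X Q - ref||_F (closed-form
#' solution via the SVD of X' ref) and returns the aligned points.
#'
#' @param X Points x dims configuration to align.
#' @param ref Reference configuration (same shape).
#' @return List: \code{rotation} Q, \code{aligned} = X Q,
#'   \code{residual} (sum of squared distances after alignment),
#'   \code{residual_unaligned}, \code{degenerate} flag (rank-deficient
#'   cross-covariance).
#' @export
procrustes_align <- function(X, ref) {
  stopifnot(all(dim(X) == dim(ref)))
  M <- crossprod(X, ref)
  sv <- svd(M)
  degenerate <- any(sv$d < 1e-10 * max(sv$d, 1e-300))
  Q <- sv$u %*% t(sv$v)
  aligned <- X %*% Q
  list(rotation = Q, aligned = aligned,
       residual = sum((aligned - ref)^2),
       residual_unaligned = sum((X - ref)^2),
       degenerate = degenerate)
}

#' Normalized task-variance profiles
#'
#' Per neuron, the variance of its stimulus-period rate across trials of
#' each task, normalized by its maximum variance across tasks.
#'
#' @param recs Named list (one per task) of \code{\link{collect_rates}}
#'   outputs.
#' @param window_ms Stimulus window used for the variance.
#' @return Neurons x tasks matrix; attribute \code{"raw"} holds the
#'   unnormalized variances. Neurons with zero variance in all tasks get
#'   NA rows.
#' @export
task_variance_profiles <- function(recs, window_ms = 200) {
  tv <- sapply(recs, function(rec) {
    X <- offer_window(rec, window_ms, average = TRUE)
    apply(X, 2, stats::var)
  })
  mx <- apply(tv, 1, max)
  prof <- tv / ifelse(mx > 0, mx, NA)
  attr(prof, "raw") <- tv
  prof
}

#' Cluster neurons by task-variance profile
#'
#' k-means (20 restarts) on normalized task-variance profiles, run
#' separately per population when cell types are given; k chosen from
#' \code{k_range} by maximum mean silhouette width.
#'
#' @param profiles Neurons x tasks matrix from
#'   \code{\link{task_variance_profiles}}.
#' @param types Optional "E"/"I" vector splitting the populations.
#' @param k_range Candidate cluster counts.
#' @param nstart k-means restarts.
#' @return data.frame with neuron, population, cluster; attributes
#'   \code{k} (chosen per population), \code{centers},
#'   \code{silhouette}, \code{degenerate} flag.
#' @export
task_variance_clusters <- function(profiles, types = NULL,
                                   k_range = 2:20, nstart = 20) {
  ok <- stats::complete.cases(profiles)
  grp <- if (is.null(types)) list(all = which(ok))
         else lapply(split(seq_along(types), types), intersect, which(ok))
  res <- list(); ks <- c(); sil <- c(); centers <- list()
  degenerate <- FALSE
  for (g in names(grp)) {
    idx <- grp[[g]]
    P <- profiles[idx, , drop = FALSE]
    dmat <- stats::dist(P)
    best <- NULL
    for (k in k_range) {
      if (k >= nrow(P) || nrow(unique(P)) <= k) break
      km <- try(stats::kmeans(P, k, nstart = nstart), silent = TRUE)
      if (inherits(km, "try-error")) next
      sw <- mean(cluster::silhouette(km$cluster, dmat)[, 3])
      if (is.null(best) || sw > best$sw) best <- list(km = km, sw = sw, k = k)
    }
    if (is.null(best)) {  # degenerate: identical profiles
      best <- list(km = list(cluster = rep(1L, nrow(P)),
                             centers = P[1, , drop = FALSE]),
                   sw = NA_real_, k = 2L)
      degenerate <- TRUE
    }
    res[[g]] <- data.frame(neuron = idx, population = g,
                           cluster = best$km$cluster)
    ks[g] <- best$k; sil[g] <- best$sw
    centers[[g]] <- best$km$centers
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "k") <- ks
  attr(out, "silhouette") <- sil
  attr(out, "centers") <- centers
  attr(out, "degenerate") <- degenerate
  out
}

#' Fractional task variance between two tasks
#'
#' (TV1 - TV2) / (TV1 + TV2) per neuron, in [-1, 1]; neurons with zero
#' summed variance are excluded.
#'
#' @param tv1,tv2 Per-neuron variance vectors.
#' @return Numeric vector of included values.
#' @export
fractional_task_variance <- function(tv1, tv2) {
  s <- tv1 + tv2
  keep <- is.finite(s) & s > 0
  ((tv1 - tv2) / s)[keep]
}

#' Reaction times and their relation to decision difficulty
#'
#' RT is measured from response-phase onset to the choice step. A linear
#' regression of RT on the absolute value difference of the two offers
#' tests whether harder decisions take longer.
#'
#' @param trials Trial log (completed trials used).
#' @return List: \code{rt_ms} vector, \code{slope} (ms per value unit),
#'   \code{p}, \code{fit} (lm object).
#' @export
reaction_times <- function(trials) {
  d <- trials[trials$completed, , drop = FALSE]
  d$dv <- abs(d$v1 - d$v2)
  if (stats::var(d$dv) == 0 || nrow(d) < 3)
    return(list(rt_ms = d$rt_ms, slope = NA_real_, p = NA_real_,
                fit = NULL))
  fit <- stats::lm(rt_ms ~ dv, data = d)
  co <- summary(fit)$coefficients
  list(rt_ms = d$rt_ms, slope = co["dv", 1], p = co["dv", 4], fit = fit)
}

#' Synthetic rate tensor with planted tuning
#'
#' Generates a firing-rate tensor with known ground truth to validate
#' the analysis suite independently of network training: trials are drawn
#' from a task's offer distribution (fixed epochs), choices from the
#' logistic behavioral model, and each neuron group's rate follows a
#' linear (or conjunctive) tuning to one decision variable during the
#' offer epoch plus Gaussian noise.
#'
#' @param task Task name.
#' @param groups List of groups: each a list with \code{n} (neurons),
#'   \code{var} (column of \code{\link{decision_variables}} or NA for
#'   untuned), \code{slope}, optional \code{baseline} (default 1).
#' @param n_trials Number of trials.
#' @param noise_sd Rate noise SD.
#' @param eta,gamma Behavioral parameters generating the choices.
#' @return List like \code{\link{collect_rates}} plus \code{truth}
#'   (per-neuron ground-truth variable) and \code{vars}.
#' @export
synthetic_rate_fixture <- function(task = "risky", groups, n_trials = 200,
                                   noise_sd = 0.1, eta = 20, gamma = 1) {
  spec <- task_spec(task)
  rho_hat <- as.list(spec$rho[setdiff(GOOD_IDS, "E")])
  names(rho_hat) <- setdiff(GOOD_IDS, "E")
  d <- simulate_choices(task, n_trials, rho_hat, gamma = gamma, eta = eta)
  d$v1 <- spec$rho[[spec$slots[[1]]$goods[1]]] * 0  # filled below
  vals <- sapply(spec$slots, function(sl) {
    v <- 0
    for (g in sl$goods)
      v <- v + spec$rho[[g]] * d[[paste0("q_", g)]] * d[[paste0("p_", g)]]
    v
  })
  d$v1 <- vals[, 1]; d$v2 <- vals[, 2]
  d$v3 <- if (ncol(vals) > 2) vals[, 3] else NA_real_
  vars <- decision_variables(d, task)
  tl <- build_trial(spec, fixed_epochs = TRUE)$timeline
  nt <- tl[["resp_start"]]
  onset <- tl[["rule_end"]]
  truth <- unlist(lapply(groups, function(g) rep(
    if (is.null(g$var) || is.na(g$var)) NA_character_ else g$var, g$n)))
  nn <- length(truth)
  rates <- array(stats::rnorm(n_trials * nt * nn, 0, noise_sd),
                 c(n_trials, nt, nn))
  j <- 0
  for (g in groups) {
    base <- if (is.null(g$baseline)) 1 else g$baseline
    for (i in seq_len(g$n)) {
      j <- j + 1
      drive <- if (is.null(g$var) || is.na(g$var)) rep(base, n_trials)
               else base + g$slope * vars[, g$var]
      # tuning switches on at offer onset
      rates[, (onset + 1):nt, j] <-
        rates[, (onset + 1):nt, j] + drive
      rates[, seq_len(onset), j] <- rates[, seq_len(onset), j] + base
    }
  }
  epochs <- c(fix_end = tl[["fix_end"]], rule_end = tl[["rule_end"]],
              o1_end = if (spec$sequential) tl[["o1_end"]] else tl[["rule_end"]],
              d_end = if (spec$sequential) tl[["d_end"]] else tl[["rule_end"]],
              resp_start = tl[["resp_start"]], resp_end = tl[["resp_end"]])
  d$completed <- TRUE
  list(rates = rates, trials = d, epochs = epochs, dt_ms = spec$dt_ms,
       truth = truth, vars = vars)
}
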