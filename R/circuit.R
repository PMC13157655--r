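# ---------------------------------------------------------------------------
# Connectivity-level analyses and causal circuit experiments.
# ---------------------------------------------------------------------------

#' Input selectivity index of a neuron
#'
#' \code{SI = (w_qC - w_qE) / (w_qC + w_qE)}: +1 for a neuron driven
#' exclusively by good C's quantity input, -1 for good E, 0 for balanced
#' input. Pairs with zero summed weight are excluded (NA).
#'
#' @param w_qC,w_qE Non-negative input weights (vectors allowed).
#' @return SI values in [-1, 1].
#' @export
selectivity_index <- function(w_qC, w_qE) {
  s <- w_qC + w_qE
  ifelse(s > 0, (w_qC - w_qE) / s, NA_real_)
}

#' Correlation structure of offer-feature input weights
#'
#' Pearson correlations between the input-weight columns (over recurrent
#' neurons) of the offer features relevant to a task: quantity and
#' probability channels of the offered goods.
#'
#' @param net Trained \code{ei_network}.
#' @param goods Goods whose features to include.
#' @return Feature x feature correlation matrix.
#' @export
input_weight_structure <- function(net, goods = c("C", "E")) {
  w <- effective_weights(net)$W_in
  colnames(w) <- obs_channels()
  feats <- c(paste0("q_", goods), paste0("p_", goods))
  stats::cor(w[, feats])
}

#' Mean non-zero excitatory input weight for one channel
#'
#' @param net An \code{ei_network}.
#' @param channel Input channel name (e.g. \code{"q_C"}).
#' @param tol Weights below \code{tol} count as zero.
#' @return Mean of the non-zero weights onto excitatory neurons.
#' @export
mean_input_weight <- function(net, channel = "q_C", tol = 1e-8) {
  w <- effective_weights(net)$W_in
  colnames(w) <- obs_channels()
  exc <- net$dale_sign > 0
  v <- w[exc, channel]
  mean(v[v > tol])
}

#' Relative-value versus input-weight regression across a cohort
#'
#' For each trained network: the behaviorally inferred relative value
#' rho_C (from a logistic fit to its choices) is paired with the mean
#' non-zero excitatory q_C input weight; a linear regression across the
#' cohort quantifies whether learned values are physically encoded in
#' input synapses.
#'
#' @param fits List of \code{behavior_fit} objects (risky task).
#' @param nets List of matching \code{ei_network}s.
#' @return List: \code{data} (rho_hat, mean_w per network), \code{slope},
#'   \code{r2}, \code{p}.
#' @export
value_weight_regression <- function(fits, nets) {
  stopifnot(length(fits) == length(nets))
  d <- data.frame(
    rho_hat = vapply(fits, function(f) unname(f$rho["C"]), 0),
    mean_w = vapply(nets, mean_input_weight, 0))
  fit <- stats::lm(mean_w ~ rho_hat, data = d)
  sm <- summary(fit)
  list(data = d, slope = stats::coef(fit)[["rho_hat"]],
       r2 = sm$r.squared, p = sm$coefficients["rho_hat", 4])
}

#' Functional pool labels for every neuron
#'
#' Classifies each neuron by cell type (E/I) and primary selectivity on
#' the target task, using the selectivity labels at the time of peak
#' population selectivity within the offer period. The pool taxonomy is
#' offer values, chosen value, per-option choice, or none.
#'
#' @param net An \code{ei_network}.
#' @param profile \code{selectivity_profile} from the target task.
#' @param epochs Epoch boundaries of the profiled tensor.
#' @return data.frame: neuron, type, selectivity, pool label
#'   (e.g. "E:CHC").
#' @export
functional_pools <- function(net, profile, epochs) {
  offer_bins <- (epochs[["rule_end"]] + 1):epochs[["resp_start"]]
  lab <- profile$labels[offer_bins, , drop = FALSE]
  frac_sel <- rowMeans(!is.na(lab))
  t_star <- offer_bins[which.max(frac_sel)]
  sel <- profile$labels[t_star, ]
  sel[is.na(sel)] <- "none"
  types <- cell_types(net)
  data.frame(neuron = seq_along(sel), type = types, selectivity = sel,
             pool = paste(types, sel, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Reduced (pool-averaged) connectivity matrix
#'
#' Mean effective synaptic weight between each pair of functional pools
#' (rows = postsynaptic pool, columns = presynaptic pool).
#'
#' @param net An \code{ei_network}.
#' @param pools \code{data.frame} from \code{\link{functional_pools}} (or
#'   any per-neuron pool label vector).
#' @return List: \code{matrix} (pool x pool means, NA for empty pairs),
#'   \code{counts} per pool.
#' @export
reduced_connectivity <- function(net, pools) {
  labels <- if (is.data.frame(pools)) pools$pool else as.character(pools)
  W <- effective_weights(net)$W_rec
  lev <- sort(unique(labels))
  M <- matrix(NA_real_, length(lev), length(lev),
              dimnames = list(post = lev, pre = lev))
  for (a in lev) for (b in lev) {
    rows <- which(labels == a); cols <- which(labels == b)
    block <- W[rows, cols, drop = FALSE]
    if (a == b && length(rows) > 1)
      block <- block[row(block) != col(block)]  # exclude self-connections
    M[a, b] <- mean(block)
  }
  list(matrix = M, counts = table(labels))
}

#' Competitive-recurrent-inhibition score
#'
#' Mean magnitude of inhibitory-to-excitatory weights between pools
#' selective for *competing* choices minus the same-choice magnitude; a
#' positive score means inhibition preferentially targets the opposing
#' choice's excitatory neurons (the WTA motif).
#'
#' @param reduced Output of \code{\link{reduced_connectivity}}.
#' @param choice_labels Selectivity labels denoting the two choices
#'   (default \code{c("CHC", "CHE")}; bundles use CHBC/CHDE).
#' @return Scalar CRI score (NA if required pools are empty).
#' @export
cri_score <- function(reduced, choice_labels = c("CHC", "CHE")) {
  M <- reduced$matrix
  ch1 <- choice_labels[1]; ch2 <- choice_labels[2]
  need <- c(paste0("E:", c(ch1, ch2)), paste0("I:", c(ch1, ch2)))
  if (!all(need %in% rownames(M))) return(NA_real_)
  cross <- mean(abs(c(M[paste0("E:", ch1), paste0("I:", ch2)],
                      M[paste0("E:", ch2), paste0("I:", ch1)])))
  same <- mean(abs(c(M[paste0("E:", ch1), paste0("I:", ch1)],
                     M[paste0("E:", ch2), paste0("I:", ch2)])))
  cross - same
}

#' Singular-value spectrum of the recurrent weight matrix
#'
#' @param net An \code{ei_network} (or a matrix).
#' @return List: \code{d} singular values (decreasing),
#'   \code{effective_rank} (participation ratio of squared singular
#'   values).
#' @export
svd_spectrum <- function(net) {
  W <- if (inherits(net, "ei_network")) effective_weights(net)$W_rec
       else net
  d <- svd(W, nu = 0, nv = 0)$d
  list(d = d, effective_rank = sum(d^2)^2 / sum(d^4))
}

#' Battery of computational lesions with paired evaluation
#'
#' Evaluates the intact and each lesioned network on matched, seeded test
#' trials and reports the percentage change in completion and accuracy.
#'
#' @param net Trained \code{ei_network}.
#' @param tasks \code{choice_task} or list of them.
#' @param lesions Named list; each element is either
#'   \code{list(type = "recurrent_removal")} or
#'   \code{list(type = "clamp", neurons = <indices>)}.
#' @param n_trials Trials per evaluation.
#' @param seed Seed used for every evaluation (paired comparison).
#' @return data.frame: lesion, task, completion/accuracy for intact and
#'   lesioned, percentage changes.
#' @export
lesion_battery <- function(net, tasks, lesions, n_trials = 500,
                           seed = 1L) {
  if (inherits(tasks, "choice_task")) tasks <- list(tasks)
  eval_one <- function(nn) {
    do.call(rbind, lapply(tasks, function(sp) {
      set.seed(seed)
      ev <- evaluate_network(nn, sp, n_trials = n_trials)
      data.frame(task = sp$name, completion = ev$completion,
                 accuracy = ev$accuracy)
    }))
  }
  base <- eval_one(clear_lesion(net))
  out <- list()
  for (nm in names(lesions)) {
    les <- lesions[[nm]]
    lnet <- apply_lesion(net, les$type, les$neurons)
    ev <- eval_one(lnet)
    # accuracy is undefined (NaN) when no trial completes; identical
    # undefined performance counts as no change for the paired metric
    pct <- function(les, intact) {
      ifelse(is.na(les) & is.na(intact), 0,
             100 * (les - intact) / pmax(intact, 1e-12))
    }
    out[[nm]] <- data.frame(
      lesion = nm, task = base$task,
      completion_intact = base$completion, completion_lesion = ev$completion,
      accuracy_intact = base$accuracy, accuracy_lesion = ev$accuracy,
      completion_change_pct = pct(ev$completion, base$completion),
      accuracy_change_pct = pct(ev$accuracy, base$accuracy))
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Neurons with significant negative value tuning
#'
#' Identifies neurons whose regression slope for any offer-value or
#' chosen-value variable is significantly negative (p < 0.05) during the
#' offer period, by majority vote over the offer-period bins.
#'
#' @param profile \code{selectivity_profile}.
#' @param epochs Epoch boundaries of the profiled tensor.
#' @param value_vars Variables counted as value variables.
#' @return Integer vector of neuron indices.
#' @export
negative_tuned_neurons <- function(profile, epochs,
                                   value_vars = NULL) {
  if (is.null(value_vars))
    value_vars <- intersect(c("OVC", "OVE", "OVA", "OVBC", "OVDE", "CV"),
                            profile$variables)
  offer_bins <- (epochs[["rule_end"]] + 1):epochs[["resp_start"]]
  nn <- ncol(profile$labels)
  hit <- rep(FALSE, nn)
  for (v in value_vars) {
    neg <- profile$slope[offer_bins, , v] < 0 &
      profile$p[offer_bins, , v] < 0.05
    hit <- hit | (colMeans(neg) > 0.5)
  }
  which(hit)
}

#' Regression heatmap of output-node dynamics
#'
#' Simple linear regressions of each output node's trial activity
#' (actor logits and critic value, averaged over a window) on each
#' decision variable, including the conjunctive chosen-value variables;
#' the winner-take-all signature is a choice output strongly predicted by
#' its own conjunctive value but not the competitor's.
#'
#' @param outputs Trials x nodes matrix of output activity.
#' @param vars Trials x variables matrix.
#' @return R2 matrix (nodes x variables).
#' @export
output_dynamics_regression <- function(outputs, vars) {
  outputs <- as.matrix(outputs)
  r2 <- matrix(0, ncol(outputs), ncol(vars),
               dimnames = list(colnames(outputs), colnames(vars)))
  for (i in seq_len(ncol(outputs))) for (k in seq_len(ncol(vars))) {
    if (stats::var(outputs[, i]) == 0 || stats::var(vars[, k]) == 0) next
    r2[i, k] <- suppressWarnings(stats::cor(outputs[, i], vars[, k])^2)
  }
  r2[is.na(r2)] <- 0
  r2
}

#' Trial-resolved output-node activity
#'
#' Collects actor logits and critic value at the end of the offer period
#' for completed trials of one task.
#'
#' @param net Trained \code{ei_network}.
#' @param spec \code{choice_task}.
#' @param n_trials Completed trials wanted.
#' @param window_ms Averaging window before response onset.
#' @return List: \code{outputs} (trials x nodes), \code{trials} log.
#' @export
collect_outputs <- function(net, spec, n_trials = 300, window_ms = 200) {
  rec <- collect_rates(net, spec, n_trials = n_trials)
  X <- offer_window(rec, window_ms, average = TRUE)  # trials x neurons
  w <- effective_weights(net)
  logits <- X %*% t(w$W_a)
  colnames(logits) <- c("fix", paste0("choice", seq_len(ncol(logits) - 1)))
  value <- X %*% t(w$W_c) + net$b_c
  outputs <- cbind(logits, critic = as.numeric(value))
  list(outputs = outputs, trials = rec$trials, rec = rec)
}

# --- toy feedforward model --------------------------------------------------

#' Toy feedforward population for multiplicative value coding
#'
#' A population of ReLU units \code{r_i = [w_iq q + w_ip p + b_i]_+}
#' with \code{w_iq = w_ip = alpha_i} and \code{b_i = -beta_i E[qp]}
#' tiles the (q, p) plane with ramp basis functions; a linear readout of
#' such a population can approximate the multiplicative value surface
#' q*p even though no single unit is multiplicative.
#'
#' @param alpha,beta Per-unit gains and bias scales (recycled to
#'   \code{n}).
#' @param n Number of units.
#' @param q,p Input vectors (trials).
#' @param e_qp Mean of q*p over the offer distribution (computed from the
#'   inputs when NULL).
#' @return Trials x units activity matrix.
#' @export
toy_feedforward <- function(q, p, alpha, beta, n = length(alpha),
                            e_qp = NULL) {
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  if (is.null(e_qp)) e_qp <- mean(q * p)
  act <- outer(q + p, alpha) + matrix(-beta * e_qp, length(q), n,
                                      byrow = TRUE)
  pmax(act, 0)
}

#' Multiplicative versus additive account of population activity
#'
#' Projects the activity onto its leading principal component (the
#' activity itself for a single unit) and compares how much of its
#' variance is explained by the multiplicative model \code{q*p} versus
#' the additive model \code{q+p}. A positive gap means the population
#' activity looks multiplicative rather than additive.
#'
#' @param activity Trials x units matrix.
#' @param q,p Input vectors.
#' @return List: \code{r2_product}, \code{r2_additive}, \code{gap}.
#' @export
mult_vs_add_readout <- function(activity, q, p) {
  activity <- as.matrix(activity)
  score <- if (ncol(activity) == 1) activity[, 1]
           else stats::prcomp(activity, center = TRUE)$x[, 1]
  r2_of <- function(pred) {
    if (stats::var(score) == 0 || stats::var(pred) == 0) return(0)
    suppressWarnings(stats::cor(score, pred)^2)
  }
  r2p <- r2_of(q * p)
  r2a <- r2_of(q + p)
  list(r2_product = r2p, r2_additive = r2a, gap = r2p - r2a)
}

#' Parameter sweep of the toy model
#'
#' Sweeps shared (alpha, beta) over a log grid and records how well a
#' linear readout of the population reconstructs the product q*p versus
#' the sum q+p, mapping the regime where the architecture computes
#' multiplicatively.
#'
#' @param n_units Units in the population.
#' @param n_trials Random (q, p) samples.
#' @param alpha_grid,beta_grid Parameter grids.
#' @param q_max Quantity range upper bound (1 = normalized channel units,
#'   matching what the network's input layer sees).
#' @return data.frame: alpha, beta, r2_product, r2_additive, gap.
#' @export
toy_parameter_sweep <- function(n_units = 200, n_trials = 400,
                                alpha_grid = 10^seq(-2, 1, length.out = 25),
                                beta_grid = 10^seq(-2, 1, length.out = 25),
                                q_max = 1) {
  q <- stats::runif(n_trials, 0, q_max)
  p <- stats::runif(n_trials)
  e_qp <- mean(q * p)
  out <- vector("list", length(alpha_grid) * length(beta_grid))
  i <- 0
  # all units share (alpha, beta) at each sweep point (simplified search)
  for (a in alpha_grid) for (b in beta_grid) {
    act <- toy_feedforward(q, p, alpha = a, beta = b,
                           n = n_units, e_qp = e_qp)
    r <- mult_vs_add_readout(act, q, p)
    i <- i + 1
    out[[i]] <- data.frame(alpha = a, beta = b,
                           r2_product = r$r2_product,
                           r2_additive = r$r2_additive, gap = r$gap)
  }
  do.call(rbind, out)
}

#' Segregated versus mixed-selectivity toy populations
#'
#' Builds two-offer toy populations: the segregated variant has two
#' pools, each seeing only one offer's (q, p); the mixed variant adds a
#' pool receiving the summed inputs of both offers. PCA of the activity
#' shows whether the leading axes align with the individual offer values
#' (segregated) or rotate toward value sum/difference (mixed).
#'
#' @param q1,p1,q2,p2 Offer features (vectors over trials).
#' @param n_per_pool Units per pool.
#' @param alpha,beta Shared gains.
#' @param variant \code{"segregated"} or \code{"mixed"}.
#' @return List: \code{activity}, \code{pca}, and \code{axis_r2}
#'   (R2 of PC1/PC2 scores against OV1, OV2, sum, difference).
#' @export
toy_two_offer_model <- function(q1, p1, q2, p2, n_per_pool = 100,
                                alpha = 1, beta = 1,
                                variant = c("segregated", "mixed")) {
  variant <- match.arg(variant)
  e1 <- mean(q1 * p1); e2 <- mean(q2 * p2)
  ja <- function() stats::runif(n_per_pool, 0.5, 1.5)
  jb <- function() stats::runif(n_per_pool, 0, 2)
  pools <- list(
    toy_feedforward(q1, p1, alpha * ja(), beta * jb(), n_per_pool, e1),
    toy_feedforward(q2, p2, alpha * ja(), beta * jb(), n_per_pool, e2))
  if (variant == "mixed")
    pools[[3]] <- toy_feedforward(q1 + q2, p1 + p2, alpha * ja(),
                                  beta * jb(), n_per_pool,
                                  mean((q1 + q2) * (p1 + p2)))
  act <- do.call(cbind, pools)
  pca <- stats::prcomp(act, center = TRUE)
  ov1 <- q1 * p1; ov2 <- q2 * p2
  targets <- cbind(OV1 = ov1, OV2 = ov2, sum = ov1 + ov2,
                   diff = ov1 - ov2)
  axis_r2 <- matrix(0, 2, ncol(targets),
                    dimnames = list(c("PC1", "PC2"), colnames(targets)))
  for (i in 1:2) for (k in seq_len(ncol(targets)))
    axis_r2[i, k] <- stats::cor(pca$x[, i], targets[, k])^2
  list(activity = act, pca = pca, axis_r2 = axis_r2)
}

#' Multiplicative computation test on the lesioned feedforward pathway
#'
#' With recurrent connections removed, stimulus-window activity is
#' collected (passive viewing), PCA is run, and the top two PCs are each
#' regressed on (a) the two offer values (products rho q p) and (b) the
#' additive feature sums (q + p per offer). Higher product-model R2
#' indicates the feedforward pathway learned a multiplicative rule.
#'
#' @param net Trained \code{ei_network} (lesion applied internally).
#' @param spec Risky \code{choice_task}.
#' @param n_trials Trials to simulate.
#' @param window_ms Stimulus window.
#' @return List: \code{r2} (2 x 2 matrix PCs x {product, additive}),
#'   \code{pca}.
#' @export
feedforward_mult_test <- function(net, spec = task_spec("risky"),
                                  n_trials = 400, window_ms = 200) {
  lnet <- apply_lesion(net, "recurrent_removal")
  rec <- collect_rates(lnet, spec, n_trials = n_trials,
                       force_hold = TRUE, keep_incomplete = TRUE)
  X <- offer_window(rec, window_ms, average = TRUE)
  pca <- stats::prcomp(X, center = TRUE)
  d <- rec$trials
  prod1 <- spec$rho[["C"]] * d$q_C * d$p_C
  prod2 <- spec$rho[["E"]] * d$q_E * d$p_E
  add1 <- d$q_C + d$p_C
  add2 <- d$q_E + d$p_E
  r2 <- matrix(0, 2, 2, dimnames = list(c("PC1", "PC2"),
                                        c("product", "additive")))
  for (i in 1:2) {
    y <- pca$x[, i]
    fp <- stats::lm(y ~ prod1 + prod2)
    fa <- stats::lm(y ~ add1 + add2)
    r2[i, "product"] <- summary(fp)$r.squared
    r2[i, "additive"] <- summary(fa)$r.squared
  }
  list(r2 = r2, pca = pca)
}
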