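# ---------------------------------------------------------------------------
# Logistic / multinomial choice models and maximum-likelihood fitting.
#
# Binary tasks model the probability of choosing the first option as a
# logistic function of the log value ratio; the fitted parameters are the
# relative value rho (per non-reference good; good E is the reference with
# rho_E = 1), the risk attitude gamma (exponent on probability), the
# choice consistency eta (inverse temperature) and, for the sequential
# task, an order bias eps. The ternary task uses a softmax over powered
# values.
# ---------------------------------------------------------------------------

# Parameter layout per task: which rho parameters are free and whether
# gamma / eps are fitted.
behavior_layout <- function(task) {
  switch(task,
    standard   = list(rho = "C", gamma = FALSE, eps = FALSE),
    risky      = list(rho = "C", gamma = TRUE, eps = FALSE),
    bundles    = list(rho = c("B", "C", "D"), gamma = TRUE, eps = FALSE),
    ternary    = list(rho = c("A", "C"), gamma = TRUE, eps = FALSE),
    sequential = list(rho = "C", gamma = TRUE, eps = TRUE),
    stop("unknown task: ", task))
}

# Powered slot value rho_hat * q * p^gamma summed over the slot's goods.
powered_value <- function(q, p, rho_hat, gamma, goods) {
  v <- 0
  for (g in goods) {
    rg <- if (g == "E") 1 else rho_hat[[g]]
    v <- v + rg * q[[paste0("q_", g)]] * p[[paste0("p_", g)]]^gamma
  }
  v
}

#' Choice probabilities under the logistic behavioral model
#'
#' Computes, for each trial, the model probability of choosing slot 1 (or
#' the probability simplex over slots for the ternary task). The powered
#' value of a slot is \code{sum_g rho_g * q_g * p_g^gamma} over its goods
#' with \code{rho_E = 1} fixed; binary tasks pass the log value ratio
#' through a logistic with slope \code{eta} (the sequential task adds
#' \code{eps * order} to the log ratio, order = +1 when good C came
#' second); the ternary model is a softmax of the values raised to
#' \code{eta}.
#'
#' @param trials data.frame of trials (columns \code{q_A..q_E},
#'   \code{p_A..p_E}, \code{order} for sequential).
#' @param task Task name.
#' @param rho_hat Named list/vector of relative values for the task's
#'   non-reference goods.
#' @param gamma Risk attitude (1 for deterministic tasks).
#' @param eta Choice consistency (> 0).
#' @param eps Order bias (sequential only).
#' @return Vector of P(choose slot 1), or an n x 3 matrix for ternary.
#' @export
choice_probability <- function(trials, task, rho_hat, gamma = 1, eta = 1,
                               eps = 0) {
  lay <- behavior_layout(task)
  slots <- task_spec(task)$slots
  vals <- sapply(slots, function(sl)
    powered_value(trials, trials, rho_hat, gamma, sl$goods))
  vals <- matrix(vals, nrow = nrow(trials))
  if (task == "ternary") {
    lv <- eta * log(vals)
    m <- apply(lv, 1, max)
    e <- exp(lv - m)
    return(e / rowSums(e))
  }
  z <- eta * (log(vals[, 1] / vals[, 2]) +
                if (lay$eps) eps * trials$order else 0)
  1 / (1 + exp(-z))
}

#' Fit the behavioral choice model by maximum likelihood
#'
#' Maximizes the model log-likelihood over the task's free parameters
#' (relative values, risk attitude for probabilistic tasks, consistency,
#' order bias for the sequential task) with \code{rho_E = 1} fixed and a
#' log parametrization of the positive parameters. Uses Nelder-Mead with
#' multiple starting points; standard errors come from the numerically
#' differentiated observed information matrix.
#'
#' @param trials Trial-log data.frame (completed trials with a recorded
#'   choice are used).
#' @param task Task name; defaults to the task of the first trial.
#' @param n_starts Number of optimizer restarts.
#' @param eta_cap Upper bound on eta; fits at the cap are flagged as
#'   (quasi-)separable.
#' @return Object of class \code{behavior_fit}: \code{rho}, \code{gamma},
#'   \code{eta}, \code{eps}, \code{log_lik}, \code{n_trials}, \code{se},
#'   \code{separable} flag.
#' @export
fit_behavior <- function(trials, task = NULL, n_starts = 5,
                         eta_cap = 1000) {
  if (is.null(task)) task <- trials$task[1]
  lay <- behavior_layout(task)
  d <- trials[trials$completed & !is.na(trials$chosen), , drop = FALSE]
  if (nrow(d) < 10) stop("too few completed trials to fit (", nrow(d), ")")
  chose1 <- d$chosen == 1
  # theta = (log rho..., [log gamma], log eta, [eps])
  nr <- length(lay$rho)
  unpack <- function(theta) {
    i <- 0
    rho <- stats::setNames(exp(theta[seq_len(nr)]), lay$rho); i <- nr
    gamma <- if (lay$gamma) exp(theta[i <- i + 1]) else 1
    eta <- exp(theta[i <- i + 1])
    eps <- if (lay$eps) theta[i + 1] else 0
    list(rho = rho, gamma = gamma, eta = eta, eps = eps)
  }
  nll <- function(theta) {
    pp <- unpack(theta)
    if (pp$eta > eta_cap) return(1e10)
    pr <- choice_probability(d, task, pp$rho, pp$gamma, pp$eta, pp$eps)
    ll <- if (task == "ternary") {
      log(pmax(pr[cbind(seq_len(nrow(d)), d$chosen)], 1e-12))
    } else {
      log(pmax(ifelse(chose1, pr, 1 - pr), 1e-12))
    }
    -sum(ll)
  }
  npar <- nr + lay$gamma + 1 + lay$eps
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1) rep(0, npar) else stats::rnorm(npar, 0, 0.7)
    fit <- try(stats::optim(th0, nll, method = "Nelder-Mead",
                            control = list(maxit = 4000, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("behavioral fit did not converge")
  pp <- unpack(best$par)
  separable <- pp$eta >= 0.99 * eta_cap
  # observed information (numerical Hessian on the internal scale)
  se <- rep(NA_real_, npar)
  H <- try(stats::optimHess(best$par, nll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    ih <- try(solve(H), silent = TRUE)
    if (!inherits(ih, "try-error")) {
      dg <- diag(ih)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  # delta method back to the natural scale for the log-parametrized terms
  natural <- c(pp$rho, if (lay$gamma) pp$gamma, pp$eta, if (lay$eps) 1)
  se_nat <- se * natural
  names(se_nat) <- c(paste0("rho_", lay$rho), if (lay$gamma) "gamma",
                     "eta", if (lay$eps) "eps")
  structure(list(task = task, rho = pp$rho, gamma = pp$gamma,
                 eta = pp$eta, eps = pp$eps,
                 log_lik = -best$value, n_trials = nrow(d),
                 se = se_nat, separable = separable),
            class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat("Behavioral fit (", x$task, ", n = ", x$n_trials, ")\n", sep = "")
  cat("  rho:", paste(sprintf("%s=%.3f", names(x$rho), x$rho),
                      collapse = " "), "\n")
  cat(sprintf("  gamma = %.3f  eta = %.3f  eps = %.3f  logLik = %.1f\n",
              x$gamma, x$eta, x$eps, x$log_lik))
  if (x$separable) cat("  [flag] eta at cap: (quasi-)separable choices\n")
  invisible(x)
}

#' Simulate choices from the behavioral model
#'
#' Generates offers with the task's offer sampler and draws choices from
#' the model probabilities; used for parameter-recovery checks.
#'
#' @param task Task name.
#' @param n Number of trials.
#' @param rho_hat,gamma,eta,eps Generating parameters.
#' @return Trial data.frame compatible with \code{fit_behavior}.
#' @export
simulate_choices <- function(task, n, rho_hat, gamma = 1, eta = 4,
                             eps = 0) {
  spec <- task_spec(task)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- build_trial(spec)
    q <- tr$offers$q; p <- tr$offers$p
    row <- data.frame(task = task, completed = TRUE, order = tr$order)
    for (g in GOOD_IDS) {
      row[[paste0("q_", g)]] <- q[[g]]
      row[[paste0("p_", g)]] <- p[[g]]
    }
    rows[[i]] <- row
  }
  d <- do.call(rbind, rows)
  pr <- choice_probability(d, task, rho_hat, gamma, eta, eps)
  if (task == "ternary") {
    d$chosen <- apply(pr, 1, function(p) sample.int(3, 1, prob = p))
  } else {
    d$chosen <- ifelse(stats::runif(n) < pr, 1L, 2L)
  }
  d
}

#' Compare behavioral fits between two datasets
#'
#' Paired table of the key parameters (and accuracy where available) for
#' e.g. the constrained training set versus the unconstrained test set of
#' the generalization experiment.
#'
#' @param fit_train,fit_test \code{behavior_fit} objects for the same task.
#' @param acc_train,acc_test Optional choice accuracies to include.
#' @return data.frame with one row per parameter: train, test, difference
#'   and relative difference.
#' @export
compare_fits <- function(fit_train, fit_test, acc_train = NA,
                         acc_test = NA) {
  stopifnot(fit_train$task == fit_test$task)
  pars <- c(stats::setNames(as.list(fit_train$rho),
                            paste0("rho_", names(fit_train$rho))),
            gamma = fit_train$gamma, eta = fit_train$eta)
  pars_t <- c(stats::setNames(as.list(fit_test$rho),
                              paste0("rho_", names(fit_test$rho))),
              gamma = fit_test$gamma, eta = fit_test$eta)
  d <- data.frame(parameter = c(names(pars), "accuracy"),
                  train = c(unlist(pars), acc_train),
                  test = c(unlist(pars_t), acc_test))
  d$difference <- d$test - d$train
  d$rel_difference <- d$difference / abs(d$train)
  d
}
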