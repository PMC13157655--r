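# ---------------------------------------------------------------------------
# Vectorized batch of task environments.
#
# Runs n parallel trial environments with state held in vectors/matrices so
# that one observation/step call serves the whole batch. Semantics are
# identical to the single-trial env_reset()/env_step() API; this engine
# exists because rollout collection steps thousands of environments per
# second during training.
# ---------------------------------------------------------------------------

# Log-matrix columns for finished trials.
log_cols <- function() {
  c("env", "task", "chosen", "reward", "completed", "aborted", "rt_ms",
    "correct", "order", "arm", "v1", "v2", "v3",
    paste0("q_", GOOD_IDS), paste0("p_", GOOD_IDS))
}

#' Create a batch of parallel task environments
#'
#' @param specs List of \code{choice_task} specs; each environment draws
#'   its next trial's task uniformly at random from this list (multitask
#'   interleaving) unless \code{length(specs) == 1}.
#' @param n Number of parallel environments.
#' @param fixed_epochs Use midpoint epoch durations (analysis trials).
#' @param log_trials Accumulate a per-trial log matrix.
#' @param auto_reset If \code{FALSE}, finished environments stay terminal
#'   (episode mode: one trial per environment, kept time-synchronized).
#' @return A mutable batch-environment object (an R environment).
#' @export
batch_env <- function(specs, n = 20, fixed_epochs = FALSE,
                      log_trials = FALSE, auto_reset = TRUE) {
  if (inherits(specs, "choice_task")) specs <- list(specs)
  be <- new.env(parent = emptyenv())
  be$specs <- specs
  be$n <- as.integer(n)
  be$fixed_epochs <- fixed_epochs
  be$log_trials <- log_trials
  be$auto_reset <- auto_reset
  be$terminal <- logical(n)
  be$dt <- specs[[1]]$dt_ms
  # per-env state
  be$task <- integer(n)
  be$t <- integer(n)
  be$seqf <- logical(n)
  be$n_choices <- integer(n)
  for (nm in c("fix_end", "rule_end", "o1_end", "d_end",
               "resp_start", "resp_end"))
    be[[nm]] <- integer(n)
  be$q <- matrix(NA_real_, 5, n)       # raw quantity per good
  be$p <- matrix(NA_real_, 5, n)
  be$qn0 <- matrix(0, 5, n)            # normalized quantity, 0 if unoffered
  be$p0 <- matrix(0, 5, n)
  be$vals <- matrix(NA_real_, 3, n)    # slot expected values
  be$first <- integer(n)               # good index presented first (seq)
  be$second <- integer(n)
  be$order <- rep(NA_integer_, n)
  be$arm <- rep(NA_integer_, n)        # 1 = fix_p arm, 0 = fix_q arm
  # counters
  be$n_trials <- 0L; be$n_completed <- 0L; be$n_correct <- 0L
  be$n_aborted <- 0L; be$n_timeout <- 0L
  # trial log buffer
  be$log <- matrix(NA_real_, 0, length(log_cols()))
  be$log_n <- 0L
  if (log_trials) be$log <- matrix(NA_real_, 4096, length(log_cols()))
  be_reset(be, seq_len(n))
  be
}

# (Re)sample trials for the environments in idx.
be_reset <- function(be, idx) {
  for (j in idx) {
    k <- if (length(be$specs) == 1) 1L else sample.int(length(be$specs), 1L)
    spec <- be$specs[[k]]
    trial <- build_trial(spec, be$fixed_epochs)
    tl <- trial$timeline
    be$task[j] <- k
    be$t[j] <- 0L
    be$seqf[j] <- spec$sequential
    be$n_choices[j] <- spec$n_choices
    be$fix_end[j] <- tl[["fix_end"]]
    be$rule_end[j] <- tl[["rule_end"]]
    be$o1_end[j] <- if (spec$sequential) tl[["o1_end"]] else tl[["rule_end"]]
    be$d_end[j] <- if (spec$sequential) tl[["d_end"]] else tl[["rule_end"]]
    be$resp_start[j] <- tl[["resp_start"]]
    be$resp_end[j] <- tl[["resp_end"]]
    off <- trial$offers
    be$q[, j] <- off$q
    be$p[, j] <- off$p
    qn <- off$q / (10 / spec$rho)
    be$qn0[, j] <- ifelse(is.na(qn), 0, qn)
    be$p0[, j] <- ifelse(is.na(off$p), 0, off$p)
    be$vals[, j] <- c(off$values, rep(NA_real_, 3 - length(off$values)))
    be$first[j] <- if (spec$sequential) match(trial$first_good, GOOD_IDS) else 0L
    be$second[j] <- if (spec$sequential) match(trial$second_good, GOOD_IDS) else 0L
    be$order[j] <- trial$order
    be$arm[j] <- if (is.na(off$arm)) NA_integer_ else as.integer(off$arm == "fix_p")
  }
  invisible(be)
}

#' Observation matrix for a batch environment
#'
#' @param be Batch environment.
#' @param noise Add per-channel Gaussian input noise.
#' @param sigma_in,alpha,u0 Input noise amplitude, discretization ratio
#'   and baseline (see \code{\link{encode_observation}}).
#' @return 16 x n matrix (rows named by \code{obs_channels()}).
#' @export
be_obs <- function(be, noise = TRUE, sigma_in = 0.01, alpha = 0.2,
                   u0 = 0.2) {
  n <- be$n
  sig <- matrix(0, 16, n, dimnames = list(obs_channels(), NULL))
  sig[1, ] <- as.numeric(be$t < be$resp_start)
  on_rule <- which(be$t >= be$fix_end)
  if (length(on_rule))
    sig[cbind(1L + be$task[on_rule], on_rule)] <- 1
  # offer visibility per good (5 x n)
  vis <- matrix(FALSE, 5, n)
  sim <- !be$seqf
  tvis <- be$t >= be$rule_end & be$t < be$resp_end
  if (any(sim)) {
    cols <- which(sim & tvis)
    vis[, cols] <- !is.na(be$q[, cols, drop = FALSE])
  }
  sq <- which(be$seqf)
  if (length(sq)) {
    v1 <- sq[be$t[sq] >= be$rule_end[sq] & be$t[sq] < be$o1_end[sq]]
    if (length(v1)) vis[cbind(be$first[v1], v1)] <- TRUE
    v2 <- sq[be$t[sq] >= be$d_end[sq] & be$t[sq] < be$resp_end[sq]]
    if (length(v2)) vis[cbind(be$second[v2], v2)] <- TRUE
  }
  sig[2 + (1:5), ] <- be$qn0 * vis
  sig[7 + (1:5), ] <- be$p0 * vis
  out <- sig + u0
  if (noise)
    out <- out + matrix(stats::rnorm(16 * n, 0, sigma_in * sqrt(2 / alpha)),
                        16, n)
  out
}

be_log_row <- function(be, j, chosen, reward, completed, aborted, rt,
                       correct) {
  if (!be$log_trials) return(invisible(NULL))
  if (be$log_n >= nrow(be$log))
    be$log <- rbind(be$log, matrix(NA_real_, nrow(be$log), ncol(be$log)))
  be$log_n <- be$log_n + 1L
  be$log[be$log_n, ] <- c(j, be$task[j], chosen, reward, completed, aborted,
                          rt, correct, be$order[j], be$arm[j],
                          be$vals[1, j], be$vals[2, j], be$vals[3, j],
                          be$q[, j], be$p[, j])
  invisible(NULL)
}

#' Step all environments in a batch
#'
#' Terminal environments are reset to fresh trials after their outcome is
#' recorded, so the batch streams trials continuously.
#'
#' @param be Batch environment.
#' @param actions Integer vector (length n) in 0..3; 0 holds fixation.
#' @return List with \code{reward} and \code{done} vectors (done refers to
#'   the trial that just ended; the env already holds a new trial).
#' @export
be_step <- function(be, actions) {
  n <- be$n
  stopifnot(length(actions) == n)
  actions <- as.integer(actions)
  live <- !be$terminal
  in_resp <- be$t >= be$resp_start & be$t < be$resp_end
  abort <- live & actions != 0L & !in_resp
  # an offered slot pays out; an unoffered slot is an unrewarded error
  choose <- live & actions != 0L & actions <= be$n_choices & in_resp
  invalid <- live & actions > be$n_choices & in_resp
  reward <- numeric(n)
  reward[abort] <- -1
  done <- abort | invalid
  for (j in which(choose)) {
    spec <- be$specs[[be$task[j]]]
    slot <- spec$slots[[actions[j]]]
    rew <- 0
    for (g in slot$goods) {
      gi <- match(g, GOOD_IDS)
      if (stats::runif(1) < be$p[gi, j])
        rew <- rew + spec$rho[[g]] * be$q[gi, j]
    }
    reward[j] <- rew
    done[j] <- TRUE
    vmax <- max(be$vals[, j], na.rm = TRUE)
    corr <- be$vals[actions[j], j] >= vmax - 1e-12
    be$n_correct <- be$n_correct + corr
    be$n_completed <- be$n_completed + 1L
    be_log_row(be, j, actions[j], reward[j], 1, 0,
               (be$t[j] - be$resp_start[j] + 1) * be$dt, as.numeric(corr))
  }
  hold <- live & !done
  be$t[hold] <- be$t[hold] + 1L
  timeout <- hold & be$t >= be$resp_end
  done <- done | timeout
  be$n_timeout <- be$n_timeout + sum(timeout)
  be$n_aborted <- be$n_aborted + sum(abort)
  be$n_trials <- be$n_trials + sum(done)
  for (j in which(abort)) be_log_row(be, j, NA, -1, 0, 1, NA, NA)
  for (j in which(invalid | timeout)) be_log_row(be, j, NA, 0, 0, 0, NA, NA)
  if (any(done)) {
    if (be$auto_reset) be_reset(be, which(done))
    else be$terminal[done] <- TRUE
  }
  list(reward = reward, done = done, terminal = be$terminal)
}

#' Extract the accumulated trial log as a data frame
#'
#' @param be Batch environment created with \code{log_trials = TRUE}.
#' @return data.frame with one row per finished trial; \code{task} is the
#'   task name, \code{arm} the constrained-sampler condition
#'   (\code{"fix_p"}/\code{"fix_q"}) where applicable.
#' @export
be_trial_log <- function(be) {
  m <- be$log[seq_len(be$log_n), , drop = FALSE]
  colnames(m) <- log_cols()
  d <- as.data.frame(m)
  d$task <- vapply(d$task, function(k) be$specs[[k]]$name, character(1))
  d$completed <- d$completed == 1
  d$aborted <- d$aborted == 1
  d$correct <- ifelse(is.na(d$correct), NA, d$correct == 1)
  d$arm <- ifelse(is.na(d$arm), NA_character_,
                  ifelse(d$arm == 1, "fix_p", "fix_q"))
  d
}

#' Completion and accuracy summary of a batch environment
#' @param be Batch environment.
#' @return List with \code{n_trials}, \code{completion}, \code{accuracy}.
#' @export
be_summary <- function(be) {
  list(n_trials = be$n_trials,
       completion = if (be$n_trials > 0) be$n_completed / be$n_trials else NA,
       accuracy = if (be$n_completed > 0) be$n_correct / be$n_completed else NA)
}
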