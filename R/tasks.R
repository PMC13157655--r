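# ---------------------------------------------------------------------------
# Economic choice task environments
#
# Five trial-based tasks (standard, risky, bundles, ternary, sequential)
# over goods A-E with intrinsic values rho_A > ... > rho_E = 1. Each trial
# runs in 20-ms steps through fixation, rule-cue, offer and response epochs;
# the agent must hold fixation until the go signal and then select an offer.
# ---------------------------------------------------------------------------

#' Default intrinsic values of the five goods
#'
#' Goods A-E carry fixed intrinsic values (dimensionless reward units) with
#' the strict ordering rho_A > rho_B > rho_C > rho_D > rho_E and rho_E = 1
#' as the reference good. Quantities are sampled from \code{[0, 10/rho_X]}
#' so every good spans the same offer-value range \code{[1, 10]}.
#'
#' @return Named numeric vector of length 5.
#' @export
goods_default <- function() {
  c(A = 3, B = 2.5, C = 2, D = 1.5, E = 1)
}

TASK_NAMES <- c("standard", "risky", "bundles", "ternary", "sequential")
GOOD_IDS <- c("A", "B", "C", "D", "E")

#' Observation channel layout
#'
#' The 16 input channels: one fixation cue, five one-hot rule cues (one per
#' task), five quantity channels and five probability channels (one per
#' good A-E). Channels of goods not offered on a trial stay at baseline.
#'
#' @return Character vector of 16 channel names.
#' @export
obs_channels <- function() {
  c("fix",
    paste0("rule_", TASK_NAMES),
    paste0("q_", GOOD_IDS),
    paste0("p_", GOOD_IDS))
}

#' Construct a task specification
#'
#' @param name One of \code{"standard"}, \code{"risky"}, \code{"bundles"},
#'   \code{"ternary"}, \code{"sequential"}.
#' @param rho Named vector of intrinsic values for goods A-E.
#' @param offer_ms Range (ms) of the offer-presentation epoch.
#' @param delay_ms Range (ms) of the inter-offer delay (sequential only).
#' @param fix_ms,rule_ms Ranges (ms) of the fixation and rule epochs.
#' @param response_ms Maximum response window (ms).
#' @param constrained Logical; for the risky task only, restrict offers to
#'   the orthogonal "cross" design used in the generalization experiment:
#'   on each trial either both probabilities are fixed at 0.5 and
#'   quantities vary, or quantities are fixed at half their maxima and
#'   probabilities vary (each arm with probability 0.5).
#' @param dt_ms Simulation time step (ms).
#' @return An object of class \code{choice_task}.
#' @export
task_spec <- function(name = TASK_NAMES,
                      rho = goods_default(),
                      offer_ms = c(500, 1500),
                      delay_ms = c(500, 1500),
                      fix_ms = c(500, 1500),
                      rule_ms = c(500, 1500),
                      response_ms = 1000,
                      constrained = FALSE,
                      dt_ms = 20) {
  name <- match.arg(name)
  # rho_E = 1 is the reference convention; the default set is strictly
  # descending A > B > C > D > E, but experiments that manipulate a
  # single good's intrinsic value (e.g. the value-weight cohort, with
  # rho_C from 1 to 5) may break the ordering deliberately.
  stopifnot(all(GOOD_IDS %in% names(rho)), all(rho > 0),
            rho[["E"]] == 1)
  if (constrained && name != "risky")
    stop("constrained offer sampling is defined for the risky task only")
  slots <- switch(name,
    standard   = list(list(goods = "C"), list(goods = "E")),
    risky      = list(list(goods = "C"), list(goods = "E")),
    bundles    = list(list(goods = c("B", "C")), list(goods = c("D", "E"))),
    ternary    = list(list(goods = "A"), list(goods = "C"), list(goods = "E")),
    sequential = list(list(goods = "C"), list(goods = "E")))
  structure(list(
    name = name,
    rho = rho[GOOD_IDS],
    slots = slots,
    n_choices = length(slots),
    deterministic = (name == "standard"),
    sequential = (name == "sequential"),
    constrained = constrained,
    fix_ms = fix_ms, rule_ms = rule_ms, offer_ms = offer_ms,
    delay_ms = delay_ms, response_ms = response_ms, dt_ms = dt_ms
  ), class = "choice_task")
}

#' Sample a single offer for one good
#'
#' Quantity is drawn uniformly from \code{[0, 10/rho]} and probability
#' uniformly from \code{[0, 1]} (or set to 1 when deterministic); the pair
#' is redrawn until the offer value \code{rho * q * p} is at least 1, so
#' every presented offer is non-trivial.
#'
#' @param good Good label in A-E.
#' @param rho Intrinsic value of the good (positive).
#' @param deterministic If \code{TRUE}, probability is exactly 1.
#' @param max_attempts Resampling cap before an error is raised.
#' @return List with \code{good}, \code{quantity}, \code{probability},
#'   \code{value}.
#' @export
sample_offer <- function(good, rho, deterministic = FALSE,
                         max_attempts = 1000) {
  stopifnot(rho > 0)
  qmax <- 10 / rho
  for (i in seq_len(max_attempts)) {
    q <- stats::runif(1, 0, qmax)
    p <- if (deterministic) 1 else stats::runif(1)
    v <- rho * q * p
    if (v >= 1)
      return(list(good = good, quantity = q, probability = p, value = v))
  }
  stop("offer resampling failed after ", max_attempts,
       " attempts (degenerate rho = ", rho, ")")
}

# Sample the offers of one trial. Returns a list with per-good quantity and
# probability vectors (NA for goods not offered) and per-slot values.
sample_trial_offers <- function(spec) {
  q <- stats::setNames(rep(NA_real_, 5), GOOD_IDS)
  p <- stats::setNames(rep(NA_real_, 5), GOOD_IDS)
  if (spec$constrained) {
    # Orthogonal cross design: one arm fixes probabilities at 0.5, the
    # other fixes quantities at half their maxima.
    arm <- if (stats::runif(1) < 0.5) "fix_p" else "fix_q"
    for (slot in spec$slots) {
      g <- slot$goods
      rho <- spec$rho[[g]]
      if (arm == "fix_p") {
        p[g] <- 0.5
        repeat {
          q[g] <- stats::runif(1, 0, 10 / rho)
          if (rho * q[g] * p[g] >= 1) break
        }
      } else {
        q[g] <- 5 / rho
        repeat {
          p[g] <- stats::runif(1)
          if (rho * q[g] * p[g] >= 1) break
        }
      }
    }
    arm_label <- arm
  } else {
    for (slot in spec$slots) {
      for (g in slot$goods) {
        off <- sample_offer(g, spec$rho[[g]], spec$deterministic)
        q[g] <- off$quantity
        p[g] <- off$probability
      }
    }
    arm_label <- NA_character_
  }
  values <- vapply(spec$slots, function(slot) {
    sum(spec$rho[slot$goods] * q[slot$goods] * p[slot$goods])
  }, numeric(1))
  list(q = q, p = p, values = values, arm = arm_label)
}

# Draw an epoch duration in steps, uniform over multiples of dt within the
# ms range; the midpoint when fixed.
draw_steps <- function(range_ms, dt_ms, fixed) {
  lo <- as.integer(range_ms[1] / dt_ms)
  hi <- as.integer(range_ms[2] / dt_ms)
  if (fixed) return(as.integer(round((lo + hi) / 2)))
  if (lo >= hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Build the timeline and offers of one trial
#'
#' Epoch durations are drawn uniformly from their configured ranges in
#' multiples of the 20-ms step (or set to the range midpoints when
#' \code{fixed_epochs}, as used for neural-analysis trials). For the
#' sequential task the presentation order of the two goods is randomized.
#'
#' @param spec A \code{choice_task}.
#' @param fixed_epochs Use deterministic midpoint durations.
#' @return List with \code{timeline} (named integer step boundaries),
#'   \code{offers} (per-good q/p and per-slot values) and \code{order}
#'   (+1 if good C is presented second, sequential only).
#' @export
build_trial <- function(spec, fixed_epochs = FALSE) {
  dt <- spec$dt_ms
  fix_n <- draw_steps(spec$fix_ms, dt, fixed_epochs)
  rule_n <- draw_steps(spec$rule_ms, dt, fixed_epochs)
  resp_n <- as.integer(spec$response_ms / dt)
  offers <- sample_trial_offers(spec)
  if (spec$sequential) {
    o1 <- draw_steps(spec$offer_ms, dt, fixed_epochs)
    dl <- draw_steps(spec$delay_ms, dt, fixed_epochs)
    o2 <- draw_steps(spec$offer_ms, dt, fixed_epochs)
    c_second <- stats::runif(1) < 0.5
    order <- if (c_second) 1L else -1L
    first <- if (c_second) "E" else "C"
    second <- if (c_second) "C" else "E"
    tl <- c(fix_end = fix_n,
            rule_end = fix_n + rule_n,
            o1_end = fix_n + rule_n + o1,
            d_end = fix_n + rule_n + o1 + dl,
            resp_start = fix_n + rule_n + o1 + dl + o2,
            resp_end = fix_n + rule_n + o1 + dl + o2 + resp_n)
    list(timeline = tl, offers = offers, order = order,
         first_good = first, second_good = second)
  } else {
    off_n <- draw_steps(spec$offer_ms, dt, fixed_epochs)
    tl <- c(fix_end = fix_n,
            rule_end = fix_n + rule_n,
            resp_start = fix_n + rule_n + off_n,
            resp_end = fix_n + rule_n + off_n + resp_n)
    list(timeline = tl, offers = offers, order = NA_integer_,
         first_good = NA_character_, second_good = NA_character_)
  }
}

#' Reset a task environment to the start of a fresh trial
#'
#' @param spec A \code{choice_task}.
#' @param fixed_epochs Use midpoint epoch durations.
#' @return Environment state list (\code{t} counts elapsed 20-ms steps).
#' @export
env_reset <- function(spec, fixed_epochs = FALSE) {
  trial <- build_trial(spec, fixed_epochs)
  list(spec = spec, trial = trial, t = 0L, done = FALSE,
       reward = 0, completed = FALSE, aborted = FALSE,
       chosen = NA_integer_, rt_ms = NA_real_)
}

# Visibility of each good's offer channels at step t (single env).
good_visibility <- function(state) {
  tl <- state$trial$timeline
  t <- state$t
  vis <- stats::setNames(rep(FALSE, 5), GOOD_IDS)
  offered <- GOOD_IDS[!is.na(state$trial$offers$q)]
  if (state$spec$sequential) {
    fg <- state$trial$first_good
    sg <- state$trial$second_good
    if (t >= tl["rule_end"] && t < tl["o1_end"]) vis[fg] <- TRUE
    if (t >= tl["d_end"] && t < tl["resp_end"]) vis[sg] <- TRUE
  } else {
    if (t >= tl["rule_end"] && t < tl["resp_end"]) vis[offered] <- TRUE
  }
  vis
}

#' Encode the current observation vector
#'
#' Active channels carry normalized signals in \code{[0, 1]}: the fixation
#' cue is high until the response phase (its offset is the go signal), the
#' task's rule cue is high from the rule epoch until trial end, and a
#' visible offer sets its good's quantity channel to \code{q/(10/rho)} and
#' its probability channel to \code{p}. Every channel carries a baseline
#' \code{u0 = 0.2} plus (optionally) Gaussian input noise whose per-step
#' standard deviation is \code{sigma_in * sqrt(2/alpha)}, the Euler
#' discretization of continuous white noise with amplitude
#' \code{sqrt(2*tau)*sigma_in}.
#'
#' @param state Environment state from \code{env_reset}/\code{env_step}.
#' @param noise Add input noise.
#' @param sigma_in Input noise amplitude.
#' @param alpha Discretization ratio dt/tau used for the noise scaling.
#' @param u0 Baseline input.
#' @return Numeric vector of length 16 named by \code{obs_channels()}.
#' @export
encode_observation <- function(state, noise = TRUE, sigma_in = 0.01,
                               alpha = 0.2, u0 = 0.2) {
  tl <- state$trial$timeline
  t <- state$t
  sig <- stats::setNames(numeric(16), obs_channels())
  if (t < tl["resp_start"]) sig["fix"] <- 1
  if (t >= tl["fix_end"]) sig[paste0("rule_", state$spec$name)] <- 1
  vis <- good_visibility(state)
  if (any(vis)) {
    g <- GOOD_IDS[vis]
    qn <- state$trial$offers$q[g] / (10 / state$spec$rho[g])
    sig[paste0("q_", g)] <- qn
    sig[paste0("p_", g)] <- state$trial$offers$p[g]
  }
  out <- sig + u0
  if (noise) out <- out + stats::rnorm(16, 0, sigma_in * sqrt(2 / alpha))
  out
}

#' Advance the environment by one 20-ms step
#'
#' Action 0 is fixate/hold; actions 1..3 select offer slots. Any non-hold
#' action before the response phase (including a slot the task does not
#' offer) breaks fixation and aborts the trial with reward -1. During the
#' response window, choosing slot X delivers each component good's reward
#' \code{rho * q} with probability \code{p} (independently per good for
#' bundles); selecting a slot that does not exist ends the trial
#' unrewarded as an error (incomplete). Failing to respond within the
#' window also ends the trial unrewarded and incomplete.
#'
#' @param state Environment state.
#' @param action Integer in 0..3.
#' @return Updated state; fields \code{reward}, \code{done},
#'   \code{completed}, \code{aborted}, \code{chosen}, \code{rt_ms} are set
#'   on terminal steps.
#' @export
env_step <- function(state, action) {
  stopifnot(!state$done, action %in% 0:3)
  tl <- state$trial$timeline
  t <- state$t
  spec <- state$spec
  in_response <- t >= tl["resp_start"] && t < tl["resp_end"]
  state$reward <- 0
  if (action != 0L && !in_response) {
    state$reward <- -1
    state$done <- TRUE
    state$aborted <- TRUE
    return(state)
  }
  if (action > spec$n_choices && in_response) {
    # error response: chose a slot the task does not offer
    state$done <- TRUE
    return(state)
  }
  if (action != 0L && in_response) {
    slot <- spec$slots[[action]]
    rew <- 0
    for (g in slot$goods) {
      q <- state$trial$offers$q[[g]]
      p <- state$trial$offers$p[[g]]
      if (stats::runif(1) < p) rew <- rew + spec$rho[[g]] * q
    }
    state$reward <- rew
    state$done <- TRUE
    state$completed <- TRUE
    state$chosen <- as.integer(action)
    state$rt_ms <- (t - unname(tl["resp_start"]) + 1) * spec$dt_ms
    return(state)
  }
  # hold
  state$t <- t + 1L
  if (state$t >= tl["resp_end"]) {
    state$done <- TRUE  # timeout, unrewarded, incomplete
  }
  state
}

#' Expected value of each offer slot
#'
#' @param spec A \code{choice_task}.
#' @param offers Offers list from \code{build_trial}.
#' @return Numeric vector of slot expected values (Offer Value
#'   \code{rho * q * p}, summed over a bundle's component goods).
#' @export
slot_values <- function(spec, offers) offers$values

#' One-row data frame summarizing a finished trial
#' @param state Terminal environment state.
#' @param trial_id Integer id to record.
#' @return data.frame with offer parameters, choice and outcome.
#' @export
trial_record <- function(state, trial_id = 1L) {
  off <- state$trial$offers
  v <- off$values
  correct <- if (state$completed) v[state$chosen] >= max(v) - 1e-12 else NA
  d <- data.frame(
    trial = trial_id, task = state$spec$name,
    chosen = state$chosen, reward = state$reward,
    completed = state$completed, aborted = state$aborted,
    rt_ms = state$rt_ms, correct = correct,
    order = state$trial$order, arm = off$arm,
    v1 = v[1], v2 = v[2], v3 = if (length(v) > 2) v[3] else NA_real_,
    stringsAsFactors = FALSE)
  for (g in GOOD_IDS) {
    d[[paste0("q_", g)]] <- off$q[[g]]
    d[[paste0("p_", g)]] <- off$p[[g]]
  }
  d
}
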